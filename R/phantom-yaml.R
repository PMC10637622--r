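#' Read a phantom spec from YAML
#'
#' Keys mirror the arguments of \code{\link{phantom_spec}}; \code{lesions}
#' is a list of maps with \code{center_mm}, \code{radii_mm}, \code{hu},
#' \code{label_value}. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated \code{phantom_spec}.
#' @export
phantom_spec_from_yaml <- function(path) {
  if (!file.exists(path))
    qv_stop("qv_parse_error", sprintf("no such file: %s", path))
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    qv_stop("qv_parse_error", sprintf("malformed YAML %s: %s", path,
                                      conditionMessage(e))))
  allowed <- names(formals(phantom_spec))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    qv_stop("qv_validation_error",
            sprintf("unknown phantom spec key(s): %s",
                    paste(unknown, collapse = ", ")))
  if (!is.null(y$lesions))
    y$lesions <- lapply(y$lesions, function(l)
      do.call(ellipsoid_lesion, l))
  if (!is.null(y$pixel_spacing_mm)) y$pixel_spacing_mm <- unlist(y$pixel_spacing_mm)
  if (!is.null(y$orientation)) y$orientation <- unlist(y$orientation)
  if (!is.null(y$origin_mm)) y$origin_mm <- unlist(y$origin_mm)
  do.call(phantom_spec, y)
}
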