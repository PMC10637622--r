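#' Structured error conditions
#'
#' All errors raised by the package are conditions inheriting from
#' \code{"qv_error"}, with a specific subclass naming the failure mode
#' (\code{"qv_validation_error"}, \code{"qv_geometry_error"},
#' \code{"qv_format_error"}, \code{"qv_linkage_error"},
#' \code{"qv_delivery_error"}, \code{"qv_plugin_error"},
#' \code{"qv_empty_segmentation_error"}, \code{"qv_parse_error"}).
#'
#' @param class character; the specific condition subclass.
#' @param message character; human-readable description.
#' @param ... named fields attached to the condition object.
#' @return Does not return; signals an error condition.
#' @keywords internal
qv_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "qv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}
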