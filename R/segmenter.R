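#' Pluggable segmentation stage
#'
#' The inference step has one stable contract: an HU image volume in, an
#' integer label volume out on the identical grid. Any algorithm honoring
#' the contract can be swapped in; the package ships a deterministic
#' HU-threshold reference segmenter (standing in for a trained network,
#' whose weights are out of scope) plus an external-command adapter that
#' runs a user model through NIfTI files on disk.
#'
#' @name qv-segmenter
NULL

#' Parameters of the reference threshold segmenter
#'
#' @param hu_low,hu_high inclusive HU band selecting foreground voxels
#'   (hu_low <= hu_high required).
#' @param keep_largest_component keep only the largest 26-connected
#'   component (ties broken by earliest-scanned component in index order).
#' @param min_component_voxels drop components smaller than this.
#' @return A \code{threshold_params}.
#' @export
threshold_params <- function(hu_low = 40, hu_high = 80,
                             keep_largest_component = FALSE,
                             min_component_voxels = 0L) {
  if (hu_low > hu_high)
    qv_stop("qv_validation_error", "hu_low must be <= hu_high",
            field = "hu_low")
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 keep_largest_component = isTRUE(keep_largest_component),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "threshold_params")
}

#' Label 26-connected components of a 3-D logical array
#'
#' Breadth-first flood fill over foreground voxels; component ids are
#' assigned in first-encounter (column-major scan) order, which fixes the
#' tie-break used by \code{\link{reference_segment}}.
#'
#' @param fg 3-D logical array.
#' @return Integer array of component labels (0 = background).
#' @export
label_components_26 <- function(fg) {
  d <- dim(fg)
  if (length(d) != 3L) qv_stop("qv_validation_error", "fg must be 3-D")
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  labels <- array(0L, d)
  seeds <- which(fg)           # column-major scan order
  if (length(seeds) == 0L) return(labels)
  # 26-neighborhood index offsets with boundary handling via coordinates
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  next_label <- 0L
  for (seed in seeds) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    queue <- seed
    labels[seed] <- next_label
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      i0 <- (cur - 1L) %% nx
      j0 <- ((cur - 1L) %/% nx) %% ny
      k0 <- (cur - 1L) %/% (nx * ny)
      for (o in seq_len(nrow(offs))) {
        i <- i0 + offs[o, 1L]; j <- j0 + offs[o, 2L]; k <- k0 + offs[o, 3L]
        okm <- i >= 0L & i < nx & j >= 0L & j < ny & k >= 0L & k < nz
        if (!any(okm)) next
        idx <- 1L + i[okm] + nx * (j[okm] + ny * k[okm])
        idx <- idx[fg[idx] & labels[idx] == 0L]
        if (length(idx)) {
          idx <- unique(idx)
          labels[idx] <- next_label
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' Reference HU-threshold segmenter
#'
#' Labels a voxel 1 when its HU value lies in \code{[hu_low, hu_high]}, then
#' removes 26-connected components below \code{min_component_voxels}; if
#' \code{keep_largest_component}, only the largest surviving component is
#' retained. Deterministic and bit-reproducible.
#'
#' @param v an HU image \code{geometric_volume}.
#' @param p a \code{threshold_params}.
#' @return A binary label \code{geometric_volume} on the same grid.
#' @export
reference_segment <- function(v, p = threshold_params()) {
  stopifnot(inherits(v, "geometric_volume"))
  if (length(v$voxels) == 0L)
    qv_stop("qv_validation_error", "empty volume")
  fg <- v$voxels >= p$hu_low & v$voxels <= p$hu_high
  mask <- array(0L, dim(v$voxels))
  if (any(fg)) {
    comps <- label_components_26(fg)
    sizes <- tabulate(comps[comps > 0L])
    keep <- which(sizes >= max(1L, p$min_component_voxels))
    if (p$keep_largest_component && length(keep)) {
      # which.max returns the earliest index on ties = earliest-scanned comp
      keep <- keep[which.max(sizes[keep])]
    }
    mask[comps %in% keep & comps > 0L] <- 1L
  }
  geometric_volume(mask, v$affine, source_sop_uids = v$source_sop_uids,
                   study_uid = v$study_uid, series_uid = v$series_uid)
}

# ---- plugin contract --------------------------------------------------------

#' Define a segmenter plugin
#'
#' @param name plugin name used in config and error messages.
#' @param run function \code{geometric_volume -> geometric_volume} producing
#'   non-negative integer labels on the input grid.
#' @return A \code{segmenter_plugin}.
#' @export
segmenter_plugin <- function(name, run) {
  stopifnot(is.character(name), is.function(run))
  structure(list(name = name, run = run), class = "segmenter_plugin")
}

#' Run a plugin and validate its output contract
#'
#' The plugin output must have the input's shape, an affine within 1e-6 of
#' the input's, and non-negative integer labels; otherwise a
#' \code{qv_plugin_error} names the violation. An error raised inside the
#' plugin is wrapped as a \code{qv_plugin_error} so a failing series is
#' reported, never silently dropped.
#'
#' @param plugin a \code{segmenter_plugin}.
#' @param v input HU \code{geometric_volume}.
#' @return The validated label \code{geometric_volume}.
#' @export
run_plugin <- function(plugin, v) {
  out <- tryCatch(plugin$run(v), error = function(e)
    qv_stop("qv_plugin_error",
            sprintf("plugin '%s' raised: %s", plugin$name,
                    conditionMessage(e)), plugin = plugin$name))
  if (!inherits(out, "geometric_volume"))
    qv_stop("qv_plugin_error",
            sprintf("plugin '%s' did not return a geometric_volume",
                    plugin$name), plugin = plugin$name)
  if (!identical(dim(out$voxels), dim(v$voxels)))
    qv_stop("qv_plugin_error",
            sprintf("plugin '%s' changed the volume shape (%s -> %s)",
                    plugin$name, paste(dim(v$voxels), collapse = "x"),
                    paste(dim(out$voxels), collapse = "x")),
            plugin = plugin$name)
  if (max(abs(out$affine - v$affine)) > 1e-6)
    qv_stop("qv_plugin_error",
            sprintf("plugin '%s' changed the affine", plugin$name),
            plugin = plugin$name)
  if (any(out$voxels < 0) || any(out$voxels != round(out$voxels)))
    qv_stop("qv_plugin_error",
            sprintf("plugin '%s' produced non-integer or negative labels",
                    plugin$name), plugin = plugin$name)
  out
}

#' Build a plugin from config
#'
#' Known names: \code{"reference_threshold"} (params: hu_low, hu_high,
#' keep_largest_component, min_component_voxels) and
#' \code{"external_command"} (params: command with \code{{input}} /
#' \code{{output}} placeholders for the NIfTI paths).
#'
#' @param name plugin name.
#' @param params named list of plugin parameters.
#' @return A \code{segmenter_plugin}.
#' @export
make_plugin <- function(name, params = list()) {
  if (name == "reference_threshold") {
    p <- do.call(threshold_params, params)
    return(segmenter_plugin(name, function(v) reference_segment(v, p)))
  }
  if (name == "external_command") {
    cmd_template <- params$command
    if (is.null(cmd_template))
      qv_stop("qv_validation_error",
              "external_command plugin requires a 'command' parameter")
    return(segmenter_plugin(name, function(v) {
      workdir <- tempfile("qv_plugin_")
      dir.create(workdir)
      on.exit(unlink(workdir, recursive = TRUE))
      in_path <- file.path(workdir, "input.nii.gz")
      out_path <- file.path(workdir, "labels.nii.gz")
      write_volume(v, in_path)
      cmd <- gsub("{input}", in_path, cmd_template, fixed = TRUE)
      cmd <- gsub("{output}", out_path, cmd, fixed = TRUE)
      status <- system(cmd)
      if (status != 0L || !file.exists(out_path))
        stop(sprintf("external command failed (exit %d)", status))
      out <- read_volume(out_path)
      # the label file carries neither the UID tree nor the affine at full
      # precision (NIfTI stores 32-bit floats): check grid congruence at the
      # file format's tolerance, then inherit the input grid exactly
      if (max(abs(out$affine - v$affine)) > 1e-4)
        stop("external command returned labels on a different grid")
      geometric_volume(out$voxels, v$affine,
                       source_sop_uids = v$source_sop_uids,
                       study_uid = v$study_uid, series_uid = v$series_uid)
    }))
  }
  qv_stop("qv_validation_error", sprintf("unknown segmenter plugin '%s'", name))
}
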