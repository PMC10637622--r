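# Shared fixture builders: every fixture is generated in code at test time.

# a small, fast phantom with one segmentable lesion centered in the grid
tiny_spec <- function(rows = 24L, cols = 24L, n_slices = 10L,
                      pixel_spacing = c(1, 1), slice_spacing = 2,
                      radii = c(6, 5, 7), hu = 60, seed = 1L, ...) {
  center <- c(-100 + cols * pixel_spacing[2] / 2,
              -80 + rows * pixel_spacing[1] / 2,
              50 + (n_slices - 1) * slice_spacing / 2)
  phantom_spec(rows = rows, cols = cols, n_slices = n_slices,
               pixel_spacing_mm = pixel_spacing,
               slice_thickness_mm = slice_spacing,
               slice_spacing_mm = slice_spacing,
               origin_mm = c(-100, -80, 50),
               lesions = list(ellipsoid_lesion(center, radii, hu = hu)),
               seed = seed, ...)
}

# a randomized phantom spec; deterministic in `i`
random_spec <- function(i) {
  set.seed(1000L + i)
  rows <- sample(16:32, 1)
  cols <- sample(16:32, 1)
  n_slices <- sample(6:14, 1)
  ps <- round(stats::runif(2, 0.6, 2.0), 2)
  step <- round(stats::runif(1, 1.0, 4.0), 1)
  hi <- max(3.5, 0.35 * min(rows * ps[1], cols * ps[2], n_slices * step))
  radii <- round(stats::runif(3, 3, hi), 1)
  tiny_spec(rows = rows, cols = cols, n_slices = n_slices,
            pixel_spacing = ps, slice_spacing = step, radii = radii,
            seed = 1000L + i)
}

# sphere phantom on an isotropic grid, radius 10 mm, centered on a voxel
sphere_spec <- function(spacing) {
  n <- as.integer(ceiling(26 / spacing))
  if (n %% 2L == 0L) n <- n + 1L   # odd extent centers the sphere on a voxel
  center <- c(-100, -80, 50) + (n - 1) / 2 * spacing
  phantom_spec(rows = n, cols = n, n_slices = n,
               pixel_spacing_mm = c(spacing, spacing),
               slice_thickness_mm = spacing, slice_spacing_mm = spacing,
               origin_mm = c(-100, -80, 50),
               lesions = list(ellipsoid_lesion(center, rep(10, 3))))
}

# independent brute-force oracle: count voxel centers inside each lesion by
# plain per-voxel loops over coordinates computed directly from spec fields
brute_force_voxel_count <- function(spec) {
  r_dir <- spec$orientation[1:3]; c_dir <- spec$orientation[4:6]
  n_dir <- c(r_dir[2] * c_dir[3] - r_dir[3] * c_dir[2],
             r_dir[3] * c_dir[1] - r_dir[1] * c_dir[3],
             r_dir[1] * c_dir[2] - r_dir[2] * c_dir[1])
  count <- 0L
  for (s in seq_len(spec$n_slices) - 1L)
    for (r in seq_len(spec$rows) - 1L)
      for (c_ in seq_len(spec$cols) - 1L) {
        p <- spec$origin_mm + c_ * spec$pixel_spacing_mm[2] * r_dir +
          r * spec$pixel_spacing_mm[1] * c_dir + s * spec$slice_spacing_mm * n_dir
        inside <- FALSE
        for (l in spec$lesions) {
          d2 <- sum(((p - l$center_mm) / l$radii_mm)^2)
          if (d2 <= 1) inside <- TRUE
        }
        if (inside) count <- count + 1L
      }
  count
}

# world position of pixel (col0, row0) of sorted slice s0 (all zero-based),
# computed slice-by-slice from DICOM tags, in RAS
brute_force_world <- function(instances, col0, row0, s0) {
  # order slices by normal projection without using package sorting
  iop <- dcm_get(instances[[1]], "ImageOrientationPatient")
  r_dir <- iop[1:3]; c_dir <- iop[4:6]
  n_dir <- c(r_dir[2] * c_dir[3] - r_dir[3] * c_dir[2],
             r_dir[3] * c_dir[1] - r_dir[1] * c_dir[3],
             r_dir[1] * c_dir[2] - r_dir[2] * c_dir[1])
  proj <- vapply(instances, function(x)
    sum(dcm_get(x, "ImagePositionPatient") * n_dir), numeric(1))
  inst <- instances[[order(proj)[s0 + 1L]]]
  ps <- dcm_get(inst, "PixelSpacing")
  lps <- dcm_get(inst, "ImagePositionPatient") +
    col0 * ps[2] * r_dir + row0 * ps[1] * c_dir
  lps * c(-1, -1, 1)
}
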