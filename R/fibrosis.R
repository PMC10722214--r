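# Orientation fields and patchy-fibrosis substrates.
#
# Fibrosis maps are produced by thresholding a stationary Gaussian random
# field (white noise convolved with an isotropic Gaussian kernel) so that an
# exact target fraction of nodes is fibrotic; connected components of the
# fibrotic set (4-connectivity, matching the axial bond directions of the
# coupling lattice) are the "patches".

#' Generate a myocyte orientation field
#'
#' Three field types are supported.  `"OY"` is the fully idealised case:
#' every node's fibre unit vector is exactly (0, 1).  `"control"` is a
#' smoothly varying field: the fibre angle is `pi/2` plus a long-wavelength
#' Gaussian-random-field perturbation, so neighbouring nodes differ by at
#' most a few degrees.  `"remodelled"` starts from a control field and
#' overwrites randomly placed rectangular blocks with angles near the
#' x-axis, producing abrupt orientation changes and a larger x-component
#' representation, as in structurally remodelled atria.
#'
#' @param field_type one of `"OY"`, `"control"`, `"remodelled"`.
#' @param nx,ny grid dimensions (nodes); both at least 2.
#' @param amplitude angular amplitude of the smooth perturbation (radians).
#' @param length_scale correlation length of the smooth perturbation
#'   (nodes).
#' @param n_blocks,block_range number and side-length range (nodes) of the
#'   abruptly rotated blocks in the remodelled field.
#' @return an `orientation_field`: list with matrices `fx`, `fy`, `theta`
#'   (radians) and metadata.  Uses R's RNG for the random field types.
#' @export
make_orientation <- function(field_type = c("OY", "control", "remodelled"),
                             nx, ny, amplitude = 0.55, length_scale = 25,
                             n_blocks = 12, block_range = c(10, 30)) {
  field_type <- match.arg(field_type)
  stopifnot(nx >= 2, ny >= 2)
  if (field_type == "OY") {
    theta <- matrix(pi / 2, nx, ny)
    fx <- matrix(0, nx, ny)
    fy <- matrix(1, nx, ny)
  } else {
    z <- generate_grf(nx, ny, length_scale)
    theta <- pi / 2 + amplitude * z
    if (field_type == "remodelled") {
      for (b in seq_len(n_blocks)) {
        w <- sample(block_range[1]:block_range[2], 1)
        h <- sample(block_range[1]:block_range[2], 1)
        x0 <- sample(seq_len(max(1, nx - w)), 1)
        y0 <- sample(seq_len(max(1, ny - h)), 1)
        ang <- runif(1, -0.25, 0.25)  # near the x-axis
        theta[x0:(x0 + w - 1), y0:(y0 + h - 1)] <- ang
      }
    }
    fx <- cos(theta)
    fy <- sin(theta)
  }
  structure(list(fx = fx, fy = fy, theta = theta, field_type = field_type,
                 nx = nx, ny = ny),
            class = "orientation_field")
}

#' Generate a stationary Gaussian random field
#'
#' White noise is convolved (circularly, via the FFT) with an isotropic
#' Gaussian kernel of standard deviation `length_scale / 2`, giving a
#' zero-mean stationary field with Gaussian autocorrelation
#' `C(r) = exp(-r^2 / length_scale^2)`, i.e. correlation `exp(-1)` at lag
#' `length_scale`.  The result is normalised to zero mean and unit variance.
#' Uses R's RNG.
#'
#' @param nx,ny grid dimensions.
#' @param length_scale correlation length in nodes (positive).  Values well
#'   below one node give an effectively white field.
#' @return an `nx` by `ny` numeric matrix.
#' @export
generate_grf <- function(nx, ny, length_scale) {
  stopifnot(length_scale > 0, nx >= 2, ny >= 2)
  noise <- matrix(rnorm(nx * ny), nx, ny)
  sk <- length_scale / 2
  if (sk < 0.2) return((noise - mean(noise)) / sd(noise))
  dxs <- pmin(0:(nx - 1), nx - (0:(nx - 1)))
  dys <- pmin(0:(ny - 1), ny - (0:(ny - 1)))
  kern <- exp(-outer(dxs^2, dys^2, "+") / (2 * sk^2))
  f <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (nx * ny)
  (f - mean(f)) / sd(f)
}

#' Threshold a scalar field into a fibrosis map with an exact area fraction
#'
#' Flags the top `area_fraction` quantile of field values as fibrotic: the
#' fibrotic node count is exactly `round(area_fraction * nx * ny)`, with
#' ties broken by the stable ordering of [order()].  Thresholding is
#' monotone: the fibrotic set at a lower fraction is a subset of the set at
#' a higher fraction for the same field.
#'
#' @param field numeric matrix, e.g. from [generate_grf()].
#' @param area_fraction target fibrotic fraction in `[0, 1]`.
#' @param patch_seed optional patch-size seed recorded as metadata.
#' @return a `fibrosis_map`: list with the logical `mask`, integer patch
#'   `labels` (4-connectivity components; 0 outside patches), `n_patches`,
#'   `area_fraction` and dimensions.
#' @export
threshold_to_area <- function(field, area_fraction, patch_seed = NA) {
  stopifnot(is.matrix(field), area_fraction >= 0, area_fraction <= 1)
  nx <- nrow(field)
  ny <- ncol(field)
  k <- round(area_fraction * nx * ny)
  mask <- matrix(FALSE, nx, ny)
  if (k > 0) mask[order(as.vector(field), decreasing = TRUE)[seq_len(k)]] <- TRUE
  labels <- .label_components_cpp(mask)
  structure(list(mask = mask, labels = labels,
                 n_patches = attr(labels, "n_components"),
                 area_fraction = area_fraction, patch_seed = patch_seed,
                 nx = nx, ny = ny),
            class = "fibrosis_map")
}

#' Generate a patchy fibrosis map
#'
#' Convenience wrapper: draws a Gaussian random field whose correlation
#' length is set by the patch-size seed and thresholds it to the target
#' total fibrotic area.  The patch-size seed is mapped to the correlation
#' length as `length_scale = patch_seed / 2.5` nodes, so seed 10 gives many
#' small patches and seed 50 a few large ones at the same total area.
#'
#' @param nx,ny grid dimensions.
#' @param patch_seed patch-size seed (dimensionless; 10 = small patches,
#'   50 = large patches).
#' @param area_fraction total fibrotic area fraction (the protocols use 0.25
#'   or 0.5).
#' @return a `fibrosis_map` (see [threshold_to_area()]).  Uses R's RNG.
#' @export
make_fibrosis <- function(nx, ny, patch_seed = 10, area_fraction = 0.25) {
  stopifnot(patch_seed > 0)
  field <- generate_grf(nx, ny, patch_seed / 2.5)
  threshold_to_area(field, area_fraction, patch_seed = patch_seed)
}

#' An all-clear (no fibrosis) map
#' @param nx,ny grid dimensions.
#' @export
no_fibrosis <- function(nx, ny) {
  threshold_to_area(matrix(0, nx, ny), 0)
}

#' Patch statistics of a fibrosis map
#'
#' @param map a `fibrosis_map`.
#' @param dx inter-nodal spacing (mm).
#' @return a list with `count`, `mean_area`, `median_area` (mm^2),
#'   `sizes_nodes` (per-patch node counts) and `areas_mm2`.
#' @export
patch_statistics <- function(map, dx = 0.3125) {
  stopifnot(inherits(map, "fibrosis_map"))
  if (is.null(map$labels)) stop("fibrosis map is unlabelled")
  if (map$n_patches == 0) {
    return(list(count = 0L, mean_area = NA_real_, median_area = NA_real_,
                sizes_nodes = integer(0), areas_mm2 = numeric(0)))
  }
  sizes <- tabulate(map$labels[map$labels > 0], nbins = map$n_patches)
  areas <- sizes * dx^2
  list(count = map$n_patches, mean_area = mean(areas),
       median_area = median(areas), sizes_nodes = sizes, areas_mm2 = areas)
}

#' @export
print.fibrosis_map <- function(x, ...) {
  cat("<fibrosis_map>", x$nx, "x", x$ny, "nodes,",
      sprintf("%.1f%% fibrotic,", 100 * x$area_fraction),
      x$n_patches, "patches\n")
  invisible(x)
}
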