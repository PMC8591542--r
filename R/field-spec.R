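#' Specification of a synthetic microscopy field
#'
#' Describes one simulated field of budding-yeast cells carrying a cytosolic
#' BFP, a general ER marker (Sec63-mNeon-like) and a high-curvature ER marker
#' (Rtn1-mCherry-like), imaged either as an optical mid section (peripheral
#' ER band along the cell border) or a cortical section (tangential view of
#' the tubule/sheet network). The same spec rendered twice yields identical
#' pixels.
#'
#' @param image_size integer c(height, width) in pixels.
#' @param n_cells number of cells to place.
#' @param cell_radius_range c(min, max) semi-major axis in pixels.
#' @param pixel_size physical pixel size in micrometres (default 0.108,
#'   a 60x objective on an sCMOS-class camera).
#' @param section "mid" or "cortical".
#' @param n_slices z-slices in the stack (default 5).
#' @param slice_spacing z-spacing in micrometres (default 1).
#' @param target_tubule_fraction,target_sheet_fraction,target_cluster_fraction
#'   desired cortex coverage of tubules, sheets and dense tubular clusters
#'   (cortical sections); their sum must be <= 1.
#' @param er_band_coverage fraction of the cell periphery covered by the
#'   peripheral ER band (mid sections).
#' @param n_gaps_per_cell number of gaps interrupting the band (mid
#'   sections); coverage < 1 requires at least one gap.
#' @param tubule_width ER structure width in pixels (band thickness for mid
#'   sections, tubule diameter for cortical).
#' @param psf_sigma in-focus Gaussian PSF sigma in pixels.
#' @param noise list with `gaussian_sd` (additive read noise, fraction of
#'   signal amplitude) and `poisson_scale` (photons per intensity unit;
#'   0 disables shot noise).
#' @param seed integer seed; all field randomness derives from it.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(image_size = c(256, 256),
                       n_cells = 8,
                       cell_radius_range = c(15, 25),
                       pixel_size = 0.108,
                       section = c("mid", "cortical"),
                       n_slices = 5,
                       slice_spacing = 1,
                       target_tubule_fraction = 0.3,
                       target_sheet_fraction = 0.2,
                       target_cluster_fraction = 0,
                       er_band_coverage = 1,
                       n_gaps_per_cell = 0,
                       tubule_width = NULL,
                       psf_sigma = 1,
                       noise = list(gaussian_sd = 0.05, poisson_scale = 0),
                       seed = 1) {
  section <- match.arg(section)
  if (is.null(tubule_width)) tubule_width <- if (section == "mid") 5 else 3
  spec <- structure(list(
    image_size = as.integer(image_size), n_cells = as.integer(n_cells),
    cell_radius_range = cell_radius_range, pixel_size = pixel_size,
    section = section, n_slices = as.integer(n_slices),
    slice_spacing = slice_spacing,
    target_tubule_fraction = target_tubule_fraction,
    target_sheet_fraction = target_sheet_fraction,
    target_cluster_fraction = target_cluster_fraction,
    er_band_coverage = er_band_coverage,
    n_gaps_per_cell = as.integer(n_gaps_per_cell),
    tubule_width = tubule_width, psf_sigma = psf_sigma,
    noise = noise, seed = as.integer(seed)
  ), class = "field_spec")
  validate_field_spec(spec)
  spec
}

validate_field_spec <- function(spec) {
  assert_that(length(spec$image_size) == 2 && all(spec$image_size >= 32),
              "image_size must be c(height, width), each >= 32")
  assert_that(spec$n_cells >= 0, "n_cells must be >= 0")
  assert_that(spec$cell_radius_range[1] <= spec$cell_radius_range[2] &&
                spec$cell_radius_range[1] >= 3,
              "cell_radius_range must satisfy 3 <= min <= max")
  assert_that(spec$n_slices >= 1, "n_slices must be >= 1")
  fr <- c(spec$target_tubule_fraction, spec$target_sheet_fraction,
          spec$target_cluster_fraction, spec$er_band_coverage)
  assert_that(all(fr >= 0 & fr <= 1), "all fractions must lie in [0, 1]")
  assert_that(spec$target_tubule_fraction + spec$target_sheet_fraction +
                spec$target_cluster_fraction <= 1,
              "tubule + sheet + cluster fractions must sum to <= 1")
  if (spec$section == "mid") {
    if (spec$er_band_coverage < 1 && spec$n_gaps_per_cell < 1)
      stop("er_band_coverage < 1 requires n_gaps_per_cell >= 1", call. = FALSE)
    if (spec$er_band_coverage >= 1 && spec$n_gaps_per_cell > 0)
      stop("a fully closed band (coverage 1) cannot contain gaps", call. = FALSE)
  }
  assert_that(spec$tubule_width >= 1, "tubule_width must be >= 1 pixel")
  invisible(spec)
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("field_spec: %s section, %dx%d px, %d cells, %d slice(s), seed %d\n",
              x$section, x$image_size[1], x$image_size[2], x$n_cells,
              x$n_slices, x$seed))
  invisible(x)
}

# deterministic sub-seed derivation (Lehmer step); stays below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed %% 2147483647L) * 48271 + k) %% 2147483647)
}
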