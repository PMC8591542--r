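## Mid-section pipeline: best-focus selection, border enhancement, cell
## segmentation, ellipse-border refinement and the three ER-size metrics.

#' Parameters of the mid-section pipeline
#'
#' @param bandpass_wavelengths c(min, max) retained feature wavelengths in
#'   pixels for the FFT bandpass contrast enhancement.
#' @param frangi_scales_border Frangi scales (px) for cell-border detection.
#' @param frangi_scales_er tubeness scales (px) for ER segmentation.
#' @param min_cell_area minimum interior object area in pixels; default 25%
#'   of the area of a circle with the smallest expected cell radius (15 px).
#' @param border_min_size minimum border-fragment size kept after opening;
#'   defaults to half of `min_cell_area`.
#' @param opening_radius radius (px) of the morphological opening that
#'   suppresses vacuole-induced false borders.
#' @param closing_radius disk radius (px) of the closing that seals small
#'   breaks in the detected borders so cell interiors stay enclosed.
#' @param mad_k intensity filter: objects dimmer than
#'   median - `mad_k` * MAD are discarded (default 2).
#' @param watershed_tolerance tolerance of the distance-transform watershed
#'   that splits touching cells.
#' @param label_completion px by which the enclosed interiors are grown
#'   (never across the midline to a neighbour) to recover the border ridge
#'   thickness, so labels approximate whole cells (default 3).
#' @param max_border_expand maximum dilation (px) of a cell object when
#'   collecting ER pixels, clipped to its watershed region.
#' @param periphery_width width (px) of the periphery band inside the fitted
#'   ellipse border (default 5).
#' @param border_offset inward shift (px) of the band start relative to the
#'   fitted ellipse (default 0).
#' @param er_tubeness_multiplier multiple of the tubeness Otsu threshold
#'   used for the ER ridge mask (default 0.6; below 1 so the tapering ridge
#'   response does not erode the band edges).
#' @param er_gate_multiplier the ER tubeness mask is gated by raw intensity
#'   above this multiple of the channel Otsu threshold (default 0.8), which
#'   keeps the ridge response from interpolating across true gaps without
#'   trimming the blurred band edges.
#' @param er_min_size ER-mask components smaller than this (px) are treated
#'   as noise and removed before the ellipse fit (default 9).
#' @param min_gap_area gap components smaller than this (px) count as
#'   segmentation noise, not ER gaps; default = `periphery_width`, so a
#'   counted gap must be at least one band-width worth of pixels.
#' @param population_sd_limit population filter keeps cells within this many
#'   SDs of the mean in every measurement (default 2.5).
#' @param mve_tolerance convergence tolerance of the minimum-volume ellipse.
#' @param pixel_size micrometres per pixel (default 0.108).
#' @return object of class `midcell_params`.
#' @export
midcell_params <- function(bandpass_wavelengths = c(2, 40),
                           frangi_scales_border = c(1, 1.5, 2),
                           frangi_scales_er = c(1.5, 2.5),
                           min_cell_area = round(0.25 * pi * 15^2),
                           border_min_size = NULL,
                           opening_radius = 1,
                           closing_radius = 2,
                           mad_k = 2,
                           watershed_tolerance = 1,
                           label_completion = 3,
                           max_border_expand = 8,
                           periphery_width = 5,
                           border_offset = 0,
                           er_tubeness_multiplier = 0.6,
                           er_gate_multiplier = 0.8,
                           er_min_size = 9,
                           min_gap_area = NULL,
                           population_sd_limit = 2.5,
                           mve_tolerance = 1e-3,
                           pixel_size = 0.108) {
  if (is.null(border_min_size)) border_min_size <- round(min_cell_area / 2)
  if (is.null(min_gap_area)) min_gap_area <- periphery_width
  p <- structure(as.list(environment()), class = "midcell_params")
  assert_that(p$periphery_width >= 1, "periphery_width must be >= 1")
  assert_that(p$mad_k > 0, "mad_k must be > 0")
  assert_that(p$population_sd_limit > 0, "population_sd_limit must be > 0")
  p
}

#' Select the in-focus slice of a stack
#'
#' The in-focus slice has the highest per-slice intensity standard
#' deviation. Ties break to the lowest index.
#'
#' @param stack 3D array (height x width x slices) or a 2D matrix.
#' @return integer slice index.
#' @export
select_best_slice <- function(stack) {
  if (is.matrix(stack)) return(1L)
  assert_that(length(dim(stack)) == 3 && dim(stack)[3] >= 1,
              "stack must have at least one slice")
  sds <- apply(stack, 3, sd)
  which.max(sds)
}

# annular FFT bandpass keeping wavelengths in [wl_min, wl_max] pixels
fft_bandpass <- function(img, wl) {
  H <- nrow(img); W <- ncol(img)
  fy <- pmin(seq_len(H) - 1, H - (seq_len(H) - 1)) / H   # cycles / pixel
  fx <- pmin(seq_len(W) - 1, W - (seq_len(W) - 1)) / W
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  keep <- fr >= 1 / wl[2] & fr <= 1 / wl[1]
  Re(stats::fft(stats::fft(img) * keep, inverse = TRUE)) / (H * W)
}

#' Enhance and binarize cell borders in a BFP mid-section image
#'
#' FFT bandpass for border contrast, Frangi vesselness, Otsu thresholding,
#' then a disk opening and a minimum size filter to suppress vacuole-induced
#' false borders.
#'
#' @param bfp 2D numeric matrix.
#' @param params a [midcell_params()].
#' @return logical border mask.
#' @export
enhance_cell_borders <- function(bfp, params = midcell_params()) {
  bfp <- as.matrix(bfp)
  if (diff(range(bfp)) == 0) return(matrix(FALSE, nrow(bfp), ncol(bfp)))
  bp <- fft_bandpass(bfp, params$bandpass_wavelengths)
  v <- frangi_filter(normalize01(bp), scales = params$frangi_scales_border)
  v <- normalize01(v)
  if (diff(range(v)) == 0) return(matrix(FALSE, nrow(bfp), ncol(bfp)))
  mask <- v > EBImage::otsu(EBImage::Image(v))
  mask <- as.matrix(EBImage::opening(
    mask * 1, EBImage::makeBrush(2 * params$opening_radius + 1, "box"))) > 0
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    mask <- matrix(sizes[pmax(lab, 1)] >= params$border_min_size & lab > 0,
                   nrow(mask), ncol(mask))
  }
  if (params$closing_radius > 0)
    mask <- as.matrix(EBImage::closing(
      mask * 1, EBImage::makeBrush(2 * params$closing_radius + 1, "disc"))) > 0
  mask
}

#' Segment cell interiors from a border mask
#'
#' The enclosed internal space identifies individual cells; dim objects
#' (below median - `mad_k` MAD of per-object mean intensity) are discarded,
#' and touching cells are split by a distance-transform watershed.
#'
#' @param border_mask logical border mask.
#' @param bfp the BFP image the mask came from.
#' @param params a [midcell_params()].
#' @return integer label matrix (0 = background).
#' @export
segment_cells <- function(border_mask, bfp, params = midcell_params()) {
  assert_that(all(dim(border_mask) == dim(bfp)),
              "border mask and intensity image must have the same shape")
  interior <- !border_mask
  lab <- EBImage::bwlabel(interior * 1)
  n <- max(lab)
  if (n == 0) { warning("no interior regions found"); return(matrix(0L, nrow(bfp), ncol(bfp))) }
  edge_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = n)
  drop <- union(edge_labels[edge_labels > 0], which(sizes < params$min_cell_area))
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) == 0) { warning("no interior regions found"); return(matrix(0L, nrow(bfp), ncol(bfp))) }
  means <- vapply(keep, function(i) mean(bfp[lab == i]), numeric(1))
  med <- median(means); m <- mad(means)   # scaled MAD (robust SD)
  keep <- keep[means >= med - params$mad_k * m]
  if (length(keep) == 0) { warning("all interior objects failed the intensity filter"); return(matrix(0L, nrow(bfp), ncol(bfp))) }
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  dm <- EBImage::distmap(mask * 1)
  out <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  out <- matrix(as.integer(out), nrow(mask), ncol(mask))
  if (params$label_completion > 0 && max(out) > 0) {
    # grow interiors back over the border ridge, nearest-label wins
    tess <- matrix(as.integer(EBImage::propagate(EBImage::Image(out * 0),
                                                 EBImage::Image(out))),
                   nrow(out), ncol(out))
    grown <- dilate_disc(out > 0, params$label_completion)
    out <- ifelse(grown, tess, 0L)
  }
  out
}

#' Refine cells: per-cell refocus, ER segmentation and ellipse border
#'
#' For each labelled cell, the best slice is re-selected from the
#' curvature-marker crop, the ER is segmented in both marker channels by a
#' tubeness filter with Otsu thresholding, and a minimum-volume ellipse
#' fitted to the combined ER mask defines the refined cell border. The
#' periphery band is the `periphery_width`-pixel radial band inside that
#' ellipse. Cells whose ER mask is empty or degenerate are dropped with a
#' message.
#'
#' @param cells integer label mask from [segment_cells()].
#' @param sec63,rtn1 marker stacks (height x width x slices) or 2D matrices.
#' @param params a [midcell_params()].
#' @return list of `cell_record` objects.
#' @export
refine_cells <- function(cells, sec63, rtn1, params = midcell_params()) {
  if (is.matrix(sec63)) sec63 <- array(sec63, c(dim(sec63), 1))
  if (is.matrix(rtn1)) rtn1 <- array(rtn1, c(dim(rtn1), 1))
  ids <- setdiff(sort(unique(as.vector(cells))), 0L)
  # Voronoi tessellation of the labels: each cell may expand into
  # background, but never across the midline to a neighbour
  tess <- if (length(ids) > 0)
    matrix(as.integer(EBImage::propagate(EBImage::Image(cells * 0),
                                         EBImage::Image(cells))),
           nrow(cells), ncol(cells)) else cells
  records <- list()
  for (id in ids) {
    rec <- tryCatch(refine_one_cell(id, cells, tess, sec63, rtn1, params),
                    error = function(e) { message("cell ", id, " dropped: ", conditionMessage(e)); NULL })
    if (!is.null(rec)) records[[length(records) + 1]] <- rec
  }
  records
}

refine_one_cell <- function(id, cells, tess, sec63, rtn1, params) {
  own <- cells == id
  ys <- range(which(rowSums(own) > 0)); xs <- range(which(colSums(own) > 0))
  mar <- params$periphery_width + params$max_border_expand
  ys <- max(1, ys[1] - mar):min(nrow(cells), ys[2] + mar)
  xs <- max(1, xs[1] - mar):min(ncol(cells), xs[2] + mar)
  crop_lab <- cells[ys, xs]
  own_c <- crop_lab == id
  tess_c <- tess[ys, xs]
  k <- select_best_slice(rtn1[ys, xs, , drop = FALSE])
  s63 <- sec63[ys, xs, k]; rt <- rtn1[ys, xs, k]
  # tubeness localizes curvilinear ER; the raw-intensity Otsu gate keeps the
  # ridge response from interpolating across true gaps in the band
  seg <- function(img) {
    tb <- normalize01(tubeness_filter(img, params$frangi_scales_er))
    if (diff(range(tb)) == 0) return(tb > 1)
    (tb > params$er_tubeness_multiplier * EBImage::otsu(EBImage::Image(tb))) &
      (img > params$er_gate_multiplier *
         EBImage::otsu(EBImage::Image(pmin(pmax(img, 0), 1))))
  }
  er <- seg(s63) | seg(rt)
  allowed <- dilate_disc(own_c, params$max_border_expand) & tess_c == id
  er <- er & allowed
  lab_er <- label8(er)
  if (max(lab_er) > 0) {
    sizes <- tabulate(lab_er[lab_er > 0])
    er <- er & matrix(sizes[pmax(lab_er, 1)] >= params$er_min_size,
                      nrow(er), ncol(er))
  }
  assert_that(sum(er) >= 3, "empty ER mask")
  pts <- cbind(x = col(er)[er], y = row(er)[er])
  hull <- grDevices::chull(pts)
  ell <- min_volume_ellipse(pts[hull, , drop = FALSE],
                            tolerance = params$mve_tolerance)
  dimc <- c(length(ys), length(xs))
  band <- ellipse_radial_band(dimc, ell$center, ell$A,
                              params$periphery_width + params$border_offset) &
    !ellipse_radial_band(dimc, ell$center, ell$A, params$border_offset)
  interior <- ellipse_interior(dimc, ell$center, ell$A)
  per <- ellipse_perimeter(ell$axes[1], ell$axes[2])
  structure(list(
    label = id, bbox = list(ys = ys, xs = xs), best_slice = k,
    border_ellipse = ell, periphery_band = band, er_mask = er,
    cell_area = sum(interior),
    roundness = 4 * pi * sum(interior) / per^2,
    mean_sec63 = mean(s63[interior]), mean_rtn1 = mean(rt[interior])
  ), class = "cell_record")
}

#' The three mid-section ER-size metrics
#'
#' Peripheral ER size (peripheral ER area / periphery band area), ER profile
#' size (mean 8-connected ER profile area / band area) and the number of ER
#' gaps per micrometre of cell periphery. Periphery length is the perimeter
#' of the band's centerline ellipse times `pixel_size`.
#'
#' @param cell a `cell_record` with a non-empty periphery band.
#' @param er_mask logical ER mask in the cell's crop frame; defaults to the
#'   record's own combined ER mask.
#' @param params a [midcell_params()].
#' @return object of class `er_size_metrics`: list with `peripheral_er_size`,
#'   `er_profile_size`, `er_gaps_per_um`, `n_gaps`, `periphery_um`.
#' @export
compute_er_metrics <- function(cell, er_mask = NULL, params = midcell_params()) {
  band <- cell$periphery_band
  assert_that(sum(band) > 0, "cell has an empty periphery band")
  if (is.null(er_mask)) er_mask <- cell$er_mask
  inter <- er_mask & band
  band_area <- sum(band)
  sizes <- component_sizes8(inter)
  n_gaps <- count_band_gaps(band & !er_mask, cell$border_ellipse,
                            params$periphery_width, params$min_gap_area)
  ax <- cell$border_ellipse$axes
  w <- params$periphery_width
  periphery_um <- ellipse_perimeter(max(ax[1] - w / 2, 1), max(ax[2] - w / 2, 1)) *
    params$pixel_size
  assert_that(periphery_um > 0, "zero-length periphery")
  structure(list(
    peripheral_er_size = sum(inter) / band_area,
    er_profile_size = if (length(sizes) == 0) 0 else mean(sizes) / band_area,
    er_gaps_per_um = n_gaps / periphery_um,
    n_gaps = n_gaps, periphery_um = periphery_um
  ), class = "er_size_metrics")
}

# Count ER gaps: 8-connected components of the band complement that are at
# least `min_area` pixels AND span most of the band radially. Slivers along
# one band edge (from a slightly offset ellipse fit) are not gaps.
count_band_gaps <- function(gap_mask, ellipse, width, min_area) {
  lab <- label8(gap_mask)
  n <- max(lab)
  if (n == 0) return(0L)
  qy <- row(lab) - ellipse$center[2]
  qx <- col(lab) - ellipse$center[1]
  rho <- sqrt(pmax(ellipse$A[1, 1] * qx^2 + 2 * ellipse$A[1, 2] * qx * qy +
                     ellipse$A[2, 2] * qy^2, 0))
  rd <- sqrt(qx^2 + qy^2) * (1 / pmax(rho, 1e-9) - 1)   # distance to border
  cnt <- 0L
  for (i in seq_len(n)) {
    sel <- lab == i
    if (sum(sel) < min_area) next
    if (diff(range(rd[sel])) >= 0.6 * width) cnt <- cnt + 1L
  }
  cnt
}

#' Run the whole mid-section pipeline on one field
#'
#' @param bfp,sec63,rtn1 channel stacks (height x width x slices).
#' @param params a [midcell_params()].
#' @param filter logical; apply the population filter to the measurement
#'   table (default TRUE).
#' @return list with `measurements` (one row per retained cell), `records`
#'   (the `cell_record` list) and `labels` (the initial segmentation).
#' @export
analyze_mid_field <- function(bfp, sec63, rtn1, params = midcell_params(),
                              filter = TRUE) {
  if (is.matrix(bfp)) bfp <- array(bfp, c(dim(bfp), 1))
  k <- select_best_slice(bfp)
  border <- enhance_cell_borders(bfp[, , k], params)
  labels <- segment_cells(border, bfp[, , k], params)
  records <- refine_cells(labels, sec63, rtn1, params)
  rows <- lapply(records, function(r) {
    m <- compute_er_metrics(r, params = params)
    data.frame(cell = r$label, best_slice = r$best_slice,
               cell_area = r$cell_area, roundness = r$roundness,
               mean_sec63 = r$mean_sec63, mean_rtn1 = r$mean_rtn1,
               peripheral_er_size = m$peripheral_er_size,
               er_profile_size = m$er_profile_size,
               er_gaps_per_um = m$er_gaps_per_um, n_gaps = m$n_gaps)
  })
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0))
  if (filter && nrow(meas) >= 2) meas <- filter_population(meas, params)
  list(measurements = meas, records = records, labels = labels)
}

#' Population filter on per-cell measurements
#'
#' Keeps cells whose every measurement (area, intensities, roundness and the
#' three ER metrics) lies within `population_sd_limit` standard deviations
#' of the population mean. Applied in a single pass.
#'
#' @param measurements data frame of per-cell measurements.
#' @param params a [midcell_params()].
#' @return the retained subset of `measurements`.
#' @export
filter_population <- function(measurements, params = midcell_params()) {
  assert_that(nrow(measurements) >= 2, "need at least 2 cells")
  cols <- intersect(c("cell_area", "roundness", "mean_sec63", "mean_rtn1",
                      "peripheral_er_size", "er_profile_size",
                      "er_gaps_per_um"), names(measurements))
  keep <- rep(TRUE, nrow(measurements))
  for (cn in cols) {
    x <- measurements[[cn]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) next
    keep <- keep & abs(x - mean(x)) <= params$population_sd_limit * s
  }
  measurements[keep, , drop = FALSE]
}
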