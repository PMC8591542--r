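## Cortical-section ER classifier: ring-kernel two-pass feature
## segmentation per channel, then tubule / sheet / tubular-cluster
## classification by trimming-factor opening.

#' Parameters of the cortical classifier
#'
#' @param tubule_radius,sheet_radius ring-kernel radii (px) of the small-
#'   and large-feature segmentation passes; `sheet_radius` must exceed
#'   `tubule_radius`.
#' @param tubule_strength,sheet_strength minimum excess of a pixel over the
#'   mean of its surrounding ring, on the [0, 1]-normalized image.
#' @param tubule_bg,total_er_bg multipliers applied to the Otsu threshold of
#'   the curvature (Rtn1) and general (Sec63) channel, respectively.
#' @param trimming_factor disk radius (px) of the morphological opening that
#'   separates sheet-like from tubule-like features.
#' @param cluster_core_coverage minimum curvature-marker coverage of a
#'   provisional sheet's eroded core for the tubular-cluster call
#'   (default 0.5).
#' @param rolling_ball_radius background-subtraction ball radius (px,
#'   default 50).
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(tubule_radius = 2,
                              sheet_radius = 6,
                              tubule_strength = 0.02,
                              sheet_strength = 0.01,
                              tubule_bg = 1.0,
                              total_er_bg = 1.0,
                              trimming_factor = 3,
                              cluster_core_coverage = 0.5,
                              rolling_ball_radius = 50) {
  p <- structure(as.list(environment()), class = "classifier_params")
  assert_that(p$tubule_radius >= 1 && p$sheet_radius >= 1, "radii must be >= 1")
  assert_that(p$sheet_radius > p$tubule_radius,
              "sheet_radius must exceed tubule_radius")
  assert_that(p$tubule_bg > 0 && p$total_er_bg > 0, "bg multipliers must be > 0")
  assert_that(p$trimming_factor >= 0, "trimming_factor must be >= 0")
  p
}

# non-flat grey erosion/dilation with a ball structuring function,
# on a (possibly downsampled) image
ball_transform <- function(img, radius, dilate = FALSE) {
  off <- disc_offsets(radius)
  hgt <- sqrt(pmax(radius^2 - (off$dy^2 + off$dx^2), 0)) - radius  # <= 0, 0 at center
  out <- matrix(if (dilate) -Inf else Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(off))) {
    s <- shift_mat(img, off$dy[i], off$dx[i], fill = if (dilate) -Inf else Inf)
    out <- if (dilate) pmax(out, s + hgt[i]) else pmin(out, s - hgt[i])
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grey-scale opening of the image with a
#' ball structuring element of the given radius (computed on a downsampled
#' copy for large radii, as ImageJ does) and subtracts it. The result is
#' clamped to be non-negative.
#'
#' @param image 2D numeric matrix.
#' @param radius ball radius in pixels (default 50).
#' @return background-subtracted matrix, >= 0 everywhere.
#' @export
rolling_ball_background <- function(image, radius = 50) {
  image <- as.matrix(image)
  assert_that(radius >= 1, "radius must be >= 1")
  shrink <- if (radius < 16) 1L else if (radius < 32) 2L else if (radius < 64) 4L else 8L
  if (shrink > 1) {
    H <- nrow(image); W <- ncol(image)
    h2 <- ceiling(H / shrink); w2 <- ceiling(W / shrink)
    # block minimum (pad with +Inf so partial blocks are handled)
    pad <- matrix(Inf, h2 * shrink, w2 * shrink)
    pad[seq_len(H), seq_len(W)] <- image
    small <- matrix(Inf, h2, w2)
    for (dy in seq_len(shrink)) for (dx in seq_len(shrink))
      small <- pmin(small, pad[seq(dy, by = shrink, length.out = h2),
                               seq(dx, by = shrink, length.out = w2)])
    bg <- ball_transform(ball_transform(small, radius / shrink), radius / shrink,
                         dilate = TRUE)
    bg <- as.matrix(EBImage::resize(EBImage::Image(bg), w = h2 * shrink,
                                    h = w2 * shrink))[seq_len(H), seq_len(W)]
  } else {
    bg <- ball_transform(ball_transform(image, radius), radius, dilate = TRUE)
  }
  pmax(image - pmin(bg, image), 0)
}

#' Bright-field preprocessing for cell segmentation
#'
#' Gaussian blur (sigma 2) to suppress noise, 2x downscaling to suppress
#' small details, a tubeness filter (sigma 1) to highlight cell outlines,
#' then upscaling back to the original resolution.
#'
#' @param bf 2D bright-field image.
#' @return border-enhanced matrix of the same shape.
#' @export
preprocess_brightfield <- function(bf) {
  bf <- as.matrix(bf)
  H <- nrow(bf); W <- ncol(bf)
  if (diff(range(bf)) == 0) return(matrix(0, H, W))
  g <- as.matrix(EBImage::gblur(bf, sigma = 2))
  small <- as.matrix(EBImage::resize(EBImage::Image(g), w = ceiling(H / 2),
                                     h = ceiling(W / 2)))
  tb <- tubeness_filter(small, sigma = 1)
  as.matrix(EBImage::resize(EBImage::Image(tb), w = H, h = W))
}

#' Ring convolution kernel
#'
#' Binary annulus of inner radius `r` and outer radius `r + 1` (Euclidean,
#' inclusive-exclusive), normalized to sum 1 with zero center weight. If
#' the discrete annulus would hold fewer than 8 pixels it is widened by
#' half a pixel.
#'
#' @param radius inner radius in pixels, >= 1.
#' @return square numeric matrix of odd size.
#' @export
ring_kernel <- function(radius) {
  assert_that(radius >= 1, "radius must be >= 1")
  k <- ceiling(radius + 1.5)
  d <- sqrt(outer((-k:k)^2, (-k:k)^2, `+`))
  ring <- d >= radius & d < radius + 1
  if (sum(ring) < 8) ring <- d >= radius & d < radius + 1.5
  ring / sum(ring)
}

#' Ring-kernel feature segmentation of one channel
#'
#' A pixel is segmented when its 3x3-median-filtered intensity exceeds the
#' mean of the surrounding ring of radius `radius` by more than `strength`,
#' and exceeds the channel's Otsu threshold scaled by `bg_multiplier`.
#'
#' @param channel 2D image normalized to [0, 1].
#' @param radius ring radius (px).
#' @param strength ring-test margin on normalized intensities.
#' @param bg_multiplier Otsu threshold multiplier.
#' @return logical feature mask.
#' @export
feature_segment <- function(channel, radius, strength, bg_multiplier) {
  channel <- as.matrix(channel)
  if (diff(range(channel)) == 0) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  med <- as.matrix(EBImage::medianFilter(pmin(pmax(channel, 0), 1), 1))
  ringmean <- as.matrix(EBImage::filter2(med, ring_kernel(radius)))
  bg <- EBImage::otsu(EBImage::Image(pmin(pmax(channel, 0), 1))) * bg_multiplier
  (med - ringmean > strength) & (med > bg)
}

#' Two-pass segmentation of one marker channel
#'
#' A small-feature pass (tubule radius/strength) and a large-feature pass
#' (sheet radius/strength); the background multiplier is the curvature
#' channel's `tubule_bg` or the general channel's `total_er_bg`. The union
#' of the two passes is the channel's total ER mask.
#'
#' @param channel 2D image normalized to [0, 1].
#' @param params a [classifier_params()].
#' @param channel_role "general" (Sec63-like) or "curvature" (Rtn1-like).
#' @return object of class `channel_masks`: list with
#'   `small_feature_mask`, `large_feature_mask`, `total_mask`.
#' @export
segment_channel <- function(channel, params = classifier_params(),
                            channel_role = c("general", "curvature")) {
  channel_role <- match.arg(channel_role)
  bgm <- if (channel_role == "curvature") params$tubule_bg else params$total_er_bg
  small <- feature_segment(channel, params$tubule_radius,
                           params$tubule_strength, bgm)
  large <- feature_segment(channel, params$sheet_radius,
                           params$sheet_strength, bgm)
  # a feature much larger than the ring radius segments only near its rim
  # (deep interior pixels match their ring mean); fill enclosed holes.
  # Only for the general marker: the curvature marker legitimately draws
  # closed rings around sheet interiors, which must stay empty.
  if (channel_role == "general")
    large <- as.matrix(EBImage::fillHull(large * 1)) > 0
  structure(list(small_feature_mask = small, large_feature_mask = large,
                 total_mask = small | large), class = "channel_masks")
}

# binary disk opening; radius 0 is the identity
open_disc <- function(mask, radius) {
  r <- round(radius)
  if (r <= 0) return(mask)
  as.matrix(EBImage::opening(mask * 1, EBImage::makeBrush(2 * r + 1, "disc"))) > 0
}

#' Classify ER into tubules, sheets and tubular clusters
#'
#' Features of the general-marker total mask that survive a disk opening of
#' radius `trimming_factor` are provisional sheets; the remainder is
#' tubules. A provisional sheet whose interior is curvature-marker-positive
#' is sheet-like in the Rtn1 mask too, hence a dense tubular cluster: such
#' components are subtracted from the sheets and added to the tubules. A
#' genuine sheet carries the curvature marker only on its 1-2 px rim, so
#' the test uses the component's 2-px-eroded core (the whole component when
#' the core erodes away).
#'
#' @param sec63_masks,rtn1_masks `channel_masks` of the general and
#'   curvature channels from the same field.
#' @param trimming_factor opening disk radius (px).
#' @param cluster_core_coverage minimum fraction of a component core that
#'   must be curvature-positive to call a tubular cluster (default 0.5).
#' @return object of class `cortical_classification`: list with
#'   `tubule_mask`, `sheet_mask`, `cluster_mask`.
#' @export
classify_cortical <- function(sec63_masks, rtn1_masks, trimming_factor = 3,
                              cluster_core_coverage = 0.5) {
  assert_that(all(dim(sec63_masks$total_mask) == dim(rtn1_masks$total_mask)),
              "channel masks must have the same shape")
  total <- sec63_masks$total_mask
  prov_sheets <- open_disc(total, trimming_factor) & total
  tubules <- total & !prov_sheets
  rtn1_total <- rtn1_masks$total_mask
  clusters <- matrix(FALSE, nrow(total), ncol(total))
  lab <- label8(prov_sheets)
  if (max(lab) > 0) {
    core <- erode_disc(prov_sheets, 2)
    n <- max(lab)
    core_n <- tabulate(lab[core], nbins = n)
    core_pos <- tabulate(lab[core & rtn1_total], nbins = n)
    all_n <- tabulate(lab[lab > 0], nbins = n)
    all_pos <- tabulate(lab[rtn1_total & lab > 0], nbins = n)
    cov <- ifelse(core_n > 0, core_pos / core_n, all_pos / all_n)
    is_cluster <- cov >= cluster_core_coverage
    clusters <- matrix(is_cluster[pmax(lab, 1)] & lab > 0,
                       nrow(total), ncol(total))
  }
  sheets <- prov_sheets & !clusters
  structure(list(tubule_mask = tubules | clusters, sheet_mask = sheets,
                 cluster_mask = clusters), class = "cortical_classification")
}

#' Assign classified ER to cells
#'
#' @param classification a `cortical_classification`.
#' @param cell_labels integer label mask of the same shape (e.g. an external
#'   segmenter's output, the generator's truth labels, or
#'   [segment_cortical_cells()]).
#' @return data frame with one row per cell: class areas (px), cortex area
#'   and tubule/sheet/cluster fractions of the cortex. ER pixels outside any
#'   cell are ignored.
#' @export
assign_to_cells <- function(classification, cell_labels) {
  assert_that(all(dim(classification$tubule_mask) == dim(cell_labels)),
              "label mask must match the classification shape")
  ids <- setdiff(sort(unique(as.vector(cell_labels))), 0L)
  if (length(ids) == 0)
    return(data.frame(cell = integer(0), tubule_area = numeric(0),
                      sheet_area = numeric(0), cluster_area = numeric(0),
                      cortex_area = numeric(0), tubule_fraction = numeric(0),
                      sheet_fraction = numeric(0), cluster_fraction = numeric(0)))
  n <- max(ids)
  area_in <- function(mask) tabulate(cell_labels[mask & cell_labels > 0], nbins = n)[ids]
  cortex <- tabulate(cell_labels[cell_labels > 0], nbins = n)[ids]
  tub <- area_in(classification$tubule_mask)
  sh <- area_in(classification$sheet_mask)
  cl <- area_in(classification$cluster_mask)
  data.frame(cell = ids, tubule_area = tub, sheet_area = sh,
             cluster_area = cl, cortex_area = cortex,
             tubule_fraction = tub / cortex, sheet_fraction = sh / cortex,
             cluster_fraction = cl / cortex)
}

#' Population medians of the classified ER measurements
#'
#' @param per_cell one per-cell table from [assign_to_cells()] or a list of
#'   them (several fields).
#' @return named list of medians across all cells: tubule fraction, sheet
#'   fraction, cluster fraction and cluster area.
#' @export
summarize_population <- function(per_cell) {
  if (is.data.frame(per_cell)) per_cell <- list(per_cell)
  tab <- do.call(rbind, per_cell)
  assert_that(nrow(tab) >= 1, "empty cell population")
  list(median_tubule_fraction = median(tab$tubule_fraction),
       median_sheet_fraction = median(tab$sheet_fraction),
       median_cluster_fraction = median(tab$cluster_fraction),
       median_cluster_area = median(tab$cluster_area),
       n_cells = nrow(tab))
}

#' Fallback cortical cell segmenter
#'
#' Bright-field preprocessing ([preprocess_brightfield()]), Otsu
#' thresholding of the border response, then labelling of enclosed
#' interiors with a distance-transform watershed. Intended as a stand-in
#' when no external label mask is supplied.
#'
#' @param bf 2D bright-field image.
#' @param min_cell_area minimum interior size in pixels.
#' @return integer label matrix.
#' @export
segment_cortical_cells <- function(bf, min_cell_area = 150) {
  v <- normalize01(preprocess_brightfield(bf))
  if (diff(range(v)) == 0) return(matrix(0L, nrow(bf), ncol(bf)))
  border <- v > EBImage::otsu(EBImage::Image(v))
  lab <- EBImage::bwlabel(!border * 1)
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(bf), ncol(bf)))
  edge_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- setdiff(which(sizes >= min_cell_area), edge_labels)
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  out <- EBImage::watershed(EBImage::distmap(mask * 1), tolerance = 1)
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' Run the whole cortical classifier on one field
#'
#' Rolling-ball background subtraction and percentile normalization of both
#' channels, two-pass segmentation, classification, and per-cell
#' assignment.
#'
#' @param sec63,rtn1 2D images (general and curvature ER marker).
#' @param cell_labels integer label mask; if NULL and `bf` is given, the
#'   fallback segmenter is used.
#' @param params a [classifier_params()].
#' @param bf optional bright-field image for the fallback segmenter.
#' @param background_subtract logical; apply rolling-ball subtraction
#'   (default TRUE).
#' @return list with `classification`, `per_cell`, `summary`, `masks`
#'   (per-channel `channel_masks`).
#' @export
analyze_cortical_field <- function(sec63, rtn1, cell_labels = NULL,
                                   params = classifier_params(), bf = NULL,
                                   background_subtract = TRUE) {
  prep <- function(img) {
    img <- as.matrix(img)
    if (background_subtract)
      img <- rolling_ball_background(img, params$rolling_ball_radius)
    normalize01(img)
  }
  s <- prep(sec63); r <- prep(rtn1)
  if (is.null(cell_labels)) {
    assert_that(!is.null(bf), "need cell_labels or a bright-field image")
    cell_labels <- segment_cortical_cells(bf)
  }
  sm <- segment_channel(s, params, "general")
  rm_ <- segment_channel(r, params, "curvature")
  cls <- classify_cortical(sm, rm_, params$trimming_factor,
                           params$cluster_core_coverage)
  per_cell <- assign_to_cells(cls, cell_labels)
  list(classification = cls, per_cell = per_cell,
       summary = if (nrow(per_cell)) summarize_population(per_cell) else NULL,
       masks = list(sec63 = sm, rtn1 = rm_))
}
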