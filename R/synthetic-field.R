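## Synthetic field rendering.
##
## The generator emulates the study's imaging conditions: diploid-yeast-sized
## ellipsoidal cells, a peripheral ER band with gaps in mid sections, and a
## cortical tubule network plus sheet patches where the curvature marker
## labels tubules and sheet rims but not sheet interiors. Ground-truth masks
## are recorded before PSF blur and noise.

#' Place non-overlapping elliptical cells
#'
#' Rejection-samples `n_cells` ellipse-shaped cells (random orientation,
#' aspect ratio <= 1.5) inside the image, labelled 1..n. Deterministic given
#' the spec's seed.
#'
#' @param spec a [field_spec()].
#' @return integer label matrix with attribute `cells`: a data frame of
#'   per-cell geometry (id, cx, cy, a, b, theta).
#' @export
generate_cell_geometry <- function(spec) {
  validate_field_spec(spec)
  with_seed(derive_seed(spec$seed, 1L), generate_cell_geometry_impl(spec))
}

generate_cell_geometry_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  labels <- matrix(0L, H, W)
  cells <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                      a = numeric(0), b = numeric(0), theta = numeric(0))
  if (spec$n_cells == 0) { attr(labels, "cells") <- cells; return(labels) }
  max_attempts <- 300L * spec$n_cells
  attempts <- 0L
  while (nrow(cells) < spec$n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("could not place %d non-overlapping cells in a %dx%d image",
                   spec$n_cells, H, W), call. = FALSE)
    a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
    b <- a / runif(1, 1, 1.5)
    theta <- runif(1, 0, pi)
    cx <- runif(1, a + 2, W - a - 2)
    cy <- runif(1, a + 2, H - a - 2)
    if (nrow(cells) > 0) {
      dd <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(dd <= cells$a + a + 2)) next
    }
    cells <- rbind(cells, data.frame(id = nrow(cells) + 1L, cx = cx, cy = cy,
                                     a = a, b = b, theta = theta))
  }
  for (i in seq_len(nrow(cells))) {
    A <- ellipse_shape_matrix(cells$a[i], cells$b[i], cells$theta[i])
    bb <- cell_bbox(cells[i, ], H, W, margin = 2)
    rho <- ellipse_rho(c(bb$h, bb$w), c(cells$cx[i] - bb$x0 + 1,
                                        cells$cy[i] - bb$y0 + 1), A)
    sub <- labels[bb$ys, bb$xs]
    sub[rho <= 1] <- cells$id[i]
    labels[bb$ys, bb$xs] <- sub
  }
  attr(labels, "cells") <- cells
  labels
}

# crop bounding box of a cell with margin
cell_bbox <- function(cell, H, W, margin = 5) {
  x0 <- max(1L, floor(cell$cx - cell$a - margin))
  x1 <- min(W, ceiling(cell$cx + cell$a + margin))
  y0 <- max(1L, floor(cell$cy - cell$a - margin))
  y1 <- min(H, ceiling(cell$cy + cell$a + margin))
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1,
       ys = y0:y1, xs = x0:x1, h = y1 - y0 + 1, w = x1 - x0 + 1)
}

# elliptical parameter angle of every pixel in a crop, in (-pi, pi]
ellipse_param_angle <- function(dim, center, a, b, theta) {
  qy <- row(matrix(0, dim[1], dim[2])) - center[2]
  qx <- col(matrix(0, dim[1], dim[2])) - center[1]
  xr <- cos(theta) * qx + sin(theta) * qy
  yr <- -sin(theta) * qx + cos(theta) * qy
  atan2(yr / b, xr / a)
}

#' Render a synthetic mid-section field
#'
#' The cytosolic BFP fills cell interiors; both ER channels form a band of
#' thickness `tubule_width` along the cell border covering
#' `er_band_coverage` of the periphery, interrupted by `n_gaps_per_cell`
#' gaps. A z-stack of `n_slices` is rendered with focus-dependent Gaussian
#' blur; the designated in-focus slice is recorded.
#'
#' @param spec a [field_spec()] with `section = "mid"`.
#' @return object of class `synthetic_field`: list with `channels`
#'   (bf/bfp/sec63/rtn1, each height x width x n_slices), `truth_cells`,
#'   `truth_er`, `per_cell_truth`, `focus_slice`, `cells`, `spec`.
#' @export
render_mid_field <- function(spec) {
  validate_field_spec(spec)
  assert_that(spec$section == "mid", "spec$section must be 'mid'")
  labels <- generate_cell_geometry(spec)
  cells <- attr(labels, "cells")
  with_seed(derive_seed(spec$seed, 2L), render_mid_impl(spec, labels, cells))
}

render_mid_impl <- function(spec, labels, cells) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  base <- list(bf = matrix(0, H, W), bfp = matrix(0, H, W),
               sec63 = matrix(0, H, W), rtn1 = matrix(0, H, W))
  truth_er <- matrix(FALSE, H, W)
  truth_band <- matrix(FALSE, H, W)
  pct <- data.frame(cell = integer(0), coverage = numeric(0),
                    n_gaps = integer(0), band_area = numeric(0))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    A <- ellipse_shape_matrix(cl$a, cl$b, cl$theta)
    bb <- cell_bbox(cl, H, W, margin = 4)
    ctr <- c(cl$cx - bb$x0 + 1, cl$cy - bb$y0 + 1)
    rho <- ellipse_rho(c(bb$h, bb$w), ctr, A)
    band <- ellipse_radial_band(c(bb$h, bb$w), ctr, A, spec$tubule_width)
    er <- band
    g <- spec$n_gaps_per_cell
    if (spec$er_band_coverage < 1) {
      ang <- ellipse_param_angle(c(bb$h, bb$w), ctr, cl$a, cl$b, cl$theta)
      r_mean <- (cl$a + cl$b) / 2
      gap_len <- (1 - spec$er_band_coverage) * 2 * pi / g
      spacing <- 2 * pi / g
      if (r_mean * gap_len < 2 || r_mean * (spacing - gap_len) < 2)
        stop("er_band_coverage and n_gaps_per_cell jointly infeasible: ",
             "gap or covered arcs below 2 px", call. = FALSE)
      offset <- runif(1, 0, 2 * pi)
      centers <- offset + (seq_len(g) - 1) * spacing +
        runif(g, -0.4, 0.4) * (spacing - gap_len)
      for (ck in centers) {
        d <- atan2(sin(ang - ck), cos(ang - ck))   # wrapped angular distance
        er <- er & !(abs(d) < gap_len / 2)
      }
    }
    amp_er <- runif(1, 0.85, 1)
    amp_bfp <- runif(1, 0.65, 0.85)
    interior <- rho <= 1
    qd <- sqrt((col(rho) - ctr[1])^2 + (row(rho) - ctr[2])^2)
    ring <- abs(qd - qd / pmax(rho, 1e-9)) <= 1.5
    put <- function(ch, mask, val) {
      sub <- base[[ch]][bb$ys, bb$xs]; sub[mask] <- pmax(sub[mask], val)
      base[[ch]][bb$ys, bb$xs] <<- sub
    }
    put("bfp", interior, amp_bfp)
    put("sec63", er, amp_er)
    put("rtn1", er, amp_er * runif(1, 0.8, 1))
    put("bf", ring, 0.8)
    sub <- truth_er[bb$ys, bb$xs]; sub[er] <- TRUE
    truth_er[bb$ys, bb$xs] <- sub
    sub <- truth_band[bb$ys, bb$xs]; sub[band] <- TRUE
    truth_band[bb$ys, bb$xs] <- sub
    pct <- rbind(pct, data.frame(cell = cl$id, coverage = sum(er) / sum(band),
                                 n_gaps = g, band_area = sum(band)))
  }
  st <- render_stack(base, spec)
  structure(list(channels = st$channels, truth_cells = labels,
                 truth_er = truth_er, truth_band = truth_band,
                 truth_tubules = truth_er,
                 truth_sheets = matrix(FALSE, H, W),
                 per_cell_truth = pct, focus_slice = st$focus,
                 cells = cells, spec = spec),
            class = "synthetic_field")
}

#' Render a synthetic cortical-section field
#'
#' Per cell, a tubule network (dilated persistent random walks) and smoothed
#' sheet patches are placed to match the spec's target cortex fractions.
#' The general ER channel carries tubules, sheets and clusters; the
#' curvature channel carries tubules, a 1-2 px sheet rim (not sheet
#' interiors) and the full extent of dense tubular clusters.
#'
#' @param spec a [field_spec()] with `section = "cortical"`.
#' @return `synthetic_field` with `truth_tubules`, `truth_sheets`,
#'   `truth_clusters` masks and `per_cell_truth` fractions.
#' @export
render_cortical_field <- function(spec) {
  validate_field_spec(spec)
  assert_that(spec$section == "cortical", "spec$section must be 'cortical'")
  labels <- generate_cell_geometry(spec)
  cells <- attr(labels, "cells")
  with_seed(derive_seed(spec$seed, 2L), render_cortical_impl(spec, labels, cells))
}

render_cortical_impl <- function(spec, labels, cells) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  base <- list(bf = matrix(0, H, W), bfp = matrix(0, H, W),
               sec63 = matrix(0, H, W), rtn1 = matrix(0, H, W))
  truth <- list(tub = matrix(FALSE, H, W), sheet = matrix(FALSE, H, W),
                clus = matrix(FALSE, H, W))
  pct <- data.frame(cell = integer(0), tubule_fraction = numeric(0),
                    sheet_fraction = numeric(0), cluster_fraction = numeric(0),
                    cortex_area = numeric(0))
  cell_seeds <- sample.int(2147483646L, max(1, nrow(cells)))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    res <- with_seed(cell_seeds[i], render_cortical_cell(spec, cl, H, W))
    bb <- res$bb
    paint <- function(full, crop) { s <- full[bb$ys, bb$xs]; s[crop] <- TRUE; full[bb$ys, bb$xs] <- s; full }
    truth$tub <- paint(truth$tub, res$tubules)
    truth$sheet <- paint(truth$sheet, res$sheets)
    truth$clus <- paint(truth$clus, res$clusters)
    put <- function(ch, mask, val) {
      sub <- base[[ch]][bb$ys, bb$xs]; sub[mask] <- pmax(sub[mask], val)
      base[[ch]][bb$ys, bb$xs] <<- sub
    }
    put("sec63", res$tubules | res$sheets | res$clusters, res$amp)
    put("rtn1", res$tubules | res$rim | res$clusters, res$amp * 0.9)
    put("bfp", res$interior, 0.4)
    put("bf", res$ring, 0.8)
    pct <- rbind(pct, data.frame(
      cell = cl$id,
      tubule_fraction = sum(res$tubules) / res$cortex_area,
      sheet_fraction = sum(res$sheets) / res$cortex_area,
      cluster_fraction = sum(res$clusters) / res$cortex_area,
      cortex_area = res$cortex_area))
  }
  st <- render_stack(base, spec)
  structure(list(channels = st$channels, truth_cells = labels,
                 truth_tubules = truth$tub, truth_sheets = truth$sheet,
                 truth_clusters = truth$clus,
                 per_cell_truth = pct, focus_slice = st$focus,
                 cells = cells, spec = spec),
            class = "synthetic_field")
}

# place sheet-like blobs into `free` cortex until `target` fraction reached
place_blobs <- function(cortex, avoid, target, cortex_area, dim, what) {
  out <- matrix(FALSE, dim[1], dim[2])
  if (target <= 0) return(out)
  attempts <- 0L
  max_attempts <- 600L
  while (sum(out) / cortex_area < target - 0.02 && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx_ok <- which(cortex & !avoid & !out)
    if (length(idx_ok) == 0) break
    remaining <- (target - sum(out) / cortex_area) * cortex_area
    r1 <- min(9, max(3.5, sqrt(remaining / pi)))
    r2 <- r1 / runif(1, 1, 1.4)
    th <- runif(1, 0, pi)
    p <- idx_ok[sample.int(length(idx_ok), 1)]
    cy <- (p - 1) %% dim[1] + 1; cx <- (p - 1) %/% dim[1] + 1
    A <- ellipse_shape_matrix(r1, r2, th)
    blob <- ellipse_interior(dim, c(cx, cy), A) & cortex
    # tolerate more overlap with already-placed blobs as packing tightens
    allow <- 0.1 + 0.5 * attempts / max_attempts
    if (sum(blob & (avoid | out)) > allow * sum(blob)) next
    if ((sum(out | blob)) / cortex_area > target + 0.05) next
    out <- out | (blob & !avoid)
  }
  if (sum(out) / cortex_area < target - 0.05)
    stop(sprintf("infeasible %s fraction target %.2f within cell", what, target),
         call. = FALSE)
  out
}

render_cortical_cell <- function(spec, cl, H, W) {
  bb <- cell_bbox(cl, H, W, margin = 4)
  dim <- c(bb$h, bb$w)
  ctr <- c(cl$cx - bb$x0 + 1, cl$cy - bb$y0 + 1)
  A <- ellipse_shape_matrix(cl$a, cl$b, cl$theta)
  rho <- ellipse_rho(dim, ctr, A)
  interior <- rho <= 1
  cortex <- rho <= 0.95
  cortex_area <- sum(cortex)
  qd <- sqrt((col(rho) - ctr[1])^2 + (row(rho) - ctr[2])^2)
  ring <- abs(qd - qd / pmax(rho, 1e-9)) <= 1.5
  w <- spec$tubule_width

  sheets <- place_blobs(cortex, matrix(FALSE, dim[1], dim[2]),
                        spec$target_sheet_fraction, cortex_area, dim, "sheet")
  clusters <- place_blobs(cortex, sheets, spec$target_cluster_fraction,
                          cortex_area, dim, "cluster")
  blocked <- dilate_disc(sheets | clusters, 1)

  # tubules: persistent random walks, dilated to width w
  skel <- matrix(FALSE, dim[1], dim[2])
  tubules <- matrix(FALSE, dim[1], dim[2])
  target_t <- spec$target_tubule_fraction
  if (target_t > 0) {
    allowed <- cortex & !blocked
    idx_ok <- which(allowed)
    assert_that(length(idx_ok) > 10,
                "infeasible fraction targets: no cortex left for tubules")
    walks <- 0L
    while (sum(tubules) / cortex_area < target_t - 0.02 && walks < 250L) {
      walks <- walks + 1L
      remaining <- (target_t - sum(tubules) / cortex_area) * cortex_area
      max_len <- max(8, min(3 * cl$a, ceiling(remaining / w)))
      p <- idx_ok[sample.int(length(idx_ok), 1)]
      y <- (p - 1) %% dim[1] + 1; x <- (p - 1) %/% dim[1] + 1
      phi <- runif(1, 0, 2 * pi)
      for (s in seq_len(max_len)) {
        yi <- round(y); xi <- round(x)
        if (yi < 1 || xi < 1 || yi > dim[1] || xi > dim[2] || !allowed[yi, xi]) break
        skel[yi, xi] <- TRUE
        x <- x + cos(phi); y <- y + sin(phi)
        phi <- phi + rnorm(1, 0, 0.25)
      }
      tubules <- dilate_disc(skel, w / 2) & cortex & !sheets & !clusters
    }
    if (sum(tubules) / cortex_area < target_t - 0.05)
      stop(sprintf("infeasible tubule fraction target %.2f within cell", target_t),
           call. = FALSE)
  }
  rim <- sheets & !erode_disc(sheets, 1.6)
  list(bb = bb, interior = interior, ring = ring, cortex_area = cortex_area,
       tubules = tubules, sheets = sheets, clusters = clusters, rim = rim,
       amp = runif(1, 0.85, 1))
}

# assemble z-stacks with focus-dependent blur, then apply the noise model
# and normalize each channel stack to [0, 1]
render_stack <- function(base, spec) {
  n <- spec$n_slices
  focus <- (n + 1L) %/% 2L
  channels <- lapply(base, function(img) {
    H <- nrow(img); W <- ncol(img)
    st <- array(0, c(H, W, n))
    for (j in seq_len(n)) {
      defocus <- abs(j - focus) * spec$slice_spacing
      sigma <- spec$psf_sigma + 1.5 * defocus
      sl <- if (sigma > 0) as.matrix(EBImage::gblur(img, sigma)) else img
      sl <- sl / (1 + 0.3 * defocus)
      if (spec$noise$poisson_scale > 0) {
        sc <- spec$noise$poisson_scale
        sl <- matrix(rpois(length(sl), pmax(sl, 0) * sc) / sc, H, W)
      }
      if (spec$noise$gaussian_sd > 0)
        sl <- sl + rnorm(length(sl), 0, spec$noise$gaussian_sd)
      st[, , j] <- pmax(sl, 0)
    }
    mx <- max(st)
    if (mx > 0) st <- st / mx
    st
  })
  list(channels = channels, focus = focus)
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("synthetic_field: %s section, %d cells, %d slice(s), focus slice %d\n",
              x$spec$section, nrow(x$cells), x$spec$n_slices, x$focus_slice))
  invisible(x)
}
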