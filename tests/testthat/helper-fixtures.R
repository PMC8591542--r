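# Shared fixtures: constructed periphery-band cell records, a brute-force
# minimum-ellipse oracle, and small field specs.

# A circular cell record with an exactly constructed periphery band.
# Returns the record plus ER masks whose band coverage is known by
# construction: a full ring, and two opposite arcs of exactly 1/4 of the
# band pixels each.
make_band_fixture <- function() {
  # pick a radius whose discrete band pixel count is divisible by 4
  for (R in 20:40) {
    dim <- c(2 * R + 11, 2 * R + 11)
    ctr <- c(R + 6, R + 6)
    A <- diag(2) / R^2
    band <- ermorph:::ellipse_radial_band(dim, ctr, A, 5)
    if (sum(band) %% 4 == 0) break
  }
  ell <- structure(list(center = ctr, A = A, axes = c(R, R), angle = 0,
                        area = pi * R^2), class = "mve")
  cell <- structure(list(label = 1L, border_ellipse = ell,
                         periphery_band = band), class = "cell_record")
  # order band pixels by angle; two arcs of exactly n/4 pixels each
  idx <- which(band)
  ang <- atan2(row(band)[idx] - ctr[2], col(band)[idx] - ctr[1])
  ord <- idx[order(ang)]
  n <- length(ord)
  arcs <- matrix(FALSE, dim[1], dim[2])
  arcs[ord[1:(n / 4)]] <- TRUE
  arcs[ord[(n / 2 + 1):(3 * n / 4)]] <- TRUE
  list(cell = cell, full = band, arcs = arcs,
       empty = matrix(FALSE, dim[1], dim[2]), n_band = n)
}

# Independent minimum-enclosing-ellipse search: penalized Nelder-Mead over
# (center, Cholesky factor of the shape matrix), multi-start. Used as the
# oracle against the Khachiyan implementation.
brute_force_mve_area <- function(points, n_starts = 4) {
  pts <- as.matrix(points)
  obj <- function(par) {
    c0 <- par[1:2]
    L <- matrix(c(par[3], par[4], 0, par[5]), 2, 2)
    M <- L %*% t(L)
    q <- rowSums((sweep(pts, 2, c0) %*% M) * sweep(pts, 2, c0))
    area <- pi / sqrt(max(det(M), 1e-12))
    log(area) + 1e5 * sum(pmax(q - 1, 0)^2)
  }
  ctr <- colMeans(pts)
  r0 <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) * 1.05
  best <- Inf
  for (s in seq_len(n_starts)) {
    sc <- 1 / (r0 * (1 + 0.3 * (s - 1)))
    fit <- optim(c(ctr, sc, 0, sc), obj,
                 control = list(maxit = 4000, reltol = 1e-12))
    # accept only feasible solutions (all points enclosed up to 0.1%)
    L <- matrix(c(fit$par[3], fit$par[4], 0, fit$par[5]), 2, 2)
    M <- L %*% t(L)
    q <- rowSums((sweep(pts, 2, fit$par[1:2]) %*% M) * sweep(pts, 2, fit$par[1:2]))
    if (max(q) <= 1.002) best <- min(best, pi / sqrt(det(M)))
  }
  best
}

small_mid_spec <- function(seed = 1, ...) {
  field_spec(section = "mid", image_size = c(192, 192), n_cells = 4,
             seed = seed, ...)
}

small_cortical_spec <- function(seed = 1, ...) {
  field_spec(section = "cortical", image_size = c(192, 192), n_cells = 4,
             n_slices = 1, seed = seed, ...)
}
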