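## Hessian-based ridge enhancement.
##
## Both the mid-section border detector and the ER segmentation rest on
## Frangi-style vesselness: bright curvilinear structures (cell outlines,
## ER tubules) produce one strongly negative Hessian eigenvalue across the
## ridge and a near-zero one along it.

# Gaussian and Gaussian-derivative kernels, gamma-normalized by sigma^2 so
# responses are comparable across scales
gauss_deriv_kernels <- function(sigma) {
  k <- max(2L, ceiling(3 * sigma))
  x <- -k:k
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  gx <- outer(g, g)                         # smoothing
  d2 <- (x^2 - sigma^2) / sigma^4 * g       # second derivative of gaussian
  d1 <- -x / sigma^2 * g                    # first derivative
  list(
    xx = sigma^2 * outer(g, d2),
    yy = sigma^2 * outer(d2, g),
    xy = sigma^2 * outer(d1, d1)
  )
}

# Hessian components at scale sigma (rows = y, cols = x)
hessian_at_scale <- function(img, sigma) {
  ker <- gauss_deriv_kernels(sigma)
  list(
    xx = as.matrix(EBImage::filter2(img, ker$xx)),
    yy = as.matrix(EBImage::filter2(img, ker$yy)),
    xy = as.matrix(EBImage::filter2(img, ker$xy))
  )
}

# eigenvalues of the 2x2 Hessian field, ordered |l1| <= |l2|
hessian_eigen <- function(h) {
  tr <- h$xx + h$yy
  disc <- sqrt(pmax((h$xx - h$yy)^2 + 4 * h$xy^2, 0))
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  list(l1 = matrix(l1, nrow(h$xx)), l2 = matrix(l2, nrow(h$xx)))
}

#' Frangi vesselness filter
#'
#' Multi-scale Hessian eigenvalue filter enhancing bright curvilinear
#' structures such as cell borders and ER tubules.
#'
#' @param img 2D numeric matrix.
#' @param scales numeric vector of Gaussian scales (pixels).
#' @param beta blob-ness sensitivity (default 0.5).
#' @param c structure-ness sensitivity; default half the maximum Hessian norm
#'   at each scale.
#' @return matrix of vesselness responses in [0, 1] (maximum over scales).
#' @export
#' @examples
#' m <- matrix(0, 32, 32); m[16, ] <- 1
#' v <- frangi_filter(m, scales = c(1, 2))
#' which.max(rowSums(v)) # ridge row
frangi_filter <- function(img, scales = c(1, 1.5, 2), beta = 0.5, c = NULL) {
  img <- as.matrix(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    ev <- hessian_eigen(hessian_at_scale(img, s))
    S <- sqrt(ev$l1^2 + ev$l2^2)
    cs <- if (is.null(c)) max(S) / 2 else c
    if (cs <= 0) next
    rb2 <- (ev$l1 / ifelse(ev$l2 == 0, .Machine$double.eps, ev$l2))^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cs^2)))
    v[ev$l2 > 0] <- 0                       # bright ridges only
    out <- pmax(out, v)
  }
  out
}

#' Tubeness filter
#'
#' Single- or multi-scale curvilinear enhancement: the magnitude of the
#' negative principal Hessian eigenvalue (bright ridges), gamma-normalized.
#'
#' @param img 2D numeric matrix.
#' @param sigma Gaussian scale(s) in pixels.
#' @return matrix of non-negative tubeness responses (max over scales).
#' @export
tubeness_filter <- function(img, sigma = 1) {
  img <- as.matrix(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (s in sigma) {
    ev <- hessian_eigen(hessian_at_scale(img, s))
    lmin <- pmin(ev$l1, ev$l2)
    out <- pmax(out, pmax(-lmin, 0))
  }
  out
}
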