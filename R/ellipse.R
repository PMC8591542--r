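## Minimum-volume enclosing ellipse (Khachiyan's algorithm) and ellipse
## geometry helpers. The refined cell border is the smallest ellipse
## enclosing the segmented ER pixels, so this primitive is load-bearing.

#' Minimum-volume enclosing ellipse
#'
#' Computes the smallest-area ellipse containing a 2D point set by
#' Khachiyan's barycentric coordinate-ascent. The ellipse is represented as
#' \{x : (x - center)' A (x - center) <= 1\}.
#'
#' @param points numeric matrix (n x 2) of (x, y) coordinates, n >= 3,
#'   not all collinear.
#' @param tolerance convergence tolerance on the barycentric step
#'   (default 1e-3); points lie inside the ellipse up to a relative margin
#'   of the same order.
#' @param max_iter iteration cap.
#' @return object of class `mve`: list with `center` (length 2), `A`
#'   (2 x 2 shape matrix), `axes` (semi-axes, decreasing), `angle`
#'   (orientation of the major axis, radians), `area`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' e <- min_volume_ellipse(cbind(cos(th), sin(th)))
#' e$axes # ~ c(1, 1)
min_volume_ellipse <- function(points, tolerance = 1e-3, max_iter = 50000) {
  P <- as.matrix(points)
  assert_that(ncol(P) == 2, "points must be an n x 2 matrix")
  P <- P[complete.cases(P), , drop = FALSE]
  n <- nrow(P)
  assert_that(n >= 3, "need at least 3 points")
  ctr <- sweep(P, 2, colMeans(P))
  assert_that(qr(ctr)$rank >= 2, "points are collinear or degenerate")

  d <- 2
  Q <- t(cbind(P, 1))                      # (d+1) x n
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))                  # (d+1) x (d+1)
    M <- colSums(Q * solve(X, Q))          # Mahalanobis distances
    j <- which.max(M)
    if ((M[j] - d - 1) / (d + 1) < tolerance) break
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  center <- drop(t(P) %*% u)
  S <- t(P) %*% (u * P) - tcrossprod(center)
  A <- solve(S) / d
  # scale minimally so every point is enclosed despite finite iteration
  ctr2 <- sweep(P, 2, center)
  qmax <- max(rowSums((ctr2 %*% A) * ctr2))
  if (qmax > 1) A <- A / qmax
  ev <- eigen(A, symmetric = TRUE)
  axes <- 1 / sqrt(ev$values)              # increasing A eigenvalue = short axis
  ord <- order(axes, decreasing = TRUE)
  axes <- axes[ord]
  major <- ev$vectors[, ord[1]]
  structure(list(
    center = center, A = A, axes = axes,
    angle = atan2(major[2], major[1]),
    area = pi * axes[1] * axes[2]
  ), class = "mve")
}

#' @export
print.mve <- function(x, ...) {
  cat(sprintf("minimum-volume ellipse: center (%.2f, %.2f), axes %.2f x %.2f, angle %.1f deg\n",
              x$center[1], x$center[2], x$axes[1], x$axes[2], x$angle * 180 / pi))
  invisible(x)
}

# shape matrix for an ellipse given semi-axes (a >= b) and orientation
ellipse_shape_matrix <- function(a, b, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  R %*% diag(1 / c(a^2, b^2)) %*% t(R)
}

#' Ramanujan approximation to the ellipse perimeter
#' @param a,b semi-axes.
#' @return perimeter length (same units as the axes).
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Pixel masks derived from an ellipse on an image grid (rows = y, cols = x).
# ellipse_rho: normalized elliptical radius per pixel (1 on the boundary).
ellipse_rho <- function(dim, center, A) {
  qy <- row(matrix(0, dim[1], dim[2])) - center[2]
  qx <- col(matrix(0, dim[1], dim[2])) - center[1]
  sqrt(pmax(A[1, 1] * qx^2 + 2 * A[1, 2] * qx * qy + A[2, 2] * qy^2, 0))
}

# band of constant radial (along-ray) width just inside the ellipse:
# pixels with rho <= 1 whose distance to the boundary along their ray is
# <= width, i.e. |q| * (1/rho - 1) <= width
ellipse_radial_band <- function(dim, center, A, width) {
  qy <- row(matrix(0, dim[1], dim[2])) - center[2]
  qx <- col(matrix(0, dim[1], dim[2])) - center[1]
  rho <- sqrt(pmax(A[1, 1] * qx^2 + 2 * A[1, 2] * qx * qy + A[2, 2] * qy^2, 0))
  d <- sqrt(qx^2 + qy^2)
  rho <= 1 & rho > 0 & d * (1 / rho - 1) <= width
}

# interior mask of an ellipse
ellipse_interior <- function(dim, center, A) ellipse_rho(dim, center, A) <= 1
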