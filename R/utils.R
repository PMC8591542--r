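#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Percentile stretch to [0, 1]
#'
#' Linear rescaling between the `lo` and `hi` percentiles, clamped to [0, 1].
#' Constant images map to all zeros.
#'
#' @param x numeric matrix.
#' @param lo,hi percentiles in [0, 100].
#' @return matrix with values in [0, 1].
#' @export
normalize01 <- function(x, lo = 0.1, hi = 99.9) {
  q <- quantile(x, c(lo, hi) / 100, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) return(x * 0)
  y <- (x - q[1]) / (q[2] - q[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

# integer offsets (dy, dx) within Euclidean distance r of the origin
disc_offsets <- function(r) {
  k <- ceiling(r)
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g[sqrt(g$dy^2 + g$dx^2) <= r, , drop = FALSE]
}

# shift a matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) < 1 || length(xs) < 1) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# binary dilation by Euclidean disc of radius r (pure shifts; r small)
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- disc_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (off$dy[i] == 0 && off$dx[i] == 0) next
    out <- out | shift_mat(mask, off$dy[i], off$dx[i], FALSE)
  }
  out
}

erode_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  !dilate_disc(!mask, r)
}

#' 8-connected component labelling
#'
#' EBImage's `bwlabel` uses 4-connectivity; ER profiles and gaps are counted
#' with 8-connectivity, so diagonal touches must merge.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label8 <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2) return(lab)
  # union-find over diagonally adjacent label pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pairs <- NULL
  for (d in list(c(1, 1), c(1, -1))) {
    s <- shift_mat(lab, d[1], d[2], 0)
    sel <- lab > 0 & s > 0 & lab != s
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(lab[sel], s[sel])))
  }
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, unique(roots))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Count 8-connected components of a mask
#' @param mask logical matrix.
#' @return integer component count.
#' @keywords internal
count_components8 <- function(mask) {
  if (!any(mask)) return(0L)
  max(label8(mask))
}

# sizes of 8-connected components, in pixels
component_sizes8 <- function(mask) {
  lab <- label8(mask)
  if (max(lab) == 0) return(integer(0))
  tabulate(lab[lab > 0])
}

# stop unless condition holds
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
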