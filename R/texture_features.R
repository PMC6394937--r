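#' Canonical names of the 14 GLCM texture features
#' @export
glcm_feature_names <- c(
  "Autocorrelation", "Contrast", "Correlation", "ClusterProminence",
  "ClusterShade", "Dissimilarity", "Energy", "Entropy", "Homogeneity",
  "DifferenceVariance", "DifferenceEntropy",
  "InformationMeasureOfCorrelation",
  "InverseDifferenceNormalized", "InverseDifferenceMoment"
)

#' Quantize a lesion to a reduced gray-level image
#'
#' Maps 8-bit gray values to `levels` bins by `floor(value * levels / 256)`,
#' a monotone non-decreasing mapping with equal-width bins (for the default
#' 8 levels, 32 gray values per bin). Only in-mask pixels carry levels;
#' everything outside the lesion is `NA`.
#'
#' @param image Integer gray-level matrix in \[0, 255\].
#' @param mask Logical lesion mask of matching dimensions.
#' @param levels Number of gray levels G (default 8).
#' @return A list with elements `levels` (integer matrix, `NA` outside the
#'   mask), `n_levels`, `mask`; class `"quantized_roi"`.
#' @export
quantize_roi <- function(image, mask, levels = 8L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("need at least 2 gray levels", call. = FALSE)
  if (!identical(dim(image), dim(mask))) {
    stop("image/mask dimension mismatch", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  q <- (image * levels) %/% 256L
  q[!mask] <- NA_integer_
  structure(list(levels = q, n_levels = levels, mask = mask),
            class = "quantized_roi")
}

# (row, col) offset of the neighbor for each direction, at distance d
.glcm_offset <- function(theta, d) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("direction must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  )
}

#' Build a directed gray-level co-occurrence matrix
#'
#' Counts pairs of quantized levels `(i, j)` at pixel offset `d` along
#' direction `theta` (degrees: 0, 45, 90 or 135). A pair contributes only
#' when both pixels lie inside the lesion mask, so background never leaks
#' into the texture statistics. Counting is symmetric — each pair increments
#' both `(i, j)` and `(j, i)` — which makes the marginals well defined; the
#' probability matrix is the count matrix normalized to sum 1.
#'
#' @param q A `"quantized_roi"` from [quantize_roi()].
#' @param d Pixel distance (default 1, capturing fine lesion detail).
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @return A list with `counts`, `probs` (G x G), `d`, `theta`, `n_levels`;
#'   class `"glcm"`.
#' @export
build_glcm <- function(q, d = 1L, theta) {
  stopifnot(inherits(q, "quantized_roi"))
  d <- as.integer(d)
  if (d < 1L) stop("distance d must be >= 1", call. = FALSE)
  off <- .glcm_offset(theta, d)
  G <- q$n_levels
  lv <- q$levels
  nr <- nrow(lv); nc <- ncol(lv)

  # source window rows/cols such that the offset target stays in the frame
  r0 <- max(1L, 1L - off[1]); r1 <- min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(nc, nc - off[2])
  if (r0 > r1 || c0 > c1) {
    stop("ROI has no valid ", theta, "-degree pixel pair at distance ", d,
         call. = FALSE)
  }
  a <- lv[r0:r1, c0:c1, drop = FALSE]
  b <- lv[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]),
          drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) {
    stop("ROI has no valid ", theta, "-degree pixel pair at distance ", d,
         call. = FALSE)
  }
  i <- a[keep]; j <- b[keep]
  counts <- matrix(tabulate(i * G + j + 1L, nbins = G * G),
                   nrow = G, ncol = G, byrow = TRUE)
  counts <- counts + t(counts)
  structure(
    list(counts = counts, probs = counts / sum(counts),
         d = d, theta = theta, n_levels = G),
    class = "glcm"
  )
}

#' The 14 co-occurrence texture statistics
#'
#' Computes, from one normalized GLCM `p(i, j)` over levels `0..G-1` with
#' marginals `px`, `py` (means `mux`, `muy`, standard deviations `sx`, `sy`)
#' and gray-level-difference distribution `pd(k) = sum_{|i-j|=k} p(i,j)`:
#'
#' * Autocorrelation `sum i*j*p`; Contrast `sum (i-j)^2*p`;
#'   Correlation `(sum i*j*p - mux*muy) / (sx*sy)`;
#' * ClusterShade and ClusterProminence, the third and fourth moments of
#'   `i + j` about `mux + muy`;
#' * Dissimilarity `sum |i-j|*p`; Energy `sum p^2`;
#'   Entropy `-sum p*log(p)` (with `0*log 0 = 0`);
#'   Homogeneity `sum p / (1 + |i-j|)`;
#' * DifferenceVariance and DifferenceEntropy, the variance and entropy of
#'   `pd`;
#' * InformationMeasureOfCorrelation, the first information-theoretic
#'   measure `(HXY - HXY1) / max(HX, HY)`;
#' * the normalized inverse-difference forms
#'   `sum p / (1 + |i-j|/G)` (InverseDifferenceNormalized) and
#'   `sum p / (1 + (i-j)^2/G^2)` (InverseDifferenceMoment).
#'
#' Correlation and InformationMeasureOfCorrelation are undefined (`NA`) when
#' a marginal standard deviation is zero, i.e. for a constant region.
#'
#' @param P A `"glcm"` from [build_glcm()], or a normalized square
#'   probability matrix.
#' @param base Logarithm base for the entropies; natural log by default.
#' @return Named numeric vector of length 14 (names `glcm_feature_names`).
#' @export
texture_statistics <- function(P, base = exp(1)) {
  p <- if (inherits(P, "glcm")) P$probs else as.matrix(P)
  G <- nrow(p)
  if (ncol(p) != G) stop("GLCM must be square", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("GLCM must be normalized to sum 1", call. = FALSE)
  }
  lg <- function(x) log(x, base = base)
  lev <- 0:(G - 1)
  I <- matrix(lev, G, G)          # row level i
  J <- t(I)                       # col level j

  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px))
  sy <- sqrt(sum((lev - muy)^2 * py))

  autoc <- sum(I * J * p)
  contrast <- sum((I - J)^2 * p)
  correlation <- if (sx * sy > 0) (autoc - mux * muy) / (sx * sy) else NA_real_
  cshade <- sum((I + J - mux - muy)^3 * p)
  cprom <- sum((I + J - mux - muy)^4 * p)
  dissim <- sum(abs(I - J) * p)
  energy <- sum(p^2)
  entropy <- -sum(p[p > 0] * lg(p[p > 0]))
  homog <- sum(p / (1 + abs(I - J)))

  # gray-level difference distribution p_{x-y}
  k <- lev
  pd <- vapply(k, function(kk) sum(p[abs(I - J) == kk]), numeric(1))
  mud <- sum(k * pd)
  dvar <- sum((k - mud)^2 * pd)
  dent <- -sum(pd[pd > 0] * lg(pd[pd > 0]))

  hxy <- entropy
  hx <- -sum(px[px > 0] * lg(px[px > 0]))
  hy <- -sum(py[py > 0] * lg(py[py > 0]))
  pxpy <- outer(px, py)
  nz <- p > 0
  hxy1 <- -sum(p[nz] * lg(pxpy[nz]))
  imc <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_

  idn <- sum(p / (1 + abs(I - J) / G))
  idm <- sum(p / (1 + (I - J)^2 / G^2))

  out <- c(autoc, contrast, correlation, cprom, cshade, dissim, energy,
           entropy, homog, dvar, dent, imc, idn, idm)
  names(out) <- glcm_feature_names
  out
}

#' Average texture vectors over the four directions
#'
#' The four directed co-occurrence matrices (0, 45, 90, 135 degrees) each
#' yield a statistics vector; the lesion descriptor is their element-wise
#' arithmetic mean. Undefined (`NA`) entries propagate to the mean.
#'
#' @param vectors List of exactly 4 named texture vectors.
#' @return Named numeric vector of length 14.
#' @export
mean_over_directions <- function(vectors) {
  if (length(vectors) != 4L) {
    stop("expected texture vectors for exactly the 4 directions, got ",
         length(vectors), call. = FALSE)
  }
  m <- do.call(rbind, vectors)
  if (!identical(colnames(m), glcm_feature_names)) {
    stop("texture vectors must carry the 14 canonical feature names",
         call. = FALSE)
  }
  colMeans(m)
}

#' Directional-mean GLCM features of a lesion
#'
#' Convenience wrapper: quantize the masked lesion, build the four directed
#' GLCMs at distance `d`, compute the 14 statistics per direction and average
#' them.
#'
#' @inheritParams quantize_roi
#' @inheritParams build_glcm
#' @inheritParams texture_statistics
#' @return Named numeric vector of length 14.
#' @export
glcm_features <- function(image, mask, levels = 8L, d = 1L, base = exp(1)) {
  q <- quantize_roi(image, mask, levels)
  vecs <- lapply(c(0, 45, 90, 135), function(th) {
    texture_statistics(build_glcm(q, d = d, theta = th), base = base)
  })
  mean_over_directions(vecs)
}
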