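# Independent oracles used across the suite. Each is implemented by a
# different route than the package code it checks.

# Point-in-polygon by winding angle (package uses even-odd ray casting).
# Vertices in pixel coordinates; polygon through pixel centers (v + 0.5).
# Points on the boundary count as inside, matching the rasterizer contract.
oracle_point_in_polygon <- function(point_rc, vertices) {
  py <- vertices[, 1] + 0.5
  px <- vertices[, 2] + 0.5
  y <- point_rc[1]; x <- point_rc[2]
  n <- length(py)
  eps <- 1e-9
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ay <- py[i] - y; ax <- px[i] - x
    by <- py[j] - y; bx <- px[j] - x
    # on-segment check
    dy <- py[j] - py[i]; dx <- px[j] - px[i]
    len2 <- dy^2 + dx^2
    if (len2 > 0) {
      cross <- dx * (y - py[i]) - dy * (x - px[i])
      tpar <- (dy * (y - py[i]) + dx * (x - px[i])) / len2
      if (abs(cross) < eps * sqrt(len2) && tpar >= -eps && tpar <= 1 + eps) {
        return(TRUE)
      }
    }
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(total) > pi   # winding number nonzero
}

oracle_rasterize <- function(vertices, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
    m[r, c] <- oracle_point_in_polygon(c(r - 0.5, c - 0.5), vertices)
  }
  m
}

# Brute-force symmetric GLCM: explicit double loop over every pixel.
oracle_glcm_counts <- function(levels_mat, G, d, theta) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0L, G, G)
  nr <- nrow(levels_mat); nc <- ncol(levels_mat)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- levels_mat[r, c]
    if (is.na(i)) next
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    j <- levels_mat[r2, c2]
    if (is.na(j)) next
    counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1L
    counts[j + 1, i + 1] <- counts[j + 1, i + 1] + 1L
  }
  counts
}

# Naive texture statistics: scalar double loops, no vectorization shared
# with the package implementation.
oracle_texture <- function(p) {
  G <- nrow(p)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:G) {
    sx2 <- sx2 + (i - 1 - mux)^2 * px[i]
    sy2 <- sy2 + (i - 1 - muy)^2 * py[i]
  }
  autoc <- 0; contrast <- 0; cshade <- 0; cprom <- 0; dissim <- 0
  energy <- 0; entropy <- 0; homog <- 0; idn <- 0; idm <- 0; hxy1 <- 0
  pd <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]; ii <- i - 1; jj <- j - 1
    autoc <- autoc + ii * jj * v
    contrast <- contrast + (ii - jj)^2 * v
    cshade <- cshade + (ii + jj - mux - muy)^3 * v
    cprom <- cprom + (ii + jj - mux - muy)^4 * v
    dissim <- dissim + abs(ii - jj) * v
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log(v)
    homog <- homog + v / (1 + abs(ii - jj))
    idn <- idn + v / (1 + abs(ii - jj) / G)
    idm <- idm + v / (1 + (ii - jj)^2 / G^2)
    if (v > 0) hxy1 <- hxy1 - v * log(px[i] * py[j])
    pd[abs(ii - jj) + 1] <- pd[abs(ii - jj) + 1] + v
  }
  mud <- 0
  for (k in 1:G) mud <- mud + (k - 1) * pd[k]
  dvar <- 0; dent <- 0
  for (k in 1:G) {
    dvar <- dvar + (k - 1 - mud)^2 * pd[k]
    if (pd[k] > 0) dent <- dent - pd[k] * log(pd[k])
  }
  hx <- 0; hy <- 0
  for (i in 1:G) {
    if (px[i] > 0) hx <- hx - px[i] * log(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log(py[i])
  }
  corr <- if (sx2 * sy2 > 0) (autoc - mux * muy) / sqrt(sx2 * sy2) else NA
  imc <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else NA
  c(Autocorrelation = autoc, Contrast = contrast, Correlation = corr,
    ClusterProminence = cprom, ClusterShade = cshade,
    Dissimilarity = dissim, Energy = energy, Entropy = entropy,
    Homogeneity = homog, DifferenceVariance = dvar,
    DifferenceEntropy = dent, InformationMeasureOfCorrelation = imc,
    InverseDifferenceNormalized = idn, InverseDifferenceMoment = idm)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank splits.
oracle_mw_enumeration <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Az as the tie-corrected all-pairs Mann-Whitney statistic.
oracle_az_pairs <- function(scores, truths) {
  s1 <- scores[truths == "tear"]
  s0 <- scores[truths == "tendinopathy"]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random masked quantized ROI for GLCM oracle checks
random_quantized_roi <- function(dim_px = 16L, G = 8L, mask_p = 0.7) {
  img <- matrix(sample(0:255, dim_px * dim_px, replace = TRUE),
                dim_px, dim_px)
  mask <- matrix(stats::runif(dim_px * dim_px) < mask_p, dim_px, dim_px)
  if (!any(mask)) mask[1, 1] <- TRUE
  quantize_roi(img, mask, G)
}

# small phantom feature table shared by a few tests (cached per session)
phantom_table_small <- local({
  cache <- NULL
  function(n = 20L) {
    if (is.null(cache)) {
      ds <- generate_dataset(phantom_config(n_per_class = n))
      cache <<- extract_features(ds$cases)
    }
    cache
  }
})

# default-configuration phantom study table (n = 50/class), cached
phantom_table_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(phantom_config())
      cache <<- extract_features(ds$cases)
    }
    cache
  }
})

# independent log-likelihood of the tear-probability model, for optimizer
# cross-checks (coefficients on the raw scale, Eq.-style constant)
oracle_loglik <- function(coefs, constant, F, y, ridge = 0) {
  eta <- drop(F %*% coefs) - constant
  sum(y * eta - log1p(exp(eta))) -
    0.5 * ridge * sum(coefs^2)
}
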