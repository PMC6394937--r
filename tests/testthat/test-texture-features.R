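test_that("quantization maps 8-bit values to equal-width monotone bins", {
  img <- matrix(0:255, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  q <- quantize_roi(img, mask, 8L)
  lv <- as.vector(q$levels)
  expect_equal(lv, (0:255) %/% 32)         # floor(v*8/256), exhaustive
  expect_equal(unname(table(lv)), rep(32L, 8), ignore_attr = TRUE)
  expect_true(all(diff(lv) >= 0))          # monotone non-decreasing
  expect_equal(q$levels[1, 1], 0L)         # value 0 -> level 0
  expect_equal(q$levels[16, 16], 7L)       # value 255 -> level 7
  expect_equal(quantize_roi(matrix(32L, 2, 2), matrix(TRUE, 2, 2))$levels[1],
               1L)                         # 32*8/256 = 1
  expect_error(quantize_roi(img, mask, 1L), "at least 2")
  expect_true(all(is.na(
    quantize_roi(img, matrix(FALSE, 16, 16) | diag(16) > 0)$levels[
      !diag(16) > 0])))
})

test_that("a single horizontal pair yields the hand-enumerated symmetric GLCM", {
  q <- quantize_roi(matrix(c(0L, 255L), 1, 2), matrix(TRUE, 1, 2))
  g <- build_glcm(q, d = 1, theta = 0)
  expected <- matrix(0L, 8, 8)
  expected[1, 8] <- 1L; expected[8, 1] <- 1L
  expect_equal(g$counts, expected)
  expect_equal(g$probs[1, 8], 0.5)
  expect_equal(g$probs[8, 1], 0.5)
  expect_equal(sum(g$probs), 1)
})

test_that("constant ROI gives a single diagonal GLCM entry", {
  q <- quantize_roi(matrix(100L, 4, 4), matrix(TRUE, 4, 4))
  for (th in c(0, 45, 90, 135)) {
    g <- build_glcm(q, theta = th)
    k <- (100 * 8) %/% 256 + 1
    expect_equal(g$probs[k, k], 1)
    expect_equal(sum(g$probs), 1)
  }
})

test_that("GLCMs match a brute-force double-loop oracle on random masked ROIs", {
  set.seed(202)
  for (rep in 1:25) {
    q <- random_quantized_roi()
    for (th in c(0, 45, 90, 135)) {
      brute <- oracle_glcm_counts(q$levels, q$n_levels, 1, th)
      if (sum(brute) == 0) {
        expect_error(build_glcm(q, theta = th), "no valid")
      } else {
        g <- build_glcm(q, theta = th)
        expect_identical(g$counts, brute)
        expect_equal(sum(g$probs), 1)
        expect_identical(g$counts, t(g$counts))  # symmetric counting
      }
    }
  }
})

test_that("degenerate-GLCM inputs raise errors", {
  q <- quantize_roi(matrix(10L, 3, 3), diag(3) > 0)  # isolated diagonal px
  expect_error(build_glcm(q, theta = 0), "no valid")
  expect_error(build_glcm(q, d = 0, theta = 0), ">= 1")
  expect_error(build_glcm(q, theta = 30), "direction")
})

test_that("texture statistics of degenerate and uniform matrices match algebra", {
  # constant ROI -> single diagonal entry
  q <- quantize_roi(matrix(200L, 3, 3), matrix(TRUE, 3, 3))
  ts <- texture_statistics(build_glcm(q, theta = 0))
  expect_equal(ts[["Energy"]], 1)
  expect_equal(ts[["Entropy"]], 0)
  expect_equal(ts[["Contrast"]], 0)
  expect_equal(ts[["Dissimilarity"]], 0)
  expect_equal(ts[["Homogeneity"]], 1)
  expect_equal(ts[["InverseDifferenceNormalized"]], 1)
  expect_equal(ts[["InverseDifferenceMoment"]], 1)
  expect_true(is.na(ts[["Correlation"]]))

  unif <- matrix(1 / 64, 8, 8)
  tu <- texture_statistics(unif)
  expect_equal(tu[["Energy"]], 1 / 64)
  expect_equal(tu[["Entropy"]], log(64))
})

test_that("all 14 statistics match an independent naive implementation", {
  set.seed(303)
  for (rep in 1:40) {
    p <- matrix(rexp(64), 8, 8)
    p <- p / sum(p)
    got <- texture_statistics(p)
    want <- oracle_texture(p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("statistics are invariant under GLCM transposition and Correlation is bounded", {
  set.seed(404)
  for (rep in 1:20) {
    p <- matrix(rexp(64), 8, 8); p <- p / sum(p)
    a <- texture_statistics(p)
    b <- texture_statistics(t(p))
    expect_equal(a, b, tolerance = 1e-12)
    expect_true(abs(a[["Correlation"]]) <= 1 + 1e-12)
    expect_true(a[["Energy"]] > 0 && a[["Energy"]] <= 1)
    expect_gte(a[["Entropy"]], 0)
  }
})

test_that("Contrast and Dissimilarity vanish exactly for purely diagonal GLCMs", {
  set.seed(505)
  d <- rexp(8); p <- diag(d / sum(d))
  ts <- texture_statistics(p)
  expect_equal(ts[["Contrast"]], 0)
  expect_equal(ts[["Dissimilarity"]], 0)
  # and are strictly positive with any off-diagonal mass
  p2 <- p * 0.9; p2[1, 2] <- p2[2, 1] <- 0.05
  ts2 <- texture_statistics(p2)
  expect_gt(ts2[["Contrast"]], 0)
  expect_gt(ts2[["Dissimilarity"]], 0)
})

test_that("direction averaging is idempotent, linear, and near-isotropic on symmetric speckle", {
  v <- texture_statistics(matrix(1 / 64, 8, 8))
  expect_equal(mean_over_directions(list(v, v, v, v)), v)
  vs <- lapply(c(0.01, 0.02, 0.03, 0.04), function(ct) {
    w <- v; w[["Contrast"]] <- ct; w
  })
  expect_equal(mean_over_directions(vs)[["Contrast"]], 0.025)
  expect_error(mean_over_directions(list(v, v, v)), "exactly the 4")

  # isotropic smooth speckle: per-direction vectors agree closely
  set.seed(77)
  s <- sonotear:::.speckle_field(c(96L, 96L), shape = 12, sigma = 2.5)
  img <- pmin(pmax(round(120 * s), 0), 255); storage.mode(img) <- "integer"
  mask <- matrix(TRUE, 96, 96)
  q <- quantize_roi(img, mask)
  vecs <- lapply(c(0, 45, 90, 135), function(th)
    texture_statistics(build_glcm(q, theta = th)))
  avg <- mean_over_directions(vecs)
  for (vec in vecs) {
    expect_equal(vec[["Energy"]], avg[["Energy"]], tolerance = 0.08)
    expect_equal(vec[["Entropy"]], avg[["Entropy"]], tolerance = 0.08)
  }
})

test_that("phantom texture medians follow the clinical ordering", {
  tab <- phantom_table_small()
  med <- function(f, lab) median(tab[[f]][tab$label == lab])
  expect_gt(med("Energy", "tear"), med("Energy", "tendinopathy"))
  expect_lt(med("Entropy", "tear"), med("Entropy", "tendinopathy"))
})
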