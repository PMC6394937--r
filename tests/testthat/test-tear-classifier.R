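# helper: quick feature table from raw vectors
toy_table <- function(f, labels, more = NULL) {
  tab <- data.frame(case_id = as.character(seq_along(labels)),
                    patient_id = as.character(seq_along(labels)),
                    label = labels, f = f)
  if (!is.null(more)) tab <- cbind(tab, more)
  tab
}

test_that("single-binary-feature fit recovers the closed-form log odds ratio", {
  # f=1: 30 tears, 10 tendinopathies; f=0: 10 tears, 30 tendinopathies
  f <- c(rep(1, 40), rep(0, 40))
  lab <- c(rep("tear", 30), rep("tendinopathy", 10),
           rep("tear", 10), rep("tendinopathy", 30))
  fit <- fit_logistic(toy_table(f, lab), "f")
  expect_equal(unname(fit$coefficients), log(9), tolerance = 1e-6)
  expect_equal(fit$constant, log(3), tolerance = 1e-6)  # -log(10/30)
  expect_false(fit$separated)
})

test_that("null data give near-zero coefficients and chance-level training accuracy", {
  set.seed(21)
  n <- 500
  tab <- toy_table(rnorm(n), sample(rep(c("tear", "tendinopathy"), n / 2)),
                   more = data.frame(g = rnorm(n), h = rnorm(n)))
  fit <- fit_logistic(tab, c("f", "g", "h"))
  expect_true(all(abs(fit$coefficients) < 0.3))
  p <- predict_probability(fit, tab[, c("f", "g", "h")])
  acc <- mean((p >= 0.5) == (tab$label == "tear"))
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("perfect separation is flagged and saturates the probabilities", {
  f <- c(rnorm(20, -3), rnorm(20, 3))
  lab <- rep(c("tendinopathy", "tear"), each = 20)
  fit <- fit_logistic(toy_table(f, lab), "f")
  expect_true(fit$separated)
  p <- predict_probability(fit, data.frame(f = f))
  expect_true(all(p[1:20] < 0.05) && all(p[21:40] > 0.95))
})

test_that("fit errors are explicit: single class, too few cases, collinearity, NA", {
  expect_error(fit_logistic(toy_table(1:6, rep("tear", 6)), "f"),
               "both classes")
  expect_error(
    fit_logistic(toy_table(1:4, c("tear", rep("tendinopathy", 3))), "f"),
    "2 cases per class")
  tab <- toy_table(rnorm(20), rep(c("tear", "tendinopathy"), 10),
                   more = data.frame(g = NA_real_))
  tab$g <- 2 * tab$f + 1
  expect_error(fit_logistic(tab, c("f", "g")), "collinear.*f.*g")
  tab$g <- rnorm(20); tab$g[3] <- NA
  expect_error(fit_logistic(tab, c("f", "g")), "undefined.*g")
})

test_that("Newton fit attains the optimum found by a generic optimizer", {
  set.seed(22)
  for (rep in 1:5) {
    n <- 40
    F <- cbind(a = rnorm(n), b = rnorm(n))
    y <- rbinom(n, 1, plogis(0.5 * F[, 1] - 0.8 * F[, 2]))
    if (length(unique(y)) < 2 || min(table(y)) < 2) next
    tab <- data.frame(label = ifelse(y == 1, "tear", "tendinopathy"), F)
    fit <- fit_logistic(tab, c("a", "b"))
    ll_fit <- oracle_loglik(fit$coefficients, fit$constant, F, y)
    opt <- optim(c(0, 0, 0), function(th)
      -oracle_loglik(th[1:2], th[3], F, y), method = "BFGS")
    expect_gte(ll_fit + 1e-6, -opt$value)
  }
})

test_that("predicted probability follows the closed logistic form", {
  m <- structure(list(feature_names = c("a", "b"),
                      coefficients = c(a = 0, b = 0), constant = 0,
                      separated = FALSE, converged = TRUE,
                      loglik = NA_real_, wald_p = NULL),
                 class = "logistic_model")
  expect_equal(predict_probability(m, c(a = 13, b = -2)), 0.5)
  m$coefficients <- c(a = 1, b = 0); m$constant <- 2
  expect_equal(predict_probability(m, c(a = 2, b = 0)), 0.5)
  expect_gt(predict_probability(m, c(a = 50, b = 0)), 1 - 1e-10)
  expect_lt(predict_probability(m, c(a = 50, b = 0)), 1)  # strictly inside
  # monotone in a feature with positive coefficient
  p <- predict_probability(m, data.frame(a = seq(-5, 5, 1), b = 0))
  expect_true(all(diff(p) > 0))
})

test_that("model JSON round-trips through plain text", {
  tab <- toy_table(c(rnorm(10, 0), rnorm(10, 1.5)),
                   rep(c("tendinopathy", "tear"), each = 10))
  fit <- fit_logistic(tab, "f")
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$constant, fit$constant)
  expect_equal(predict_probability(back, data.frame(f = -2:2)),
               predict_probability(fit, data.frame(f = -2:2)))
  unlink(path)
})

test_that("LOOCV predicts each case from a model fitted without it", {
  # N=4, separable by construction
  tab <- toy_table(c(-2, -1, 1, 2),
                   c("tendinopathy", "tendinopathy", "tear", "tear"))
  pr <- loocv(tab, "f")
  expect_equal(nrow(pr), 4)
  expect_equal(pr$predicted, pr$truth)
  # per-fold oracle: maximize the ridge-penalized fold likelihood directly
  for (i in 1:4) {
    Ftr <- matrix(tab$f[-i], ncol = 1)
    ytr <- as.integer(tab$label[-i] == "tear")
    opt <- optim(c(0, 0), function(th)
      -oracle_loglik(th[1], th[2], Ftr, ytr, ridge = 1e-6),
      method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    p_or <- plogis(tab$f[i] * opt$par[1] - opt$par[2])
    expect_lt(abs(pr$probability[i] - p_or), 0.005)
  }
  expect_error(loocv(tab[1:2, ], "f"), "at least 3")
})

test_that("LOOCV accuracy on a duplicated dataset is not below training accuracy", {
  set.seed(23)
  f <- c(rnorm(15, 0), rnorm(15, 1.2))
  lab <- rep(c("tendinopathy", "tear"), each = 15)
  tab <- toy_table(c(f, f), c(lab, lab))
  fit <- fit_logistic(tab, "f")
  train_acc <- mean((predict_probability(fit, tab) >= 0.5) ==
                    (tab$label == "tear"))
  cv_acc <- mean(loocv(tab, "f")$predicted == tab$label)
  expect_gte(cv_acc, train_acc - 0.05)
})

test_that("single-class folds fall back to the training majority and are flagged", {
  tab <- toy_table(c(-1, 0.5, 1, 2), c("tendinopathy", rep("tear", 3)))
  pr <- loocv(tab, "f")
  expect_true(pr$fallback[1])       # removing the only tendinopathy
  expect_equal(pr$predicted[1], "tear")
  expect_false(any(pr$fallback[-1]))
})

test_that("backward elimination returns a single-feature start unchanged", {
  tab <- toy_table(c(rnorm(10), rnorm(10, 2)),
                   rep(c("tendinopathy", "tear"), each = 10))
  sel <- backward_eliminate(tab, "f")
  expect_equal(sel$features, "f")
  expect_equal(nrow(sel$trace), 0)
})

test_that("backward elimination strips noise and keeps signal on synthetic data", {
  set.seed(24)
  hits <- replicate(10, {
    n <- 120
    lab <- rep(c("tendinopathy", "tear"), each = n / 2)
    sig <- (lab == "tear") * 1.6
    tab <- data.frame(
      label = lab,
      s1 = rnorm(n) + sig, s2 = rnorm(n) + sig,
      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)
    )
    sel <- backward_eliminate(tab, c("s1", "s2", "n1", "n2", "n3"))
    !any(c("n1", "n2", "n3") %in% sel$features) &&
      length(sel$features) >= 1
  })
  expect_gte(mean(hits), 0.7)
})

test_that("all-noise elimination ends near the chance error rate", {
  set.seed(25)
  n <- 150
  tab <- data.frame(label = sample(rep(c("tendinopathy", "tear"), n / 2)),
                    a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sel <- backward_eliminate(tab, c("a", "b", "c"))
  expect_lt(abs(sel$cv_error - 0.5), 0.15)
  # surviving sets strictly shrink and stay nonempty
  expect_gte(length(sel$features), 1)
  if (nrow(sel$trace) > 0) {
    sizes <- nchar(gsub("[^+]", "", sel$trace$surviving))
    expect_true(all(diff(sizes) < 0) || length(sizes) == 1)
  }
})

test_that("known 3-coefficient models are recovered from simulated cases", {
  set.seed(26)
  n <- 3000
  F <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  true_c <- c(1.0, -0.7, 0.4); true_const <- 0.3
  y <- rbinom(n, 1, plogis(drop(F %*% true_c) - true_const))
  tab <- data.frame(label = ifelse(y == 1, "tear", "tendinopathy"), F)
  fit <- fit_logistic(tab, c("a", "b", "c"))
  expect_true(all(abs(fit$coefficients - true_c) / abs(true_c) < 0.15))
})

test_that("z-scored fitting reports coefficients on the raw scale", {
  set.seed(27)
  f <- c(rnorm(30, 100, 20), rnorm(30, 160, 20))
  lab <- rep(c("tendinopathy", "tear"), each = 30)
  tab <- toy_table(f, lab)
  raw <- fit_logistic(tab, "f")
  std <- fit_logistic(tab, "f", z_score = TRUE)
  expect_equal(std$coefficients, raw$coefficients, tolerance = 1e-4)
  expect_equal(std$constant, raw$constant, tolerance = 1e-3)
})
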