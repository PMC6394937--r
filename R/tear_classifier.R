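# Core Newton-Raphson fit for binary logistic regression.
# X includes the intercept as its first column; y is 0/1. `ridge` penalizes
# the non-intercept coefficients only. Converged when the penalized
# log-likelihood changes by < tol. Step-halving guards against overshoot.
.logit_newton <- function(X, y, ridge = 0, beta0 = NULL,
                          tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  pen <- c(0, rep(ridge, p - 1L))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # stable: log(1+exp(eta)) without overflow
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))) -
      0.5 * sum(pen * b^2)
  }
  ll <- loglik(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      # flat (aliased) directions: escalate a diagonal jitter until the
      # system solves; predictions are invariant along the flat directions
      jit <- 1e-10 * max(diag(H))
      while (is.null(step) && jit < max(diag(H))) {
        step <- tryCatch(solve(H + diag(jit, p), grad),
                         error = function(e) NULL)
        jit <- jit * 100
      }
      if (is.null(step)) break
    }
    new_beta <- beta + step
    new_ll <- loglik(new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    if (is.finite(new_ll) && abs(new_ll - ll) < tol) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X * w, X) + diag(pen, p)
  list(beta = beta, loglik = ll, converged = converged, fitted = mu, H = H)
}

#' Fit the logistic-regression tear-probability model
#'
#' Maximum-likelihood fit of
#' `P(tear) = 1 / (1 + exp(-(f1*C1 + ... + fn*Cn - constant)))`
#' by Newton iterations (convergence when the log-likelihood changes by less
#' than 1e-8, at most 100 iterations). When the classes are completely
#' separated the unpenalized likelihood has no finite optimum; this is
#' detected (non-convergence or near-zero deviance) and the model is refit
#' with a small ridge penalty (1e-6) and flagged via `separated = TRUE`.
#' Features enter on their raw scale; `z_score = TRUE` standardizes
#' internally for conditioning, with coefficients reported back on the raw
#' scale.
#'
#' @param table Feature table with a `label` column.
#' @param features Character vector of feature columns to use.
#' @param z_score Standardize features internally before fitting.
#' @param ridge Ridge penalty on the coefficients (default 0; used
#'   automatically on separation).
#' @return A list of class `"logistic_model"`: `feature_names`,
#'   `coefficients` (named, raw scale), `constant`, `separated`, `converged`,
#'   `loglik`, `wald_p`.
#' @export
fit_logistic <- function(table, features, z_score = FALSE, ridge = 0) {
  .check_feature_table(table, features)
  if (length(features) < 1L) stop("no features given", call. = FALSE)
  y <- as.integer(as.character(table$label) == "tear")
  if (length(unique(y)) < 2L) {
    stop("both classes are needed to fit the classifier", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("need at least 2 cases per class", call. = FALSE)
  }
  F <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(F)) {
    bad <- features[colSums(is.na(F)) > 0]
    stop("undefined feature value(s) in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .check_collinear(F, features)
  fit <- .fit_logistic_matrix(F, y, z_score = z_score, ridge = ridge)
  se <- sqrt(diag(solve(fit$H)))
  z <- fit$beta_internal / se
  wald_p <- 2 * stats::pnorm(-abs(z))[-1]
  names(wald_p) <- features
  coefs <- unname(fit$beta_raw[-1])
  names(coefs) <- features
  structure(
    list(feature_names = features, coefficients = coefs,
         constant = unname(-fit$beta_raw[1]), separated = fit$separated,
         converged = fit$converged, loglik = fit$loglik, wald_p = wald_p),
    class = "logistic_model"
  )
}

# collinearity guard: exact duplicates-up-to-affine pairs and rank deficiency
.check_collinear <- function(F, features) {
  if (ncol(F) >= 2L) {
    sds <- apply(F, 2, stats::sd)
    ok <- sds > 0
    if (sum(ok) >= 2L) {
      cc <- suppressWarnings(stats::cor(F[, ok, drop = FALSE]))
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 0
      if (any(abs(cc) > 1 - 1e-10)) {
        idx <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)[1, ]
        nm <- colnames(cc)[idx]
        stop("collinear feature pair: ", nm[1], " and ", nm[2], call. = FALSE)
      }
    }
  }
  sds <- apply(F, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
         paste(features[sds == 0], collapse = ", "), call. = FALSE)
  }
  # exact-degeneracy guard on the standardized design; near-collinearity is
  # tolerated (the texture family is strongly correlated by construction)
  X <- cbind(1, scale(F))
  if (qr(X, tol = 1e-9)$rank < ncol(X)) {
    stop("design matrix is rank deficient for features: ",
         paste(features, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

# internal fit on a plain feature matrix (no table plumbing); returns raw
# and internal-scale coefficients plus separation flag
.fit_logistic_matrix <- function(F, y, z_score = FALSE, ridge = 0,
                                 beta0 = NULL) {
  if (z_score) {
    ctr <- colMeans(F)
    scl <- apply(F, 2, stats::sd)
    scl[scl == 0] <- 1
    Xf <- sweep(sweep(F, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(F)); scl <- rep(1, ncol(F))
    Xf <- F
  }
  X <- cbind(1, Xf)
  fit <- .logit_newton(X, y, ridge = ridge, beta0 = beta0)
  deviance <- -2 * fit$loglik
  separated <- !fit$converged || deviance < 1e-6
  if (separated && ridge < 1e-6) {
    fit <- .logit_newton(X, y, ridge = 1e-6, beta0 = NULL)
  }
  beta <- fit$beta
  # map standardized coefficients back to the raw feature scale
  b_raw <- beta
  if (z_score) {
    b_raw[-1] <- beta[-1] / scl
    b_raw[1] <- beta[1] - sum(beta[-1] * ctr / scl)
  }
  list(beta_internal = beta, beta_raw = b_raw, loglik = fit$loglik,
       converged = fit$converged, separated = separated, H = fit$H,
       fitted = fit$fitted)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic tear-probability model\n")
  cat("  P(tear) = 1 / (1 + exp(-(sum_i C_i * f_i - constant)))\n")
  for (i in seq_along(x$feature_names)) {
    cat(sprintf("  C[%s] = %.6g\n", x$feature_names[i], x$coefficients[i]))
  }
  cat(sprintf("  constant = %.6g\n", x$constant))
  if (isTRUE(x$separated)) cat("  note: separation detected; ridge refit\n")
  invisible(x)
}

#' Tear probability for feature values
#'
#' Evaluates
#' `P(tear) = 1 / (1 + exp(-(f1*C1 + ... + fn*Cn - constant)))`
#' for one or more cases.
#'
#' @param model A `"logistic_model"`.
#' @param feature_values Named numeric vector, matrix or data.frame carrying
#'   the model's features.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, feature_values) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.null(dim(feature_values))) {
    feature_values <- matrix(feature_values, nrow = 1,
                             dimnames = list(NULL, names(feature_values)))
  }
  fm <- as.matrix(as.data.frame(feature_values)[, model$feature_names,
                                                drop = FALSE])
  eta <- drop(fm %*% model$coefficients) - model$constant
  # strictly inside (0,1) even where plogis saturates in double precision
  pmin(pmax(stats::plogis(eta), .Machine$double.xmin),
       1 - .Machine$double.eps / 2)
}

#' Serialize / restore a fitted model as plain text
#'
#' @param model A `"logistic_model"`.
#' @param path Output (input) JSON path.
#' @return `write_model`: `path` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         coefficients = unname(model$coefficients),
         constant = model$constant,
         separated = model$separated, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.numeric(obj$coefficients)
  names(coefs) <- obj$feature_names
  structure(
    list(feature_names = obj$feature_names, coefficients = coefs,
         constant = obj$constant, separated = isTRUE(obj$separated),
         converged = isTRUE(obj$converged), loglik = NA_real_,
         wald_p = NULL),
    class = "logistic_model"
  )
}

# fast internal LOOCV over a fixed feature set: returns probabilities.
# Warm-started from the all-data fit. Folds whose training part is
# single-class fall back to the training majority (probability 0/1-ish).
.loocv_probs <- function(F, y, z_score = FALSE) {
  n <- length(y)
  full <- .fit_logistic_matrix(F, y, z_score = FALSE)
  ridge <- if (full$separated) 1e-6 else 0
  probs <- numeric(n)
  X <- cbind(1, F)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) {
      probs[i] <- mean(yi)          # majority fallback, flagged upstream
      next
    }
    fit <- .logit_newton(X[-i, , drop = FALSE], yi, ridge = ridge,
                         beta0 = full$beta_internal)
    if (!fit$converged && ridge == 0) {
      fit <- .logit_newton(X[-i, , drop = FALSE], yi, ridge = 1e-6)
    }
    probs[i] <- stats::plogis(sum(X[i, ] * fit$beta))
  }
  probs
}

#' Leave-one-out cross-validation of the classifier
#'
#' Each case is predicted by a model trained on the remaining N-1 cases;
#' cases with probability >= `threshold` are called tears. With
#' `select = "none"` the given feature set is used in every fold; with
#' `select = "inside"` stepwise backward elimination is re-run inside each
#' training fold (leakage-free, but much slower). Folds whose training part
#' degenerates to a single class fall back to the training majority and are
#' flagged in the `fallback` column.
#'
#' @param table Feature table.
#' @param features Feature columns to use (the starting set under
#'   `select = "inside"`).
#' @param select `"none"` or `"inside"`.
#' @param threshold Classification threshold on the tear probability
#'   (default 0.5).
#' @return A data.frame (class `"loocv_predictions"`): `case_id`,
#'   `probability`, `predicted`, `truth`, `fallback`.
#' @export
loocv <- function(table, features, select = c("none", "inside"),
                  threshold = 0.5) {
  select <- match.arg(select)
  .check_feature_table(table, features)
  n <- nrow(table)
  if (n < 3L) stop("LOOCV needs at least 3 cases, got ", n, call. = FALSE)
  y <- as.integer(as.character(table$label) == "tear")
  F <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(F)) stop("undefined feature values in the selected features",
                     call. = FALSE)
  fallback <- vapply(seq_len(n), function(i) length(unique(y[-i])) < 2L,
                     logical(1))
  if (select == "none") {
    probs <- .loocv_probs(F, y)
  } else {
    probs <- vapply(seq_len(n), function(i) {
      if (fallback[i]) return(mean(y[-i]))
      sel <- backward_eliminate(table[-i, , drop = FALSE], features)
      fi <- .fit_logistic_matrix(
        as.matrix(table[-i, sel$features, drop = FALSE]), y[-i])
      stats::plogis(sum(c(1, as.numeric(F[i, sel$features])) * fi$beta_raw))
    }, numeric(1))
  }
  ids <- if ("case_id" %in% names(table)) as.character(table$case_id)
         else as.character(seq_len(n))
  out <- data.frame(
    case_id = ids,
    probability = probs,
    predicted = ifelse(probs >= threshold, "tear", "tendinopathy"),
    truth = as.character(table$label),
    fallback = fallback
  )
  class(out) <- c("loocv_predictions", "data.frame")
  out
}

#' Stepwise backward feature elimination
#'
#' Greedy elimination driven by the leave-one-out error of the candidate
#' sets: starting from `start_features`, each step evaluates the LOOCV error
#' of every single-feature removal and removes the feature whose removal
#' yields the lowest error, provided that error stays within one standard
#' error (`sqrt(e(1-e)/N)`) of the current error — the usual 1-SE parsimony
#' slack, without which chance fluctuations of one or two held-out cases
#' routinely protect irrelevant features from removal. Removal ties are
#' broken by dropping the feature with the largest Wald p-value in the
#' full-data fit. The loop stops when every removal worsens the error beyond
#' the slack or a single feature remains.
#'
#' @param table Feature table.
#' @param start_features Starting feature set (nonempty).
#' @param threshold Classification threshold used for the error rate.
#' @return List of class `"elimination_result"`: `features` (surviving set),
#'   `model` (full-data fit on it), `cv_error`, and `trace` — a data.frame
#'   with one row per elimination step (feature removed, error before/after,
#'   surviving set).
#' @export
backward_eliminate <- function(table, start_features, threshold = 0.5) {
  .check_feature_table(table, start_features)
  if (length(start_features) < 1L) {
    stop("`start_features` must be nonempty", call. = FALSE)
  }
  y <- as.integer(as.character(table$label) == "tear")
  err_of <- function(feats) {
    F <- as.matrix(table[, feats, drop = FALSE])
    mean((.loocv_probs(F, y) >= threshold) != y)
  }
  n <- nrow(table)
  current <- start_features
  current_err <- err_of(current)
  steps <- list()
  while (length(current) > 1L) {
    cand_err <- vapply(current, function(f) err_of(setdiff(current, f)),
                       numeric(1))
    best <- min(cand_err)
    slack <- sqrt(current_err * (1 - current_err) / n)
    if (best > current_err + slack) break
    ties <- current[cand_err == best]
    if (length(ties) > 1L) {
      wp <- fit_logistic(table, current)$wald_p[ties]
      drop_f <- ties[which.max(wp)]
    } else {
      drop_f <- ties
    }
    steps[[length(steps) + 1L]] <- data.frame(
      removed = drop_f, error_before = current_err, error_after = best,
      surviving = paste(setdiff(current, drop_f), collapse = "+")
    )
    current <- setdiff(current, drop_f)
    current_err <- best
  }
  trace <- if (length(steps)) do.call(rbind, steps) else
    data.frame(removed = character(), error_before = numeric(),
               error_after = numeric(), surviving = character())
  structure(
    list(features = current, model = fit_logistic(table, current),
         cv_error = current_err, trace = trace),
    class = "elimination_result"
  )
}

#' @export
print.elimination_result <- function(x, ...) {
  cat("Backward elimination:", nrow(x$trace), "feature(s) removed\n")
  cat("  surviving:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  LOOCV error of surviving set: %.4f\n", x$cv_error))
  invisible(x)
}
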