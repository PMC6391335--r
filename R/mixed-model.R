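# Random-intercept linear mixed model for repeated sessions per subject,
# fit natively: the fixed effects have a closed-form GLS solution at any
# value of the variance ratio lambda = sigma_subject^2 / sigma_resid^2, and
# the likelihood is profiled over lambda by 1-D optimization. ML is the
# default (AIC/BIC comparisons across fixed-effect sets stay valid); REML is
# available via a switch.

# Per-group sufficient statistics for the compound-symmetry GLS algebra:
# with W = I - (lambda / (1 + lambda n)) J,
#   X'WX = X'X - mu (X'1)(1'X),  mu = lambda / (1 + lambda n).
mixed_suffstats <- function(X, y, group) {
  gl <- split(seq_len(nrow(X)), group)
  lapply(gl, function(ix) {
    Xi <- X[ix, , drop = FALSE]
    yi <- y[ix]
    list(
      n = length(ix),
      XtX = crossprod(Xi), Xty = crossprod(Xi, yi),
      X1 = colSums(Xi), y1 = sum(yi),
      yty = sum(yi^2)
    )
  })
}

mixed_profile <- function(ss, lambda, N, p, reml = FALSE) {
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  for (s in ss) {
    mu <- lambda / (1 + lambda * s$n)
    A <- A + s$XtX - mu * tcrossprod(s$X1)
    bvec <- bvec + s$Xty - mu * s$X1 * s$y1
  }
  beta <- solve(A, bvec)
  q <- 0
  logdet <- 0
  for (s in ss) {
    mu <- lambda / (1 + lambda * s$n)
    rss <- s$yty - 2 * sum(beta * s$Xty) + drop(t(beta) %*% s$XtX %*% beta)
    r1 <- s$y1 - sum(s$X1 * beta)
    q <- q + rss - mu * r1^2
    logdet <- logdet + log1p(lambda * s$n)
  }
  if (reml) {
    sig2 <- q / (N - p)
    ll <- -0.5 * ((N - p) * log(2 * pi * sig2) + (N - p) + logdet +
      determinant(A, logarithm = TRUE)$modulus[1])
  } else {
    sig2 <- q / N
    ll <- -0.5 * (N * log(2 * pi * sig2) + N + logdet)
  }
  list(beta = beta, sigma2_resid = sig2, loglik = ll, A = A, lambda = lambda)
}

#' Fit a random-intercept mixed linear model
#'
#' Gaussian model `y = X beta + b_subject + e` with one random intercept per
#' subject, fit by maximum likelihood: profile likelihood over the variance
#' ratio with closed-form GLS fixed effects at each ratio.
#'
#' @param data data.frame with a `subject_id` column, the feature columns in
#'   `formula_terms`, and the response column.
#' @param formula_terms character vector of feature column names (fixed
#'   effects; an intercept is always included).
#' @param response response column name.
#' @param reml use REML instead of ML.
#' @return A `mixed_fit`: `fixed_effects`, `se`, `sigma_subject`,
#'   `sigma_resid`, `loglik`, `aic`, `bic`, `n_obs`, `n_subjects`,
#'   `lambda`, `reml`.
#' @export
fit_mixed_model <- function(data, formula_terms, response = "ultrasound_ga",
                            reml = FALSE) {
  stopifnot(
    "subject_id" %in% names(data),
    response %in% names(data),
    all(formula_terms %in% names(data))
  )
  group <- as.factor(data$subject_id)
  if (nlevels(group) < 2) {
    stop("fit_mixed_model: need at least 2 subjects")
  }
  if (max(table(group)) < 2) {
    stop("fit_mixed_model: need at least one subject with >= 2 sessions")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, formula_terms, drop = FALSE]))
  y <- as.numeric(data[[response]])
  if (anyNA(X) || anyNA(y)) {
    stop("fit_mixed_model: missing values in design or response")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(
      "fit_mixed_model: design is rank deficient; collinear term(s): ",
      paste(dropped, collapse = ", ")
    )
  }
  N <- nrow(X)
  p <- ncol(X)
  ss <- mixed_suffstats(X, y, group)

  obj <- function(u) mixed_profile(ss, exp(u), N, p, reml)$loglik
  # profile over log(lambda); also consider the lambda -> 0 boundary (OLS)
  opt <- stats::optimize(obj, interval = c(-14, 14), maximum = TRUE,
    tol = 1e-9)
  at0 <- mixed_profile(ss, 0, N, p, reml)
  best <- if (at0$loglik >= opt$objective) {
    at0
  } else {
    mixed_profile(ss, exp(opt$maximum), N, p, reml)
  }

  sigma_resid <- sqrt(best$sigma2_resid)
  sigma_subject <- sqrt(best$lambda * best$sigma2_resid)
  k <- p + 2
  ll <- best$loglik
  se <- sqrt(diag(solve(best$A)) * best$sigma2_resid)
  fe <- drop(best$beta)
  names(fe) <- colnames(X)
  names(se) <- colnames(X)
  structure(
    list(
      fixed_effects = fe, se = se,
      sigma_subject = sigma_subject, sigma_resid = sigma_resid,
      loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(N),
      n_obs = N, n_subjects = nlevels(group),
      lambda = best$lambda, reml = reml
    ),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_fit %s | %d obs, %d subjects>\n",
    if (x$reml) "REML" else "ML", x$n_obs, x$n_subjects
  ))
  tab <- cbind(Estimate = x$fixed_effects, `Std.Error` = x$se)
  print(round(tab, 4))
  cat(sprintf(
    "  sigma_subject = %.3f  sigma_resid = %.3f\n  logLik = %.2f  AIC = %.2f  BIC = %.2f\n",
    x$sigma_subject, x$sigma_resid, x$loglik, x$aic, x$bic
  ))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing feature `j` on the remaining
#' features (with intercept). Perfect collinearity is reported as `Inf`.
#'
#' @param data data.frame containing the feature columns.
#' @param terms character vector of feature names (>= 2).
#' @return Named numeric vector of VIFs.
#' @export
variance_inflation <- function(data, terms) {
  stopifnot(length(terms) >= 2, all(terms %in% names(data)))
  if (nrow(data) < length(terms) + 2) {
    stop("variance_inflation: need at least #terms + 2 rows")
  }
  X <- as.matrix(data[, terms, drop = FALSE])
  vapply(seq_along(terms), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, yj)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) {
      return(Inf)
    }
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(terms)
}
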