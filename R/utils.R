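# Internal fitting kernels shared by the marker-wise scans and the
# single-marker simulation experiments. Both return Wald-type estimates the
# way summary.glm reports them: z-based p-values for binomial fits, t-based
# for gaussian fits (dispersion estimated).

.assert_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  bad <- !is.finite(x) |
    (if (open_left) x <= 0 else x < 0) |
    (if (open_right) x >= 1 else x > 1)
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie in %s0, 1%s; got %s.",
      name, if (open_left) "(" else "[", if (open_right) ")" else "]",
      paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")
    ))
  }
  invisible(x)
}

# Wald fit of y on design X (first column must be the intercept); returns the
# coefficient, standard error and two-sided p-value for column `term`.
# On rank deficiency or non-convergence returns ok = FALSE with a reason.
.wald_fit <- function(X, y, family = "gaussian", term = 2L) {
  n <- length(y)
  k <- ncol(X)
  if (n <= k) {
    return(list(ok = FALSE, reason = "too_few_observations"))
  }
  if (family == "gaussian") {
    fit <- lm.fit(X, y)
    if (fit$rank < k) {
      return(list(ok = FALSE, reason = "rank_deficient"))
    }
    rss <- sum(fit$residuals^2)
    df <- n - k
    sigma2 <- rss / df
    R <- qr.R(fit$qr)
    XtX_inv <- chol2inv(R)
    se <- sqrt(sigma2 * XtX_inv[term, term])
    beta <- fit$coefficients[term]
    if (!is.finite(se) || se <= 0) {
      return(list(ok = FALSE, reason = "degenerate_variance"))
    }
    p <- 2 * pt(-abs(beta / se), df)
    list(ok = TRUE, beta = unname(beta), se = se, p = p, n = n)
  } else {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    cf <- fit$coefficients
    if (any(is.na(cf)) || fit$rank < k) {
      return(list(ok = FALSE, reason = "rank_deficient"))
    }
    info <- crossprod(X, X * fit$weights)
    V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(V)) {
      return(list(ok = FALSE, reason = "singular_information"))
    }
    se <- sqrt(V[term, term])
    beta <- unname(cf[term])
    if (!is.finite(se) || se <= 0) {
      return(list(ok = FALSE, reason = "degenerate_variance"))
    }
    p <- 2 * pnorm(-abs(beta / se))
    list(ok = TRUE, beta = beta, se = se, p = p, n = n)
  }
}

.match_family <- function(family) {
  family <- match.arg(family, c("gaussian", "binomial"))
  family
}

# Seed handling: functions that accept `seed = NULL` leave the RNG stream
# alone; an integer seed makes the call deterministic.
.with_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      abort("`seed` must be a single finite number or NULL.")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
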