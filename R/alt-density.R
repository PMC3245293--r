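#' Noncentrality parameter of a calibrated chi-square alternative
#'
#' Computes the noncentrality parameter \eqn{\lambda} of the noncentral
#' \eqn{\chi^2_1} density that a 1-df test run at type-I error `alpha` would
#' need in order to attain power `1 - beta`. For a two-tailed test
#' \eqn{\lambda = (\Phi^{-1}(1-\alpha/2) + \Phi^{-1}(1-\beta))^2}; for a
#' one-tailed test \eqn{\alpha/2} is replaced by \eqn{\alpha}. Wald tests from
#' generalized linear models are two-sided, so `"two"` is the default.
#'
#' @param alpha Per-test type-I error rate, in (0, 1).
#' @param beta Type-II error rate (power is `1 - beta`), in (0, 1).
#' @param tails `"two"` (default) or `"one"`.
#' @return The noncentrality parameter (a nonnegative scalar).
#' @examples
#' noncentrality(0.05 / 368.8, 0.2) # about 21.7
#' @export
noncentrality <- function(alpha, beta, tails = c("two", "one")) {
  tails <- match.arg(tails)
  .assert_prob(alpha, "alpha")
  .assert_prob(beta, "beta")
  div <- if (tails == "two") 2 else 1
  (qnorm(1 - alpha / div) + qnorm(1 - beta))^2
}

#' Calibrated alternative density for a 1-df chi-square test
#'
#' Bundles the calibration of one testing stage: the per-test type-I error
#' `alpha` (typically 0.05 divided by the effective number of tests), the
#' target power, the chi-square degrees of freedom, the implied noncentrality
#' parameter, and the prior probability that a locus affects the phenotype
#' (typically 1 over the effective number of tests).
#'
#' @inheritParams noncentrality
#' @param power Target power `1 - beta`; defaults to 0.8.
#' @param df Chi-square degrees of freedom (1 for Wald tests of a single
#'   coefficient).
#' @param prior Prior probability that a locus affects the phenotype, in
#'   `[0, 1]`, or `NULL` to leave it unset.
#' @return An object of class `"alt_density"`.
#' @examples
#' alternative_density(alpha = 0.05 / 368.8, prior = 1 / 368.8)
#' @export
alternative_density <- function(alpha, power = 0.8, df = 1, prior = NULL,
                                tails = c("two", "one")) {
  tails <- match.arg(tails)
  .assert_prob(alpha, "alpha")
  .assert_prob(power, "power")
  if (!is.null(prior)) {
    .assert_prob(prior, "prior", open_left = FALSE, open_right = FALSE)
  }
  if (df < 1 || df != round(df)) abort("`df` must be a positive integer.")
  structure(
    list(
      alpha = alpha, beta = 1 - power, df = as.integer(df),
      ncp = noncentrality(alpha, 1 - power, tails),
      prior = prior, tails = tails
    ),
    class = "alt_density"
  )
}

#' @export
print.alt_density <- function(x, ...) {
  cat(sprintf(
    "Calibrated chi-square alternative (df = %d, %s-tailed)\n  alpha = %.4g, power = %.3f, ncp = %.4f%s\n",
    x$df, x$tails, x$alpha, 1 - x$beta, x$ncp,
    if (is.null(x$prior)) "" else sprintf(", prior = %.4g", x$prior)
  ))
  invisible(x)
}

#' Calibrate the admixture and association alternative densities
#'
#' Convenience constructor for the pair of calibrations the joint test needs,
#' from the two effective numbers of tests: each stage gets type-I error
#' `alpha_budget / n_eff`, prior `1 / n_eff`, and the noncentrality implied by
#' the target power.
#'
#' @param n_eff_admix,n_eff_assoc Effective numbers of tests for the
#'   admixture and association scans (need not be integers).
#' @param power Target power, default 0.8.
#' @param alpha_budget Genome-wide type-I error budget, default 0.05.
#' @inheritParams noncentrality
#' @return A list with elements `admix` and `assoc`, each an
#'   [alternative_density()].
#' @examples
#' calibrate_densities(368.8, 345450.3)
#' @export
calibrate_densities <- function(n_eff_admix, n_eff_assoc, power = 0.8,
                                alpha_budget = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n_eff_admix < 1 || n_eff_assoc < 1) {
    abort("Effective numbers of tests must be >= 1.")
  }
  list(
    admix = alternative_density(alpha_budget / n_eff_admix, power,
      prior = 1 / n_eff_admix, tails = tails
    ),
    assoc = alternative_density(alpha_budget / n_eff_assoc, power,
      prior = 1 / n_eff_assoc, tails = tails
    )
  )
}

#' Transform p-values to chi-square statistics
#'
#' Inverse of the central chi-square survival function: returns the statistic
#' whose upper-tail probability equals `p`.
#'
#' @param p P-values in (0, 1].
#' @param df Degrees of freedom.
#' @return Chi-square statistics of the same length as `p`.
#' @examples
#' pvalue_to_chisq(0.05, 1) # 3.8415
#' @export
pvalue_to_chisq <- function(p, df = 1) {
  .assert_prob(p, "p", open_left = TRUE, open_right = FALSE)
  qchisq(p, df = df, lower.tail = FALSE)
}

#' Bayes factor from the chi-square density ratio
#'
#' The marginal likelihood ratio \eqn{f_1(x)/f_0(x)} of the noncentral
#' (alternative) to the central (null) chi-square density at the observed
#' statistic `x`. For df = 1 both densities diverge at the origin but their
#' ratio has the analytic limit \eqn{e^{-\lambda/2}}, which is returned at
#' `x = 0` so that a completely null statistic still yields a finite (and
#' maximally unfavourable) Bayes factor.
#'
#' @param x Observed chi-square statistics (nonnegative).
#' @param density An [alternative_density()].
#' @return Bayes factors of the same length as `x`.
#' @export
bayes_factor <- function(x, density) {
  stopifnot(inherits(density, "alt_density"))
  if (any(!is.finite(x) | x < 0)) abort("`x` must be finite and >= 0.")
  exp(.log_bayes_factor(x, density$df, density$ncp))
}

.log_bayes_factor <- function(x, df, ncp) {
  out <- dchisq(x, df = df, ncp = ncp, log = TRUE) -
    dchisq(x, df = df, log = TRUE)
  # analytic x -> 0+ limit of the density ratio (only the j = 0 Poisson
  # mixture term diverges with the central density)
  out[x == 0] <- -ncp / 2
  out
}

#' Posterior probability that a locus affects the phenotype
#'
#' Converts a p-value into a posterior probability through Bayes' theorem:
#' the p-value is mapped to a chi-square statistic with [pvalue_to_chisq()],
#' the Bayes factor is the noncentral-over-central density ratio, and the
#' prior odds are updated to posterior odds. A prior of exactly 1 cannot be
#' updated by any data (the posterior is returned as 1 with a warning); a
#' prior of 0 returns 0.
#'
#' @param p P-values in (0, 1].
#' @param density An [alternative_density()] supplying df and ncp (and the
#'   default prior).
#' @param prior Prior probabilities in `[0, 1]`; either length 1 or the
#'   length of `p`. Defaults to `density$prior`.
#' @return Posterior probabilities in `[0, 1]`.
#' @examples
#' d <- alternative_density(0.05 / 368.8, prior = 1 / 368.8)
#' posterior_probability(1e-5, d)
#' @export
posterior_probability <- function(p, density, prior = density$prior) {
  stopifnot(inherits(density, "alt_density"))
  if (is.null(prior)) abort("No `prior` supplied and `density$prior` is NULL.")
  .assert_prob(p, "p", open_left = TRUE, open_right = FALSE)
  .assert_prob(prior, "prior", open_left = FALSE, open_right = FALSE)
  if (length(prior) == 1) prior <- rep(prior, length(p))
  if (length(prior) != length(p)) {
    abort("`prior` must have length 1 or length(p).")
  }
  out <- numeric(length(p))
  one <- prior == 1
  zero <- prior == 0
  if (any(one)) {
    warn(paste(
      "Prior probability of 1 cannot be updated by the data;",
      "the posterior is returned as 1."
    ))
    out[one] <- 1
  }
  mid <- !one & !zero
  if (any(mid)) {
    x <- pvalue_to_chisq(p[mid], density$df)
    log_odds <- qlogis(prior[mid]) + .log_bayes_factor(x, density$df, density$ncp)
    out[mid] <- plogis(log_odds)
  }
  out
}

#' Chi-square statistic achieving a target posterior probability
#'
#' Solves for the statistic `x` at which [posterior_probability()] with the
#' given prior equals `target`. The Bayes factor is strictly increasing in
#' `x` for df = 1 and ncp > 0, so the root is unique; it is found by
#' bracketed root-finding on the log Bayes factor (relative tolerance below
#' 1e-10). If the target posterior is below the posterior attainable at
#' `x = 0` (where the Bayes factor is `exp(-ncp/2)`), no solution exists and
#' an error is raised.
#'
#' @param prior Prior probability, in (0, 1).
#' @param target Target posterior probability, in (0, 1).
#' @param density An [alternative_density()]; its `prior` field is ignored.
#' @return The chi-square statistic (scalar).
#' @export
required_chisq_for_posterior <- function(prior, target, density) {
  stopifnot(inherits(density, "alt_density"))
  .assert_prob(prior, "prior")
  .assert_prob(target, "target")
  if (density$ncp <= 0) abort("Requires a calibrated density with ncp > 0.")
  need <- qlogis(target) - qlogis(prior) # required log Bayes factor
  if (need <= -density$ncp / 2) {
    abort(paste(
      "Target posterior is not attainable: it is at or below the posterior",
      "at a zero statistic."
    ))
  }
  f <- function(x) .log_bayes_factor(x, density$df, density$ncp) - need
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = 1e-12)$root
}
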