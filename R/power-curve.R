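#' Change in association sample size implied by an admixture-mapping p-value
#'
#' Quantifies how prior evidence from admixture mapping alters the evidence
#' (and hence, proportionally, the sample size) that association mapping
#' needs for genome-wide significance. The admixture p-value is converted to
#' a posterior probability (under the admixture calibration), that posterior
#' becomes the association-stage prior, and the chi-square statistic at which
#' the association posterior reaches 0.5 is solved for. The returned value is
#' the fractional change of that statistic relative to the statistic required
#' under the uniform association prior `assoc_density$prior`; the required
#' statistic is treated as proportional to sample size.
#'
#' @param p_admix Admixture-mapping p-values in (0, 1].
#' @param admix_density An [alternative_density()] calibrated for admixture
#'   mapping, with its prior set (1 over the admixture testing burden).
#' @param assoc_density An [alternative_density()] calibrated for association
#'   mapping, with its prior set (1 over the association testing burden).
#' @param target Posterior probability defining significance (default 0.5).
#' @return Fractional sample-size changes (e.g. `0.265` is a 26.5% increase).
#' @seealso [break_even_pvalue()], [power_curve()]
#' @export
sample_size_change <- function(p_admix, admix_density, assoc_density,
                               target = 0.5) {
  stopifnot(inherits(admix_density, "alt_density"),
            inherits(assoc_density, "alt_density"))
  if (is.null(admix_density$prior) || is.null(assoc_density$prior)) {
    abort("Both densities must carry their priors.")
  }
  x_ref <- required_chisq_for_posterior(assoc_density$prior, target,
                                        assoc_density)
  chained <- posterior_probability(p_admix, admix_density)
  vapply(chained, function(pr) {
    required_chisq_for_posterior(pr, target, assoc_density) / x_ref - 1
  }, numeric(1))
}

#' Break-even admixture-mapping p-value
#'
#' The admixture p-value at which the admixture-stage posterior equals the
#' uniform association prior, i.e. at which chaining neither helps nor hurts
#' the association stage ([sample_size_change()] is zero). Admixture
#' p-values below this point increase downstream association power.
#'
#' @inheritParams sample_size_change
#' @return A p-value (scalar).
#' @export
break_even_pvalue <- function(admix_density, assoc_density) {
  stopifnot(inherits(admix_density, "alt_density"),
            inherits(assoc_density, "alt_density"))
  target <- assoc_density$prior
  if (is.null(target) || is.null(admix_density$prior)) {
    abort("Both densities must carry their priors.")
  }
  f <- function(lp) {
    log(posterior_probability(exp(lp), admix_density)) - log(target)
  }
  # posterior is monotone decreasing in p; solve on the log-p scale
  root <- uniroot(f, c(log(1e-300), log(1)), tol = 1e-14)$root
  exp(root)
}

#' Admixture-evidence power curve
#'
#' Tabulates, over a grid of admixture-mapping p-values, the chained
#' association prior, the association chi-square statistic needed for a joint
#' posterior of 0.5, and the implied fractional change in association sample
#' size.
#'
#' @inheritParams sample_size_change
#' @param p_grid Grid of admixture p-values.
#' @return A tibble with columns `p_admix`, `admix_posterior`,
#'   `required_stat`, `sample_size_change`.
#' @examples
#' cal <- calibrate_densities(368.8, 345450.3)
#' power_curve(cal$admix, cal$assoc, p_grid = c(1e-4, 0.05, 0.31, 1))
#' @export
power_curve <- function(admix_density, assoc_density,
                        p_grid = 10^seq(-6, 0, length.out = 121),
                        target = 0.5) {
  x_ref <- required_chisq_for_posterior(assoc_density$prior, target,
                                        assoc_density)
  chained <- posterior_probability(p_grid, admix_density)
  req <- vapply(chained, required_chisq_for_posterior,
                numeric(1), target = target, density = assoc_density)
  tibble::tibble(
    p_admix = p_grid,
    admix_posterior = chained,
    required_stat = req,
    sample_size_change = req / x_ref - 1
  )
}

#' Plot the admixture-evidence power curve
#'
#' @param curve A tibble from [power_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve, ...) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$p_admix,
                                      y = 100 * .data$sample_size_change)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "admixture-mapping p-value",
      y = "change in association sample size (%)"
    ) +
    ggplot2::theme_minimal()
}
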