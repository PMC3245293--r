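#' Joint Bayesian ancestry and association test, genome-wide
#'
#' Runs the six-step joint test over aligned local-ancestry and genotype
#' panels:
#' 1. admixture mapping: GLM of phenotype on local ancestry, adjusted for
#'    global ancestry and covariates;
#' 2. conversion of admixture p-values to posterior probabilities under the
#'    calibrated noncentral chi-square alternative, with prior 1 over the
#'    admixture testing burden;
#' 3. association mapping: GLM of phenotype on genotype within strata of
#'    local ancestry, same adjustments;
#' 4. inverse-variance fixed-effects pooling across strata;
#' 5. two-sided p-value of the pooled z statistic;
#' 6. conversion of association p-values to posterior probabilities, using
#'    the admixture-stage posteriors as priors.
#'
#' Every marker is carried through both stages regardless of its admixture
#' significance — there is no conditional filtering and hence no winner's
#' curse. Testing burdens are estimated once per input panel by
#' autoregressive spectral analysis ([testing_burden()]) unless supplied in
#' `burdens`. The genomic-control inflation factor of the association scan
#' is reported but never used to rescale statistics.
#'
#' @inheritParams association_scan
#' @param burdens Optional list with elements `admix` and `assoc` overriding
#'   the estimated effective numbers of tests (useful for simulation studies
#'   that fix the testing burden).
#' @param power Target power used to calibrate the alternative densities
#'   (default 0.8).
#' @param alpha_budget Genome-wide type-I error budget (default 0.05).
#' @param threshold Posterior-probability significance threshold (default
#'   0.5, the point at which the posterior odds switch hypothesis).
#' @param max_ar_order Maximum AR order for burden estimation.
#' @return An object of class `"bmix_fit"`: list with `results` (per-marker
#'   tibble), `strata` (per-marker per-stratum details) and `metadata`.
#' @examples
#' sim <- simulate_cohort_panels(n_individuals = 60, n_markers = 12, seed = 1)
#' fit <- bmix(sim$phenotypes, sim$genotypes, sim$local_ancestry,
#'             phenotype = "phenotype",
#'             burdens = list(admix = 8, assoc = 12))
#' head(tidy(fit))
#' @export
bmix <- function(data, genotypes, local_ancestry, phenotype,
                 covariates = NULL,
                 family = c("gaussian", "binomial"),
                 burdens = NULL,
                 power = 0.8,
                 alpha_budget = 0.05,
                 threshold = 0.5,
                 min_stratum = 10,
                 max_ar_order = NULL,
                 include_global_ancestry = TRUE,
                 id_col = "id") {
  family <- match.arg(family)
  .assert_prob(power, "power")
  .assert_prob(threshold, "threshold")
  genotypes <- validate_panel(genotypes)
  local_ancestry <- validate_panel(local_ancestry)
  alignment <- .align_individuals(data, genotypes, id_col)

  if (is.null(burdens)) {
    burdens <- list(
      admix = testing_burden(local_ancestry, max_ar_order, "admixture")$genome_wide,
      assoc = testing_burden(genotypes, max_ar_order, "association")$genome_wide
    )
  }
  cal <- calibrate_densities(burdens$admix, burdens$assoc,
                             power = power, alpha_budget = alpha_budget)

  adm <- admixture_scan(data, local_ancestry, phenotype, covariates,
                        family, include_global_ancestry, id_col)
  asc <- association_scan(data, genotypes, local_ancestry, phenotype,
                          covariates, family, include_global_ancestry,
                          min_stratum, id_col)

  admix_posterior <- rep(NA_real_, nrow(adm))
  ok_a <- is.finite(adm$p)
  admix_posterior[ok_a] <- posterior_probability(adm$p[ok_a], cal$admix)

  joint_posterior <- rep(NA_real_, nrow(asc))
  ok_j <- is.finite(asc$p) & is.finite(admix_posterior)
  if (any(ok_j)) {
    joint_posterior[ok_j] <- posterior_probability(
      asc$p[ok_j], cal$assoc, prior = admix_posterior[ok_j]
    )
  }

  lambda_gc <- if (sum(is.finite(asc$p)) >= 100) {
    genomic_control_lambda(asc$p[is.finite(asc$p)])
  } else {
    NA_real_
  }

  results <- tibble::tibble(
    marker = adm$marker, chrom = adm$chrom, pos = adm$pos,
    admix_beta = adm$beta, admix_se = adm$se, admix_p = adm$p,
    admix_posterior = admix_posterior,
    pooled_beta = asc$pooled_beta, pooled_se = asc$pooled_se,
    assoc_z = asc$z, assoc_p = asc$p,
    joint_posterior = joint_posterior,
    admix_status = adm$status, assoc_status = asc$status
  )

  structure(
    list(
      results = results,
      strata = asc[, c("marker", "strata")],
      metadata = list(
        family = family,
        covariates = covariates,
        burdens = burdens,
        alphas = list(admix = cal$admix$alpha, assoc = cal$assoc$alpha),
        ncps = list(admix = cal$admix$ncp, assoc = cal$assoc$ncp),
        priors = list(admix = cal$admix$prior, assoc = cal$assoc$prior),
        power = power,
        alpha_budget = alpha_budget,
        threshold = threshold,
        lambda_gc = lambda_gc,
        n_individuals = length(alignment$ids),
        n_individuals_dropped = alignment$n_dropped,
        n_markers = nrow(results)
      )
    ),
    class = "bmix_fit"
  )
}

#' @export
print.bmix_fit <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Joint ancestry/association scan (%s family)\n  markers: %d, individuals: %d\n  burdens: admixture %.3f, association %.3f\n  ncp: admixture %.3f, association %.3f\n  lambda_GC: %s\n  significant (posterior > %.2f): admixture %d, joint %d\n",
    md$family, md$n_markers, md$n_individuals,
    md$burdens$admix, md$burdens$assoc, md$ncps$admix, md$ncps$assoc,
    ifelse(is.na(md$lambda_gc), "NA", sprintf("%.3f", md$lambda_gc)),
    md$threshold,
    nrow(call_significant(x, stage = "admixture")),
    nrow(call_significant(x, stage = "joint"))
  ))
  invisible(x)
}

#' @export
tidy.bmix_fit <- function(x, ...) {
  x$results
}

#' @export
glance.bmix_fit <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    family = md$family,
    n_markers = md$n_markers,
    n_individuals = md$n_individuals,
    burden_admix = md$burdens$admix,
    burden_assoc = md$burdens$assoc,
    ncp_admix = md$ncps$admix,
    ncp_assoc = md$ncps$assoc,
    lambda_gc = md$lambda_gc,
    n_significant_admix = nrow(call_significant(x, stage = "admixture")),
    n_significant_joint = nrow(call_significant(x, stage = "joint"))
  )
}

#' Markers exceeding the posterior significance threshold
#'
#' @param fit A `"bmix_fit"` or its results tibble.
#' @param threshold Posterior threshold; markers strictly above it are
#'   called (a posterior exactly at the threshold is not significant).
#'   Defaults to the fit's configured threshold, or 0.5.
#' @param stage `"joint"` or `"admixture"`.
#' @return The subset of the results tibble called significant.
#' @export
call_significant <- function(fit, threshold = NULL,
                             stage = c("joint", "admixture")) {
  stage <- match.arg(stage)
  results <- if (inherits(fit, "bmix_fit")) fit$results else fit
  if (is.null(threshold)) {
    threshold <- if (inherits(fit, "bmix_fit")) fit$metadata$threshold else 0.5
  }
  col <- if (stage == "joint") "joint_posterior" else "admix_posterior"
  results[!is.na(results[[col]]) & results[[col]] > threshold, , drop = FALSE]
}

#' Plot-ready Manhattan table of posterior probabilities
#'
#' Orders markers by (chromosome, position), adds a strictly increasing
#' genome-wide cumulative position, and carries both posteriors through
#' unchanged together with significance flags.
#'
#' @inheritParams call_significant
#' @return Tibble with columns `marker`, `chrom`, `pos`, `cum_pos`,
#'   `admix_posterior`, `joint_posterior`, `admix_significant`,
#'   `joint_significant`.
#' @export
manhattan_table <- function(fit, threshold = NULL) {
  results <- if (inherits(fit, "bmix_fit")) fit$results else fit
  if (is.null(threshold)) {
    threshold <- if (inherits(fit, "bmix_fit")) fit$metadata$threshold else 0.5
  }
  out <- results |>
    dplyr::arrange(.data$chrom, .data$pos)
  offsets <- out |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$pos), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$span, default = 0)))
  out |>
    dplyr::left_join(offsets[, c("chrom", "offset")], by = "chrom") |>
    dplyr::mutate(
      cum_pos = .data$pos + .data$offset,
      admix_significant = !is.na(.data$admix_posterior) &
        .data$admix_posterior > threshold,
      joint_significant = !is.na(.data$joint_posterior) &
        .data$joint_posterior > threshold
    ) |>
    dplyr::select("marker", "chrom", "pos", "cum_pos",
                  "admix_posterior", "joint_posterior",
                  "admix_significant", "joint_significant")
}

#' Bayesian Manhattan plot
#'
#' Posterior probability that each locus affects the phenotype, for the
#' admixture stage and the joint test, with the significance threshold drawn
#' as a horizontal line.
#'
#' @param object A `"bmix_fit"`.
#' @param threshold Posterior significance threshold (default: the fit's).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bmix_fit <- function(object, threshold = NULL, ...) {
  tab <- manhattan_table(object, threshold)
  if (is.null(threshold)) threshold <- object$metadata$threshold
  long <- tab |>
    tidyr::pivot_longer(
      cols = c("admix_posterior", "joint_posterior"),
      names_to = "stage", values_to = "posterior"
    ) |>
    dplyr::mutate(stage = dplyr::recode(.data$stage,
      admix_posterior = "admixture mapping",
      joint_posterior = "joint test"
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cum_pos, y = .data$posterior,
                                     colour = factor(.data$chrom))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red") +
    ggplot2::facet_wrap(~stage, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "genome position", y = "posterior probability") +
    ggplot2::theme_minimal()
}
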