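#' Fit an autoregressive model by Yule-Walker with AIC order selection
#'
#' Fits AR(p) models for p = 0..`max_order` to the mean-centred series and
#' keeps the AIC-minimising order. The default maximum order,
#' `min(n - 1, floor(10 * log10(n)))`, matches the convention of common
#' time-series and MCMC-diagnostic software.
#'
#' @param series Numeric vector (at least 8 finite values, not constant).
#' @param max_order Maximum AR order to consider.
#' @return An object of class `"ar_model"` with fields `order`,
#'   `coefficients`, `innovation_variance`, `constant`, `series_length`,
#'   `aic` (the selected model's AIC relative to the best, always 0) and
#'   `stationary`.
#' @export
fit_ar <- function(series, max_order = NULL) {
  series <- as.numeric(series)
  if (any(!is.finite(series))) abort("`series` must be finite (impute first).")
  n <- length(series)
  if (n < 8) abort("`series` must contain at least 8 values.")
  if (var(series) == 0) {
    abort("`series` is constant; no autoregressive model can be fitted.",
          class = "bmix_degenerate_series")
  }
  if (is.null(max_order)) max_order <- min(n - 1, floor(10 * log10(n)))
  fit <- ar(series, aic = TRUE, order.max = max_order,
            method = "yule-walker", demean = TRUE)
  phi <- as.numeric(fit$ar)
  stationary <- length(phi) == 0 ||
    all(Mod(polyroot(c(1, -phi))) > 1)
  structure(
    list(
      order = fit$order,
      coefficients = phi,
      innovation_variance = fit$var.pred,
      constant = unname(fit$x.mean * (1 - sum(phi))),
      series_length = n,
      aic = unname(fit$aic[as.character(fit$order)]),
      stationary = stationary
    ),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf(
    "AR(%d) model (Yule-Walker, AIC-selected), n = %d\n  innovation variance = %.4g%s\n",
    x$order, x$series_length, x$innovation_variance,
    if (x$order > 0) {
      sprintf("\n  coefficients = %s", paste(format(x$coefficients, digits = 3),
                                             collapse = ", "))
    } else ""
  ))
  invisible(x)
}

#' Spectral density of an AR model at frequency zero
#'
#' For a stationary AR(p) model with innovation variance \eqn{\sigma^2} and
#' coefficients \eqn{\phi_1, ..., \phi_p}, the spectral density at frequency
#' zero is \eqn{\sigma^2 / (1 - \sum_i \phi_i)^2}.
#'
#' @param model An [fit_ar()] result.
#' @return The spectral density at frequency zero (scalar).
#' @export
spectral_density_zero <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  s <- sum(model$coefficients)
  if (!model$stationary || abs(1 - s) < 1e-10) {
    abort("AR model is not stationary (unit root); spectral density at zero is undefined.")
  }
  model$innovation_variance / (1 - s)^2
}

#' Effective number of independent observations in an autocorrelated series
#'
#' Estimates the effective sample size as
#' `n * var(series) / spectral_density_zero(fit_ar(series))`, clamped to
#' `[1, n]`. A constant series carries exactly one independent observation
#' and returns 1; a series too short for AR fitting (fewer than 8 values) is
#' treated as uncorrelated and returns its length (or 1 if constant).
#'
#' @inheritParams fit_ar
#' @return The effective number of tests (scalar in `[1, n]`).
#' @examples
#' set.seed(1)
#' effective_size(rnorm(2000)) # close to 2000
#' @export
effective_size <- function(series, max_order = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n == 0) abort("`series` is empty.")
  if (n == 1 || var(series) == 0) return(1)
  if (n < 8) return(n)
  model <- fit_ar(series, max_order)
  ess <- n * var(series) / spectral_density_zero(model)
  min(max(ess, 1), n)
}

#' Count ancestry switches along a chromosome
#'
#' Number of adjacent unequal pairs in an ordered local-ancestry sequence;
#' a chromosome with `s` switches is a mosaic of `s + 1` segments.
#'
#' @param ancestry_series Ordered vector of 0/1/2 local-ancestry values.
#' @return Integer switch count.
#' @examples
#' count_switches(c(0, 0, 1, 1, 2, 1, 1, 0, 0, 0, 1, 1)) # 5
#' @export
count_switches <- function(ancestry_series) {
  if (length(ancestry_series) == 0) abort("`ancestry_series` is empty.")
  sum(diff(as.numeric(ancestry_series)) != 0)
}

#' Generations since admixture from the ancestry-switch count
#'
#' Under a hybrid-isolation model, a diploid genome of genetic length `L`
#' Morgans accumulates an expected \eqn{4 g \theta (1 - \theta) L} ancestry
#' switches over `g` generations at admixture proportion \eqn{\theta}, so
#' \eqn{\hat g = S / (4 \theta (1 - \theta) L)}. The autosomal map length is
#' a required input: published maps differ enough that no default is
#' presented as ground truth.
#'
#' @param total_switches Observed (or mean) number of ancestry switches per
#'   person across the diploid autosomal genome.
#' @param admixture_prop Admixture proportion \eqn{\theta}, strictly in (0, 1).
#' @param map_length Diploid autosomal genetic map length in Morgans (per
#'   haploid genome; about 35 for humans).
#' @return Estimated generations since admixture began.
#' @export
estimate_generations <- function(total_switches, admixture_prop, map_length) {
  if (admixture_prop <= 0 || admixture_prop >= 1) {
    abort("`admixture_prop` must be strictly inside (0, 1).")
  }
  if (map_length <= 0) abort("`map_length` must be positive.")
  if (total_switches < 0) abort("`total_switches` must be nonnegative.")
  total_switches / (4 * admixture_prop * (1 - admixture_prop) * map_length)
}

#' Testing burden of a scan from marker-to-marker autocorrelation
#'
#' Estimates the effective number of tests of an admixture or association
#' scan. For every individual and chromosome, the ordered sequence of values
#' (local-ancestry copies or minor-allele counts) is reduced to an effective
#' sample size via [effective_size()]; chromosomes are summed within
#' individual and the per-individual totals are averaged.
#'
#' Missing values are mean-imputed within each (individual, chromosome)
#' sequence before fitting; the number imputed is reported.
#'
#' @param panel A marker panel tibble: columns `marker`, `chrom`, `pos`, then
#'   one column of 0/1/2 values per individual (see [read_local_ancestry()]).
#' @param max_order Maximum AR order passed to [effective_size()].
#' @param scan_type `"admixture"` or `"association"`; recorded in the report.
#' @return An object of class `"burden_report"`: a list with
#'   `per_individual_per_chromosome` (tibble: individual, chrom, n_markers,
#'   effective_tests), `per_individual_total` (tibble: individual,
#'   effective_tests), `genome_wide` (scalar mean), `scan_type`, and
#'   `n_imputed`.
#' @export
testing_burden <- function(panel, max_order = NULL,
                           scan_type = c("admixture", "association")) {
  scan_type <- match.arg(scan_type)
  panel <- validate_panel(panel)
  ids <- panel_individuals(panel)
  n_imputed <- 0L
  per_ic <- purrr::map_dfr(split(panel, panel$chrom), function(chr) {
    purrr::map_dfr(ids, function(id) {
      x <- chr[[id]]
      miss <- is.na(x)
      if (all(miss)) {
        abort(sprintf("Individual %s has no observed values on chromosome %s.",
                      id, chr$chrom[1]))
      }
      if (any(miss)) {
        x[miss] <- mean(x[!miss])
        n_imputed <<- n_imputed + sum(miss)
      }
      tibble::tibble(
        individual = id,
        chrom = chr$chrom[1],
        n_markers = length(x),
        effective_tests = effective_size(x, max_order)
      )
    })
  })
  per_ind <- per_ic |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(effective_tests = sum(.data$effective_tests),
                     .groups = "drop")
  structure(
    list(
      per_individual_per_chromosome = per_ic,
      per_individual_total = per_ind,
      genome_wide = mean(per_ind$effective_tests),
      scan_type = scan_type,
      n_imputed = n_imputed
    ),
    class = "burden_report"
  )
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf(
    "Testing burden (%s scan)\n  individuals: %d, chromosomes: %d\n  genome-wide effective number of tests: %.1f\n",
    x$scan_type,
    nrow(x$per_individual_total),
    length(unique(x$per_individual_per_chromosome$chrom)),
    x$genome_wide
  ))
  if (x$n_imputed > 0) cat(sprintf("  (%d missing values mean-imputed)\n", x$n_imputed))
  invisible(x)
}

#' @export
tidy.burden_report <- function(x, ...) {
  x$per_individual_per_chromosome
}

#' @export
glance.burden_report <- function(x, ...) {
  tibble::tibble(
    scan_type = x$scan_type,
    n_individuals = nrow(x$per_individual_total),
    n_chromosomes = length(unique(x$per_individual_per_chromosome$chrom)),
    genome_wide_effective_tests = x$genome_wide,
    n_imputed = x$n_imputed
  )
}
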