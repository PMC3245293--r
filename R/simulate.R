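# Vicariance-model simulator: two parental populations drift from a common
# ancestral allele frequency to a target FST (Balding-Nichols model), then
# mix. Individual admixture proportions theta are Beta-distributed; each of
# an individual's two chromosome copies at a marker carries an ancestry drawn
# Bernoulli(theta), and each allele copy is drawn from the parental frequency
# matching that copy's ancestry, so genotype and local ancestry have exactly
# the dependence the stratified association step relies on.

#' Parental allele frequencies under the Balding-Nichols model
#'
#' Draws, per marker, an ancestral frequency from
#' `Uniform(ancestral_range)` and two parental frequencies from the
#' Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. With this parameterisation the pairwise
#' Hudson FST between the two parental populations equals `fst` in
#' expectation.
#'
#' @param n_markers Number of markers.
#' @param fst Target differentiation, in (0, 1); 0.12 mimics the West
#'   African / European split.
#' @param seed Optional integer seed (same seed, same frequencies).
#' @param ancestral_range Support of the ancestral frequency (bounded away
#'   from 0 and 1 to avoid monomorphic markers).
#' @return Tibble with columns `marker`, `p_anc`, `p1`, `p2`.
#' @export
simulate_parental_freqs <- function(n_markers, fst = 0.12, seed = NULL,
                                    ancestral_range = c(0.1, 0.9)) {
  .assert_prob(fst, "fst")
  .with_seed(seed)
  p <- runif(n_markers, ancestral_range[1], ancestral_range[2])
  sh <- (1 - fst) / fst
  tibble::tibble(
    marker = paste0("m", seq_len(n_markers)),
    p_anc = p,
    p1 = rbeta(n_markers, p * sh, (1 - p) * sh),
    p2 = rbeta(n_markers, p * sh, (1 - p) * sh)
  )
}

#' Pairwise Hudson FST from parental frequency pairs
#'
#' Ratio-of-averages Hudson estimator on population frequencies:
#' `mean((p1-p2)^2) / mean(p1(1-p2) + p2(1-p1))`.
#'
#' @param freqs A tibble with columns `p1`, `p2` (e.g. from
#'   [simulate_parental_freqs()]).
#' @return Estimated FST.
#' @export
hudson_fst <- function(freqs) {
  num <- mean((freqs$p1 - freqs$p2)^2)
  den <- mean(freqs$p1 * (1 - freqs$p2) + freqs$p2 * (1 - freqs$p1))
  num / den
}

#' Simulate an admixed cohort (ancestries and genotypes, no phenotype)
#'
#' Per-individual admixture proportions are Beta-distributed with the given
#' mean and standard deviation (or fixed via `theta`); each chromosome copy
#' at each marker draws its ancestry Bernoulli(theta) and its allele from
#' the matching parental frequency. Local ancestry is the number of copies
#' from the first parental population; the genotype is the derived-allele
#' count.
#'
#' @param n_individuals Number of individuals.
#' @param freqs Parental frequencies from [simulate_parental_freqs()]; its
#'   row count sets the number of markers.
#' @param admixture_mean,admixture_sd Mean and standard deviation of the
#'   Beta distribution of individual admixture proportions (defaults 0.8 and
#'   0.1, mimicking African Americans).
#' @param theta Optional fixed admixture proportion(s) overriding the Beta
#'   draw (length 1 or `n_individuals`).
#' @param seed Optional integer seed.
#' @return An object of class `"bmix_cohort"`: list with matrices
#'   `local_ancestry` and `genotypes` (markers x individuals), vector
#'   `theta`, and `freqs`.
#' @export
simulate_admixed_cohort <- function(n_individuals, freqs,
                                    admixture_mean = 0.8,
                                    admixture_sd = 0.1,
                                    theta = NULL, seed = NULL) {
  .with_seed(seed)
  n_markers <- nrow(freqs)
  if (is.null(theta)) {
    .assert_prob(admixture_mean, "admixture_mean")
    conc <- admixture_mean * (1 - admixture_mean) / admixture_sd^2 - 1
    if (conc <= 0) abort("`admixture_sd` too large for the given mean.")
    theta <- rbeta(n_individuals, admixture_mean * conc,
                   (1 - admixture_mean) * conc)
  } else {
    theta <- rep_len(theta, n_individuals)
    .assert_prob(theta, "theta", open_left = FALSE, open_right = FALSE)
  }
  th <- matrix(theta, nrow = n_markers, ncol = n_individuals, byrow = TRUE)
  c1 <- matrix(rbinom(n_markers * n_individuals, 1, th), n_markers)
  c2 <- matrix(rbinom(n_markers * n_individuals, 1, th), n_markers)
  P1 <- matrix(freqs$p1, n_markers, n_individuals)
  P2 <- matrix(freqs$p2, n_markers, n_individuals)
  x1 <- matrix(rbinom(n_markers * n_individuals, 1,
                      ifelse(c1 == 1, P1, P2)), n_markers)
  x2 <- matrix(rbinom(n_markers * n_individuals, 1,
                      ifelse(c2 == 1, P1, P2)), n_markers)
  ids <- paste0("ind", seq_len(n_individuals))
  la <- c1 + c2
  g <- x1 + x2
  dimnames(la) <- dimnames(g) <- list(freqs$marker, ids)
  structure(
    list(local_ancestry = la, genotypes = g, theta = setNames(theta, ids),
         freqs = freqs),
    class = "bmix_cohort"
  )
}

#' Quantitative phenotype for a simulated cohort
#'
#' `y = beta_ancestry * ancestry + beta_genotype * genotype + covariates +
#' noise`, with ancestry and genotype taken at one causal marker.
#'
#' @param cohort A [simulate_admixed_cohort()] result.
#' @param causal_marker Marker id or index (default: middle marker).
#' @param beta_ancestry,beta_genotype Effects per ancestry copy and per
#'   derived-allele copy, in phenotype units.
#' @param noise_sd Residual standard deviation.
#' @param covariate_effects Optional named list mapping covariate vectors to
#'   coefficients, as `list(age = list(values =, beta =))`.
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector, one value per individual.
#' @export
simulate_quantitative_trait <- function(cohort, causal_marker = NULL,
                                        beta_ancestry = 0,
                                        beta_genotype = 0,
                                        noise_sd = 1,
                                        covariate_effects = NULL,
                                        seed = NULL) {
  .with_seed(seed)
  n <- length(cohort$theta)
  j <- .resolve_marker(cohort, causal_marker)
  y <- beta_ancestry * cohort$local_ancestry[j, ] +
    beta_genotype * cohort$genotypes[j, ]
  for (cv in covariate_effects) {
    y <- y + cv$beta * cv$values
  }
  y + rnorm(n, sd = noise_sd)
}

.resolve_marker <- function(cohort, causal_marker) {
  n_markers <- nrow(cohort$local_ancestry)
  if (is.null(causal_marker)) return(ceiling(n_markers / 2))
  if (is.character(causal_marker)) {
    j <- match(causal_marker, rownames(cohort$local_ancestry))
    if (is.na(j)) abort("`causal_marker` not found.")
    return(j)
  }
  as.integer(causal_marker)
}

#' Simulated cohort as analysis-ready panels
#'
#' Wraps frequency, cohort and quantitative-trait simulation into the
#' tibble panels the scan functions consume. Markers are laid out on
#' `n_chromosomes` chromosomes at 1 Mb spacing.
#'
#' @inheritParams simulate_admixed_cohort
#' @param n_markers Number of markers.
#' @param n_chromosomes Number of chromosomes to spread markers over.
#' @param beta_ancestry,beta_genotype,causal_marker,noise_sd Passed to
#'   [simulate_quantitative_trait()].
#' @param fst Parental differentiation.
#' @param seed Optional integer seed.
#' @return List with `local_ancestry`, `genotypes` (panels), `phenotypes`
#'   (tibble: id, phenotype, age, sex), `theta`, `freqs`, `causal_marker`.
#' @export
simulate_cohort_panels <- function(n_individuals, n_markers,
                                   n_chromosomes = 1,
                                   beta_ancestry = 0, beta_genotype = 0,
                                   causal_marker = NULL, noise_sd = 1,
                                   admixture_mean = 0.8, admixture_sd = 0.1,
                                   fst = 0.12, seed = NULL) {
  .with_seed(seed)
  freqs <- simulate_parental_freqs(n_markers, fst)
  cohort <- simulate_admixed_cohort(n_individuals, freqs,
                                    admixture_mean, admixture_sd)
  n <- n_individuals
  age <- round(runif(n, 25, 75))
  sex <- rbinom(n, 1, 0.5)
  y <- simulate_quantitative_trait(
    cohort, causal_marker, beta_ancestry, beta_genotype, noise_sd,
    covariate_effects = list(age = list(values = (age - 50) / 10, beta = 0.05))
  )
  j <- .resolve_marker(cohort, causal_marker)
  chrom <- rep(seq_len(n_chromosomes), length.out = n_markers)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), seq_along),
                use.names = FALSE) * 1e6
  meta <- tibble::tibble(marker = freqs$marker, chrom = chrom, pos = pos)
  ids <- colnames(cohort$local_ancestry)
  list(
    local_ancestry = dplyr::bind_cols(
      meta, tibble::as_tibble(cohort$local_ancestry)
    ),
    genotypes = dplyr::bind_cols(meta, tibble::as_tibble(cohort$genotypes)),
    phenotypes = tibble::tibble(id = ids, phenotype = y, age = age, sex = sex),
    theta = cohort$theta,
    freqs = freqs,
    causal_marker = freqs$marker[j]
  )
}

#' Simulate a single-marker admixed case-control cohort
#'
#' Disease status follows the logistic model
#' `logit P(case) = logit(baseline_prev) + log(ancestry_or) * ancestry +
#' log(genotype_or) * genotype`; individuals are drawn from the admixed
#' population and rejection-sampled until the case and control quotas are
#' met.
#'
#' @param freqs One row of parental frequencies (columns `p1`, `p2`), e.g.
#'   `simulate_parental_freqs(1)`; the ancestral frequency is typically
#'   re-drawn per replicate to marginalise over allele frequencies.
#' @param ancestry_or Odds ratio per ancestry copy from the first parental
#'   population.
#' @param genotype_or Odds ratio per derived-allele copy.
#' @param n_cases,n_controls Quotas (defaults 1500/1500).
#' @param admixture_mean,admixture_sd Admixture distribution parameters.
#' @param baseline_prev Baseline disease prevalence at zero ancestry and
#'   zero derived alleles (default 0.1).
#' @param seed Optional integer seed.
#' @param max_draws Sampling budget; exceeding it (pathological prevalence)
#'   is an error.
#' @return An object of class `"bmix_cc_cohort"`: list with `data` (tibble
#'   `id`, `case`, `ancestry`, `genotype`, `theta`), `p1`, `p2` and the
#'   generating parameters.
#' @export
simulate_case_control <- function(freqs, ancestry_or, genotype_or,
                                  n_cases = 1500, n_controls = 1500,
                                  admixture_mean = 0.8, admixture_sd = 0.1,
                                  baseline_prev = 0.1, seed = NULL,
                                  max_draws = 500 * (n_cases + n_controls)) {
  if (ancestry_or <= 0 || genotype_or <= 0) abort("Odds ratios must be > 0.")
  .assert_prob(baseline_prev, "baseline_prev")
  .with_seed(seed)
  p1 <- freqs$p1[1]; p2 <- freqs$p2[1]
  conc <- admixture_mean * (1 - admixture_mean) / admixture_sd^2 - 1
  b0 <- qlogis(baseline_prev)
  la <- log(ancestry_or); lr <- log(genotype_or)
  need_case <- n_cases; need_ctl <- n_controls
  drawn <- 0
  acc <- list()
  while (need_case > 0 || need_ctl > 0) {
    nb <- min(8000, max(2000, 4 * (need_case + need_ctl)))
    drawn <- drawn + nb
    if (drawn > max_draws) {
      abort("Sampling budget exhausted before meeting case/control quotas.",
            class = "bmix_sampling_budget")
    }
    th <- rbeta(nb, admixture_mean * conc, (1 - admixture_mean) * conc)
    c1 <- rbinom(nb, 1, th); c2 <- rbinom(nb, 1, th)
    x1 <- rbinom(nb, 1, ifelse(c1 == 1, p1, p2))
    x2 <- rbinom(nb, 1, ifelse(c2 == 1, p1, p2))
    a <- c1 + c2; g <- x1 + x2
    y <- rbinom(nb, 1, plogis(b0 + la * a + lr * g))
    kc <- which(y == 1)[seq_len(min(need_case, sum(y == 1)))]
    kt <- which(y == 0)[seq_len(min(need_ctl, sum(y == 0)))]
    kk <- c(kc, kt)
    acc[[length(acc) + 1]] <-
      cbind(y = y[kk], a = a[kk], g = g[kk], th = th[kk])
    need_case <- need_case - length(kc)
    need_ctl <- need_ctl - length(kt)
  }
  m <- do.call(rbind, acc)
  structure(
    list(
      data = tibble::tibble(
        id = paste0("ind", seq_len(nrow(m))),
        case = as.integer(m[, "y"]), ancestry = as.integer(m[, "a"]),
        genotype = as.integer(m[, "g"]), theta = m[, "th"]
      ),
      p1 = p1, p2 = p2,
      params = list(ancestry_or = ancestry_or, genotype_or = genotype_or,
                    n_cases = n_cases, n_controls = n_controls,
                    baseline_prev = baseline_prev,
                    admixture_mean = admixture_mean,
                    admixture_sd = admixture_sd)
    ),
    class = "bmix_cc_cohort"
  )
}

#' Joint test at a single marker
#'
#' Runs the full posterior chain at one marker: admixture GLM, posterior
#' conversion under the admixture calibration, local-ancestry stratified
#' association with inverse-variance pooling, and the chained association
#' posterior. With a single marker, global ancestry averaged over markers is
#' collinear with local ancestry itself, so no global-ancestry covariate is
#' included.
#'
#' @param y Phenotype vector (0/1 for `family = "binomial"`).
#' @param genotype,ancestry Integer 0/1/2 vectors.
#' @param calibration A list with `admix` and `assoc`
#'   [alternative_density()] objects (see [calibrate_densities()]).
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param min_stratum Minimum usable stratum size.
#' @return One-row tibble: `admix_beta`, `admix_se`, `admix_p`,
#'   `admix_posterior`, `pooled_beta`, `pooled_se`, `assoc_p`,
#'   `joint_posterior`.
#' @export
bmix_single_marker <- function(y, genotype, ancestry, calibration,
                               family = c("binomial", "gaussian"),
                               min_stratum = 10) {
  family <- match.arg(family)
  out <- tibble::tibble(
    admix_beta = NA_real_, admix_se = NA_real_, admix_p = NA_real_,
    admix_posterior = NA_real_, pooled_beta = NA_real_,
    pooled_se = NA_real_, assoc_p = NA_real_, joint_posterior = NA_real_
  )
  if (var(ancestry) > 0) {
    adm <- .wald_fit(cbind(1, ancestry), y, family)
    if (adm$ok) {
      out$admix_beta <- adm$beta; out$admix_se <- adm$se; out$admix_p <- adm$p
      out$admix_posterior <- posterior_probability(adm$p, calibration$admix)
    }
  }
  est <- purrr::map_dfr(0:2, function(k) {
    idx <- ancestry == k
    if (sum(idx) >= min_stratum && length(unique(genotype[idx])) >= 2) {
      fit <- .wald_fit(cbind(1, genotype[idx]), y[idx], family)
      if (fit$ok) {
        return(tibble::tibble(beta = fit$beta, se = fit$se, status = "ok"))
      }
    }
    tibble::tibble(beta = NA_real_, se = NA_real_, status = "skipped")
  })
  pooled <- pool_fixed_effects(est)
  if (!is.na(pooled$pooled_se) && !is.na(out$admix_posterior)) {
    out$pooled_beta <- pooled$pooled_beta
    out$pooled_se <- pooled$pooled_se
    out$assoc_p <- association_pvalue(pooled$pooled_beta, pooled$pooled_se)
    out$joint_posterior <- posterior_probability(
      out$assoc_p, calibration$assoc, prior = out$admix_posterior
    )
  }
  out
}

#' MIX combined ancestry/association score test
#'
#' One-degree-of-freedom Rao score test of the joint null (no genotype and
#' no ancestry effect) along the one-parameter alternative in which an
#' allelic odds ratio R induces the ancestry odds ratio
#' `Lambda(R) = (1 + (R-1) p1) / (1 + (R-1) p2)` through the parental
#' control allele frequencies. At the null the constrained direction in
#' (genotype, ancestry) effect space is `(1, p1 - p2)`; the score statistic
#' projects the joint score onto it, with nuisance parameters (intercept and
#' optional covariates) profiled out.
#'
#' @param y 0/1 case status.
#' @param genotype,ancestry Integer 0/1/2 vectors.
#' @param p1,p2 Parental (control) allele frequencies of the counted allele.
#' @param covariates Optional numeric matrix of nuisance covariates.
#' @return One-row tibble with `statistic` (signed z), `p`; `NA` for a
#'   monomorphic marker.
#' @export
mix_score <- function(y, genotype, ancestry, p1, p2, covariates = NULL) {
  if (var(genotype) == 0) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_))
  }
  n <- length(y)
  C <- cbind(rep(1, n), covariates)
  if (ncol(C) == 1) {
    mu <- rep(mean(y), n)
  } else {
    null_fit <- suppressWarnings(glm.fit(C, y, family = binomial()))
    mu <- null_fit$fitted.values
  }
  w <- mu * (1 - mu)
  X <- cbind(genotype, ancestry)
  U <- crossprod(X, y - mu)
  XtWC <- crossprod(X, C * w)
  CtWC_inv <- chol2inv(chol(crossprod(C, C * w)))
  info <- crossprod(X, X * w) - XtWC %*% CtWC_inv %*% t(XtWC)
  d <- c(1, p1 - p2)
  z <- drop(crossprod(d, U)) / sqrt(drop(t(d) %*% info %*% d))
  tibble::tibble(statistic = z, p = 2 * pnorm(-abs(z)))
}

#' Power experiment over a grid of ancestry and genotype odds ratios
#'
#' For each grid cell, simulates `n_reps` independent single-marker
#' case-control cohorts (ancestral frequency re-drawn each replicate) and
#' measures the power of the joint Bayesian test (joint posterior > 0.5
#' under the supplied testing burdens) and of the MIX score at its
#' Bonferroni threshold `alpha_budget / burdens$assoc`.
#'
#' @param or_grid Tibble with columns `ancestry_or`, `genotype_or`.
#' @param n_reps Replicates per cell.
#' @param burdens List with `admix` and `assoc` effective test counts
#'   (defaults 8.067 and 6039, mimicking chromosome 22).
#' @inheritParams simulate_case_control
#' @param fst Parental differentiation.
#' @param power,alpha_budget Calibration of the alternative densities.
#' @param threshold Joint-posterior significance threshold.
#' @param seed Optional integer seed (one stream across the whole grid).
#' @return Tibble with per-cell power estimates and Monte-Carlo standard
#'   errors: `ancestry_or`, `genotype_or`, `n_reps`, `bmix_power`,
#'   `bmix_se`, `mix_power`, `mix_se`.
#' @export
power_experiment <- function(or_grid, n_reps,
                             burdens = list(admix = 8.067, assoc = 6039),
                             n_cases = 1500, n_controls = 1500,
                             admixture_mean = 0.8, admixture_sd = 0.1,
                             baseline_prev = 0.1, fst = 0.12,
                             power = 0.8, alpha_budget = 0.05,
                             threshold = 0.5, seed = NULL) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (burdens$admix <= 1 || burdens$assoc <= 1) abort("Burdens must be > 1.")
  .with_seed(seed)
  cal <- calibrate_densities(burdens$admix, burdens$assoc,
                             power = power, alpha_budget = alpha_budget)
  mix_alpha <- alpha_budget / burdens$assoc
  purrr::map_dfr(seq_len(nrow(or_grid)), function(i) {
    lam <- or_grid$ancestry_or[i]
    R <- or_grid$genotype_or[i]
    bm <- mx <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      fr <- simulate_parental_freqs(1, fst)
      co <- simulate_case_control(fr, lam, R, n_cases, n_controls,
                                  admixture_mean, admixture_sd,
                                  baseline_prev)
      d <- co$data
      jt <- bmix_single_marker(d$case, d$genotype, d$ancestry, cal)
      bm[r] <- isTRUE(jt$joint_posterior > threshold)
      mp <- mix_score(d$case, d$genotype, d$ancestry, co$p1, co$p2)$p
      mx[r] <- isTRUE(mp < mix_alpha)
    }
    tibble::tibble(
      ancestry_or = lam, genotype_or = R, n_reps = n_reps,
      bmix_power = mean(bm),
      bmix_se = sqrt(mean(bm) * (1 - mean(bm)) / n_reps),
      mix_power = mean(mx),
      mix_se = sqrt(mean(mx) * (1 - mean(mx)) / n_reps)
    )
  })
}

#' Local- versus global-ancestry adjustment under confounding
#'
#' Two-SNP experiment: the phenotype depends only on an untested SNP whose
#' allele frequency differs strongly between the parental populations, so
#' the phenotype tracks individual admixture theta. The test SNP is analysed
#' (a) adjusting for its local ancestry only and (b) adjusting for estimated
#' global ancestry (local ancestry averaged over a background marker panel).
#' Reported are empirical rejection rates at level `alpha` with binomial
#' 95% bounds.
#'
#' Local-ancestry calls derive from a window of markers and are imperfectly
#' coupled to the ancestral origin of the typed alleles; the generator
#' therefore draws the reported local-ancestry call and the genotype's
#' latent copy ancestries independently given theta. Under perfect coupling
#' the local-ancestry adjustment would block the confounding path entirely
#' and the two adjustments would be indistinguishable.
#'
#' @param n_individuals Cohort size per replicate (default 1000).
#' @param n_reps Number of replicates.
#' @param effect Phenotype effect per derived allele of the untested SNP,
#'   in residual-SD units (default 1.5; 0 gives an unconfounded null).
#' @param freq_test,freq_untested Parental frequency pairs `c(p1, p2)` for
#'   the test and untested SNPs.
#' @param n_background Background markers used to estimate global ancestry
#'   (default 400, giving the estimate a standard error near 0.014 at
#'   `theta = 0.8` — comparable to genome-wide averaging of real
#'   local-ancestry calls).
#' @param admixture_mean,admixture_sd Admixture distribution.
#' @param alpha Test level (default 0.05).
#' @param seed Optional integer seed.
#' @return Tibble with one row per adjustment: `adjustment`, `rejections`,
#'   `n_reps`, `rate`, `lower`, `upper` (binomial 95% bounds around
#'   `alpha`).
#' @export
confounding_experiment <- function(n_individuals = 1000, n_reps = 2000,
                                   effect = 1.5,
                                   freq_test = c(0.7, 0.3),
                                   freq_untested = c(0.9, 0.1),
                                   n_background = 400,
                                   admixture_mean = 0.8, admixture_sd = 0.1,
                                   alpha = 0.05, seed = NULL) {
  .with_seed(seed)
  conc <- admixture_mean * (1 - admixture_mean) / admixture_sd^2 - 1
  draw_snp <- function(th, pq) {
    n <- length(th)
    c1 <- rbinom(n, 1, th); c2 <- rbinom(n, 1, th)
    rbinom(n, 1, ifelse(c1 == 1, pq[1], pq[2])) +
      rbinom(n, 1, ifelse(c2 == 1, pq[1], pq[2]))
  }
  rej <- c(local_ancestry = 0L, global_ancestry = 0L)
  for (r in seq_len(n_reps)) {
    th <- rbeta(n_individuals, admixture_mean * conc,
                (1 - admixture_mean) * conc)
    g1 <- draw_snp(th, freq_test)
    g2 <- draw_snp(th, freq_untested)
    a1 <- rbinom(n_individuals, 2, th) # reported call, decoupled given theta
    a2 <- rbinom(n_individuals, 2, th)
    bg <- rbinom(n_individuals, 2L * n_background, th)
    theta_hat <- (bg + a1 + a2) / (2 * (n_background + 2))
    y <- effect * g2 + rnorm(n_individuals)
    fa <- .wald_fit(cbind(1, g1, a1), y, "gaussian")
    fb <- .wald_fit(cbind(1, g1, theta_hat), y, "gaussian")
    if (fa$ok && fa$p < alpha) rej["local_ancestry"] <- rej["local_ancestry"] + 1L
    if (fb$ok && fb$p < alpha) rej["global_ancestry"] <- rej["global_ancestry"] + 1L
  }
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_reps)
  tibble::tibble(
    adjustment = names(rej),
    rejections = as.integer(rej),
    n_reps = n_reps,
    rate = as.numeric(rej) / n_reps,
    lower = alpha - half,
    upper = alpha + half
  )
}
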