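test_that("parental frequencies are deterministic and hit the target FST", {
  f1 <- simulate_parental_freqs(1000, seed = 31)
  f2 <- simulate_parental_freqs(1000, seed = 31)
  expect_identical(f1, f2)
  # vanishing drift keeps the populations together
  f_small <- simulate_parental_freqs(1e4, fst = 0.001, seed = 32)
  expect_lt(mean(abs(f_small$p1 - f_small$p2)), 0.05)
  # realized pairwise differentiation at the default target
  f_big <- simulate_parental_freqs(1e5, fst = 0.12, seed = 33)
  expect_equal(hudson_fst(f_big), 0.12, tolerance = 0.01 / 0.12)
  expect_error(simulate_parental_freqs(10, fst = 1.2), "fst")
})

test_that("admixed cohorts have the configured ancestry structure", {
  freqs <- simulate_parental_freqs(50, seed = 34)
  co <- simulate_admixed_cohort(2000, freqs, seed = 35)
  expect_equal(mean(co$local_ancestry) / 2, 0.8, tolerance = 0.02 / 0.8)
  # fixed theta = 1: everything from population 1
  co1 <- simulate_admixed_cohort(50, freqs, theta = 1, seed = 36)
  expect_true(all(co1$local_ancestry == 2))
  exp_af <- mean(freqs$p1)
  expect_equal(mean(co1$genotypes) / 2, exp_af, tolerance = 0.05)
})

test_that("genotype law within an ancestry stratum matches the parental mix", {
  freqs <- tibble::tibble(marker = "m1", p_anc = 0.5, p1 = 0.7, p2 = 0.2)
  co <- simulate_admixed_cohort(8000, freqs, seed = 37)
  a <- co$local_ancestry[1, ]
  g <- co$genotypes[1, ]
  # a = 2: Binomial(2, p1); a = 0: Binomial(2, p2);
  # a = 1: one draw from each parental frequency
  probs <- list(
    `2` = dbinom(0:2, 2, 0.7),
    `0` = dbinom(0:2, 2, 0.2),
    `1` = c((1 - 0.7) * (1 - 0.2), 0.7 * (1 - 0.2) + 0.2 * (1 - 0.7),
            0.7 * 0.2)
  )
  for (k in c(0, 1, 2)) {
    obs <- tabulate(g[a == k] + 1, nbins = 3)
    gof <- suppressWarnings(chisq.test(obs, p = probs[[as.character(k)]]))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("case-control simulation is deterministic and null-balanced", {
  fr <- simulate_parental_freqs(1, seed = 38)
  c1 <- simulate_case_control(fr, 1, 1, n_cases = 200, n_controls = 200,
                              seed = 39)
  c2 <- simulate_case_control(fr, 1, 1, n_cases = 200, n_controls = 200,
                              seed = 39)
  expect_identical(c1$data, c2$data)
  expect_equal(sum(c1$data$case), 200)
  # under the null, case and control genotype frequencies agree
  big <- simulate_case_control(fr, 1, 1, seed = 40)
  tt <- t.test(big$data$genotype ~ big$data$case)
  expect_gt(tt$p.value, 0.01)
  expect_error(
    simulate_case_control(fr, 1, 1, n_cases = 100, n_controls = 100,
                          baseline_prev = 1e-5, seed = 41, max_draws = 5000),
    class = "bmix_sampling_budget"
  )
})

test_that("the logistic generator reproduces its allelic odds ratio", {
  betas <- vapply(1:150, function(s) {
    fr <- simulate_parental_freqs(1, seed = 4000 + s)
    co <- simulate_case_control(fr, 1, 1.5, n_cases = 500, n_controls = 500,
                                seed = 5000 + s)
    fit <- suppressWarnings(glm.fit(cbind(1, co$data$genotype, co$data$ancestry),
                                    co$data$case, family = binomial()))
    fit$coefficients[2]
  }, numeric(1))
  expect_equal(mean(betas), log(1.5), tolerance = 0.05)
})

test_that("genotype is independent of theta within an ancestry stratum", {
  # the conditional-independence property that validates stratified testing
  freqs <- tibble::tibble(marker = "m1", p_anc = 0.5, p1 = 0.6, p2 = 0.3)
  co <- simulate_admixed_cohort(6000, freqs, seed = 42)
  a <- co$local_ancestry[1, ]; g <- co$genotypes[1, ]; th <- co$theta
  for (k in 1:2) {
    idx <- a == k
    fit <- summary(stats::lm(g[idx] ~ th[idx]))$coefficients
    expect_gt(fit[2, 4], 0.01)
  }
})

test_that("MIX score is deterministic, calibrated, and power-monotone in R", {
  fr <- tibble::tibble(p1 = 0.6, p2 = 0.25)
  co <- simulate_case_control(fr, 1.2, 1.2, n_cases = 400, n_controls = 400,
                              seed = 43)
  m1 <- mix_score(co$data$case, co$data$genotype, co$data$ancestry,
                  co$p1, co$p2)
  m2 <- mix_score(co$data$case, co$data$genotype, co$data$ancestry,
                  co$p1, co$p2)
  expect_identical(m1, m2)
  expect_true(is.na(mix_score(co$data$case, rep(1, 800), co$data$ancestry,
                              co$p1, co$p2)$p))
  # null calibration at alpha = 0.05
  hits <- vapply(1:800, function(s) {
    fr <- simulate_parental_freqs(1, seed = 6000 + s)
    co <- simulate_case_control(fr, 1, 1, n_cases = 400, n_controls = 400,
                                seed = 7000 + s)
    isTRUE(mix_score(co$data$case, co$data$genotype, co$data$ancestry,
                     co$p1, co$p2)$p < 0.05)
  }, logical(1))
  half <- 1.96 * sqrt(0.05 * 0.95 / 800)
  expect_gt(mean(hits), 0.05 - half)
  expect_lt(mean(hits), 0.05 + half)
  # power rises with the allelic odds ratio
  pow <- vapply(c(1, 1.25, 1.5), function(R) {
    mean(vapply(1:120, function(s) {
      fr <- simulate_parental_freqs(1, seed = 8000 + s)
      co <- simulate_case_control(fr, 1, R, n_cases = 400, n_controls = 400,
                                  seed = 9000 + s)
      isTRUE(mix_score(co$data$case, co$data$genotype, co$data$ancestry,
                       co$p1, co$p2)$p < 0.05)
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(pow) > 0))
})

test_that("quantitative traits decompose variance as specified", {
  freqs <- simulate_parental_freqs(3, seed = 44)
  co <- simulate_admixed_cohort(6000, freqs, seed = 45)
  y <- simulate_quantitative_trait(co, causal_marker = 2,
                                   beta_ancestry = 0.5, seed = 46)
  a <- co$local_ancestry[2, ]
  expl <- 0.5^2 * var(a) / var(y)
  expect_equal(summary(stats::lm(y ~ a))$r.squared, expl, tolerance = 0.1)
  # null trait gives calibrated scans
  y0 <- simulate_quantitative_trait(co, seed = 47)
  expect_equal(var(y0), 1, tolerance = 0.05)
})

test_that("single-marker joint test chains the two stages", {
  cal <- calibrate_densities(8.067, 6039)
  fr <- simulate_parental_freqs(1, seed = 48)
  co <- simulate_case_control(fr, 1.5, 1.2, n_cases = 800, n_controls = 800,
                              seed = 49)
  jt <- bmix_single_marker(co$data$case, co$data$genotype, co$data$ancestry,
                           cal)
  expect_true(is.finite(jt$joint_posterior))
  expect_equal(
    jt$joint_posterior,
    posterior_probability(jt$assoc_p, cal$assoc, prior = jt$admix_posterior),
    tolerance = 1e-12
  )
  expect_equal(jt$assoc_p,
               association_pvalue(jt$pooled_beta, jt$pooled_se),
               tolerance = 1e-12)
})
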