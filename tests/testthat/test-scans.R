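test_that("admixture scan is calibrated under the null", {
  sim <- simulate_cohort_panels(n_individuals = 300, n_markers = 200,
                                seed = 21)
  res <- admixture_scan(sim$phenotypes, sim$local_ancestry,
                        phenotype = "phenotype", covariates = c("age", "sex"))
  expect_equal(nrow(res), 200)
  expect_true(all(res$status == "ok"))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("admixture scan recovers a simulated ancestry effect", {
  b <- 0.6
  covered <- vapply(1:100, function(s) {
    sim <- simulate_cohort_panels(n_individuals = 250, n_markers = 1,
                                  beta_ancestry = b, seed = 1000 + s)
    # a single-marker panel makes global ancestry collinear with local
    # ancestry, so it is omitted here
    res <- admixture_scan(sim$phenotypes, sim$local_ancestry,
                          phenotype = "phenotype",
                          include_global_ancestry = FALSE)
    isTRUE(abs(res$beta - b) < 2 * res$se)
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("degenerate markers are flagged, not fatal", {
  sim <- simulate_cohort_panels(n_individuals = 80, n_markers = 5, seed = 22)
  la <- sim$local_ancestry
  ids <- panel_individuals(la)
  la[3, ids] <- as.list(rep(2, length(ids)))
  res <- admixture_scan(sim$phenotypes, la, phenotype = "phenotype")
  expect_equal(res$status[3], "constant_ancestry")
  expect_true(is.na(res$p[3]))
  expect_true(all(res$status[-3] == "ok"))
})

test_that("a single-stratum marker collapses to the plain GLM", {
  sim <- simulate_cohort_panels(n_individuals = 150, n_markers = 1,
                                beta_genotype = 0.4, seed = 23)
  la <- sim$local_ancestry
  ids <- panel_individuals(la)
  la[1, ids] <- as.list(rep(2L, length(ids)))
  res <- association_scan(sim$phenotypes, sim$genotypes, la,
                          phenotype = "phenotype",
                          include_global_ancestry = FALSE)
  strata <- res$strata[[1]]
  expect_equal(sum(strata$status == "ok"), 1L)
  expect_equal(res$pooled_beta, strata$beta[strata$status == "ok"])
  expect_equal(res$pooled_se, strata$se[strata$status == "ok"])
  # oracle: stats::glm on the full sample
  g <- as.numeric(sim$genotypes[1, ids])
  ref <- summary(stats::glm(sim$phenotypes$phenotype ~ g))$coefficients
  expect_equal(res$pooled_beta, ref["g", "Estimate"], tolerance = 1e-10)
  expect_equal(res$pooled_se, ref["g", "Std. Error"], tolerance = 1e-10)
})

test_that("monomorphic and undersized strata are skipped with reasons", {
  sim <- simulate_cohort_panels(n_individuals = 120, n_markers = 1, seed = 24)
  ids <- panel_individuals(sim$genotypes)
  geno <- sim$genotypes
  la <- sim$local_ancestry
  # make genotype monomorphic within the ancestry-2 stratum
  a <- as.numeric(la[1, ids])
  geno[1, ids[a == 2]] <- as.list(rep(1L, sum(a == 2)))
  res <- association_scan(sim$phenotypes, geno, la, phenotype = "phenotype")
  strata <- res$strata[[1]]
  expect_equal(strata$status[strata$stratum == 2], "skipped(monomorphic)")
  small <- strata$n < 10 & strata$stratum != 2
  expect_true(all(strata$status[small] == "skipped(small)"))
})

test_that("per-stratum effects are homogeneous when simulated equal", {
  # Cochran's Q across strata should be null-distributed
  nonsig <- vapply(1:50, function(s) {
    sim <- simulate_cohort_panels(n_individuals = 400, n_markers = 1,
                                  beta_genotype = 0.3, seed = 2000 + s)
    res <- association_scan(sim$phenotypes, sim$genotypes, sim$local_ancestry,
                            phenotype = "phenotype")
    st <- res$strata[[1]]
    ok <- st$status == "ok"
    if (sum(ok) < 2) return(TRUE)
    w <- 1 / st$se[ok]^2
    q <- sum(w * (st$beta[ok] - res$pooled_beta)^2)
    pchisq(q, sum(ok) - 1, lower.tail = FALSE) > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.8)
})

test_that("fixed-effects pooling matches the weighted-mean formulas", {
  p <- pool_fixed_effects(data.frame(beta = c(1, 3), se = c(1, 1)))
  expect_equal(p$pooled_beta, 2)
  expect_equal(p$pooled_se, 0.70711, tolerance = 1e-5)
  p1 <- pool_fixed_effects(data.frame(beta = 0.4, se = 0.1))
  expect_equal(p1$pooled_beta, 0.4)
  expect_equal(p1$pooled_se, 0.1)
  set.seed(25)
  est <- data.frame(beta = rnorm(6), se = runif(6, 0.05, 2))
  p2 <- pool_fixed_effects(est)
  w <- 1 / est$se^2
  expect_equal(p2$pooled_beta, sum(w * est$beta) / sum(w), tolerance = 1e-12)
  expect_equal(p2$pooled_se, sqrt(1 / sum(w)), tolerance = 1e-12)
  # pooled se never exceeds the best stratum; order of strata is irrelevant
  expect_lte(p2$pooled_se, min(est$se))
  p3 <- pool_fixed_effects(est[sample(6), ])
  expect_equal(p3$pooled_beta, p2$pooled_beta)
  # nothing usable -> missing result
  expect_true(is.na(pool_fixed_effects(
    data.frame(beta = NA_real_, se = NA_real_)
  )$pooled_beta))
})

test_that("association p-values are two-sided standard normal", {
  expect_equal(association_pvalue(0, 1), 1)
  expect_equal(association_pvalue(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(association_pvalue(-2.5, 1), association_pvalue(2.5, 1))
  expect_error(association_pvalue(1, 0), "pooled_se")
})

test_that("genomic-control lambda is the median chi-square ratio", {
  expect_equal(genomic_control_lambda(rep(0.5, 200)), 1, tolerance = 1e-10)
  set.seed(26)
  expect_equal(genomic_control_lambda(runif(1e5)), 1, tolerance = 0.02)
  # constructed inflation: statistics scaled by 1.2
  set.seed(27)
  stats_infl <- 1.2 * rchisq(2e4, 1)
  p_infl <- pchisq(stats_infl, 1, lower.tail = FALSE)
  expect_equal(genomic_control_lambda(p_infl), 1.2, tolerance = 0.05)
  expect_error(genomic_control_lambda(runif(50)), "at least 100")
})
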