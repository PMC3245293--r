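test_that("spectral density at frequency zero has its closed form", {
  mk <- function(phi, s2) {
    structure(list(order = length(phi), coefficients = phi,
                   innovation_variance = s2, constant = 0,
                   series_length = 1000, aic = 0, stationary = TRUE),
              class = "ar_model")
  }
  expect_equal(spectral_density_zero(mk(numeric(0), 1)), 1)
  expect_equal(spectral_density_zero(mk(0.5, 1)), 4)
  expect_equal(spectral_density_zero(mk(c(0.5, 0.25), 2)), 32)
  m <- mk(1, 1); m$stationary <- FALSE
  expect_error(spectral_density_zero(m), "stationary")
})

test_that("AIC order selection recognises white noise and AR(1)", {
  # AIC retains a spurious low order on white noise with its usual ~20-30%
  # overfitting probability; the spectral density at zero (and hence the
  # effective size) is what must stay right
  fits <- lapply(1:20, function(s) {
    set.seed(s)
    fit_ar(rnorm(5000))
  })
  expect_gte(mean(vapply(fits, `[[`, integer(1), "order") == 0), 0.6)
  spec0 <- vapply(fits, spectral_density_zero, numeric(1))
  expect_true(all(abs(spec0 - 1) < 0.15))
  fit <- fit_ar(sim_ar1(5000, 0.9, seed = 42))
  expect_gte(fit$order, 1)
  expect_equal(fit$coefficients[1], 0.9, tolerance = 0.05)
  expect_error(fit_ar(rep(1, 100)), class = "bmix_degenerate_series")
  expect_error(fit_ar(rnorm(5)), "at least 8")
})

test_that("effective size matches the AR(1) closed form and clamps", {
  set.seed(7)
  expect_equal(effective_size(rnorm(2000)), 2000, tolerance = 0.1)
  # ESS of AR(1) is n (1 - phi) / (1 + phi)
  ess <- vapply(1:5, function(s) {
    effective_size(sim_ar1(5000, 0.8, seed = 100 + s))
  }, numeric(1))
  expect_equal(mean(ess), 5000 / 9, tolerance = 0.15)
  for (phi in c(0, 0.3, 0.6, 0.9)) {
    ess <- mean(vapply(1:4, function(s) {
      effective_size(if (phi == 0) {
        set.seed(200 + s); rnorm(5000)
      } else {
        sim_ar1(5000, phi, seed = 200 + s)
      })
    }, numeric(1)))
    expect_equal(ess, 5000 * (1 - phi) / (1 + phi), tolerance = 0.15)
  }
  expect_equal(effective_size(rep(2, 500)), 1)
  set.seed(8)
  x <- rnorm(300)
  expect_true(effective_size(x) >= 1 && effective_size(x) <= 300)
})

test_that("effective size is invariant to affine rescaling", {
  set.seed(9)
  x <- sim_ar1(2000, 0.5, seed = 9)
  expect_equal(effective_size(3.7 * x + 11), effective_size(x),
               tolerance = 1e-8)
})

test_that("testing burden aggregates per-sequence effective sizes", {
  panel <- make_panel(500, 40, seed = 10)
  rep_iid <- testing_burden(panel)
  expect_equal(rep_iid$genome_wide, 500, tolerance = 0.1)

  # brute-force aggregation oracle
  ids <- panel_individuals(panel)
  brute <- mean(vapply(ids, function(id) {
    sum(vapply(split(panel[[id]], panel$chrom), effective_size, numeric(1)))
  }, numeric(1)))
  expect_equal(rep_iid$genome_wide, brute, tolerance = 1e-10)

  # one constant ancestry block per chromosome: burden = chromosome count
  n_chrom <- 5
  vals <- matrix(rep(sample(0:2, n_chrom * 8, TRUE), each = 20), ncol = 8)
  blocky <- make_panel(100, 8, n_chrom = n_chrom, values = vals)
  expect_equal(testing_burden(blocky)$genome_wide, n_chrom)

  # single individual, single chromosome: burden equals that effective size
  single <- panel[, c("marker", "chrom", "pos", ids[1])]
  expect_equal(testing_burden(single)$genome_wide,
               effective_size(panel[[ids[1]]]))

  # averaging over individuals is order-free
  perm <- panel[, c("marker", "chrom", "pos", rev(ids))]
  expect_equal(testing_burden(perm)$genome_wide, rep_iid$genome_wide)
})

test_that("missing panel values are mean-imputed and counted", {
  panel <- make_panel(200, 5, seed = 11)
  panel$ind1[c(3, 50)] <- NA
  rep_ <- testing_burden(panel)
  expect_equal(rep_$n_imputed, 2L)
  expect_true(is.finite(rep_$genome_wide))
})

test_that("ancestry switches are counted as adjacent unequal pairs", {
  expect_equal(count_switches(c(0, 0, 0)), 0)
  expect_equal(count_switches(c(0, 0, 1, 1, 2, 1, 1, 0, 0, 0, 1, 1)), 5)
  set.seed(12)
  x <- sample(0:2, 400, TRUE)
  brute <- sum(vapply(seq_len(399), function(i) x[i] != x[i + 1], logical(1)))
  expect_equal(count_switches(x), brute)
  expect_error(count_switches(numeric(0)), "empty")
})

test_that("generations since admixture follow the hybrid-isolation formula", {
  expect_equal(estimate_generations(0, 0.5, 35), 0)
  expect_equal(estimate_generations(4 * 0.25 * 35, 0.5, 35), 1)
  expect_equal(estimate_generations(186, 0.797, 35),
               186 / (4 * 0.797 * 0.203 * 35))
  expect_error(estimate_generations(10, 0, 35), "admixture_prop")
  expect_error(estimate_generations(10, 1, 35), "admixture_prop")
  expect_error(estimate_generations(10, 0.5, 0), "map_length")
})
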