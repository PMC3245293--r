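# Independent oracles used across tests.

# Exact closed form for the df = 1 noncentral/central chi-square density
# ratio: f1(x; 1, l) / f0(x; 1) = exp(-l/2) * cosh(sqrt(l * x)).
oracle_bf <- function(x, ncp) exp(-ncp / 2) * cosh(sqrt(ncp * x))

# Closed-form inverse of the df = 1 Bayes factor: the statistic at which the
# posterior (prior pi) reaches the target.
oracle_required_chisq <- function(prior, target, ncp) {
  K <- (1 - prior) / prior * target / (1 - target)
  acosh(K * exp(ncp / 2))^2 / ncp
}

# Hand-composed posterior via direct density evaluation.
oracle_posterior <- function(p, prior, ncp, df = 1) {
  x <- qchisq(p, df, lower.tail = FALSE)
  f1 <- dchisq(x, df, ncp = ncp)
  f0 <- dchisq(x, df)
  prior * f1 / (prior * f1 + (1 - prior) * f0)
}

# Simulate an AR(1) series with unit-variance innovations.
sim_ar1 <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

# Small iid 0/1/2 panel on one or more chromosomes.
make_panel <- function(n_markers, n_individuals, n_chrom = 1, seed = 1,
                       values = NULL) {
  set.seed(seed)
  chrom <- sort(rep(seq_len(n_chrom), length.out = n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), seq_along),
                use.names = FALSE) * 1000
  m <- if (is.null(values)) {
    matrix(sample(0:2, n_markers * n_individuals, TRUE), n_markers)
  } else {
    values
  }
  colnames(m) <- paste0("ind", seq_len(n_individuals))
  dplyr::bind_cols(
    tibble::tibble(marker = paste0("m", seq_len(n_markers)),
                   chrom = chrom, pos = pos),
    tibble::as_tibble(m)
  )
}
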