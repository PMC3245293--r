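#' Admixture mapping scan
#'
#' Regresses the phenotype on local ancestry marker by marker with a
#' generalized linear model, adjusting for global ancestry and any further
#' covariates, and reports the Wald test of the local-ancestry coefficient.
#'
#' @param data Tibble with one row per individual: an `id` column matching
#'   the panel's individual columns, the phenotype column, and covariates.
#' @param local_ancestry Local-ancestry panel (see [validate_panel()]).
#' @param phenotype Name of the phenotype column in `data`.
#' @param covariates Character vector of covariate column names (default
#'   none beyond global ancestry).
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit link).
#' @param include_global_ancestry Adjust for global ancestry (default TRUE).
#' @param id_col Name of the id column in `data`.
#' @return Tibble with columns `marker`, `chrom`, `pos`, `beta`, `se`, `p`,
#'   `n`, `status` (`"ok"` or a skip reason). Markers with no local-ancestry
#'   variance, or rank-deficient designs, are flagged rather than failing
#'   the scan.
#' @export
admixture_scan <- function(data, local_ancestry, phenotype,
                           covariates = NULL,
                           family = c("gaussian", "binomial"),
                           include_global_ancestry = TRUE,
                           id_col = "id") {
  family <- match.arg(family)
  local_ancestry <- validate_panel(local_ancestry)
  al <- .align_individuals(data, local_ancestry, id_col)
  la <- panel_matrix(local_ancestry)[, al$ids, drop = FALSE]
  ga <- global_ancestry(local_ancestry)[al$ids]
  y <- al$data[[phenotype]]
  .check_phenotype(y, family)
  Z <- .covariate_matrix(al$data, covariates,
                         if (include_global_ancestry) ga else NULL)
  res <- purrr::map_dfr(seq_len(nrow(local_ancestry)), function(j) {
    lj <- la[j, ]
    keep <- !is.na(lj) & !is.na(y) & complete.cases(Z)
    out <- tibble::tibble(beta = NA_real_, se = NA_real_, p = NA_real_,
                          n = sum(keep), status = "ok")
    if (sum(keep) < ncol(Z) + 2) {
      out$status <- "too_few_observations"
      return(out)
    }
    if (var(lj[keep]) == 0) {
      out$status <- "constant_ancestry"
      return(out)
    }
    fit <- .wald_fit(cbind(1, lj[keep], Z[keep, , drop = FALSE]),
                     y[keep], family)
    if (!fit$ok) {
      out$status <- fit$reason
      return(out)
    }
    out$beta <- fit$beta; out$se <- fit$se; out$p <- fit$p
    out
  })
  dplyr::bind_cols(local_ancestry[, c("marker", "chrom", "pos")], res)
}

#' Local-ancestry stratified association scan
#'
#' For every marker, individuals are stratified by their local ancestry
#' (0, 1, or 2 copies) at that marker and, within each stratum, the
#' phenotype is regressed on genotype with a generalized linear model,
#' adjusting for global ancestry and covariates. Stratifying keeps genotype
#' conditionally independent of local ancestry; the per-stratum genotype
#' coefficients are then pooled by inverse-variance fixed effects.
#'
#' Strata with fewer than `min_stratum` usable individuals, with monomorphic
#' genotype, or with degenerate designs are skipped with a reason; a marker
#' needs at least one usable stratum to yield a pooled estimate.
#'
#' @inheritParams admixture_scan
#' @param genotypes Genotype panel aligned with `local_ancestry` on markers.
#' @param min_stratum Minimum stratum size (default 10).
#' @return Tibble with columns `marker`, `chrom`, `pos`, `pooled_beta`,
#'   `pooled_se`, `z`, `p`, `n_strata_ok`, `status`, and a list-column
#'   `strata` of per-stratum tibbles (`stratum`, `beta`, `se`, `n`,
#'   `status`).
#' @export
association_scan <- function(data, genotypes, local_ancestry, phenotype,
                             covariates = NULL,
                             family = c("gaussian", "binomial"),
                             include_global_ancestry = TRUE,
                             min_stratum = 10,
                             id_col = "id") {
  family <- match.arg(family)
  genotypes <- validate_panel(genotypes)
  local_ancestry <- validate_panel(local_ancestry)
  if (!identical(genotypes$marker, local_ancestry$marker)) {
    abort("Genotype and local-ancestry panels are not aligned on markers.")
  }
  if (!setequal(panel_individuals(genotypes),
                panel_individuals(local_ancestry))) {
    abort("Genotype and local-ancestry panels cover different individuals.")
  }
  al <- .align_individuals(data, genotypes, id_col)
  gm <- panel_matrix(genotypes)[, al$ids, drop = FALSE]
  lm_ <- panel_matrix(local_ancestry)[, al$ids, drop = FALSE]
  ga <- global_ancestry(local_ancestry)[al$ids]
  y <- al$data[[phenotype]]
  .check_phenotype(y, family)
  Z <- .covariate_matrix(al$data, covariates,
                         if (include_global_ancestry) ga else NULL)

  res <- purrr::map_dfr(seq_len(nrow(genotypes)), function(j) {
    gj <- gm[j, ]; lj <- lm_[j, ]
    usable <- !is.na(gj) & !is.na(lj) & !is.na(y) & complete.cases(Z)
    strata <- purrr::map_dfr(0:2, function(k) {
      idx <- usable & lj == k
      nk <- sum(idx)
      row <- tibble::tibble(stratum = k, beta = NA_real_, se = NA_real_,
                            n = nk, status = "ok")
      if (nk == 0) {
        row$status <- "skipped(empty)"
        return(row)
      }
      if (nk < min_stratum) {
        row$status <- "skipped(small)"
        return(row)
      }
      if (length(unique(gj[idx])) < 2) {
        row$status <- "skipped(monomorphic)"
        return(row)
      }
      X <- cbind(1, gj[idx], Z[idx, , drop = FALSE])
      # within a stratum some covariates (notably global ancestry at a
      # single-marker panel) can be constant; drop constant columns
      keep_col <- c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2,
                                      function(v) var(v) > 0))
      fit <- .wald_fit(X[, keep_col, drop = FALSE], y[idx], family)
      if (!fit$ok) {
        row$status <- paste0("skipped(", fit$reason, ")")
        return(row)
      }
      row$beta <- fit$beta; row$se <- fit$se
      row
    })
    pooled <- pool_fixed_effects(strata)
    tibble::tibble(
      pooled_beta = pooled$pooled_beta,
      pooled_se = pooled$pooled_se,
      z = if (is.na(pooled$pooled_se)) NA_real_ else
        pooled$pooled_beta / pooled$pooled_se,
      p = if (is.na(pooled$pooled_se)) NA_real_ else
        association_pvalue(pooled$pooled_beta, pooled$pooled_se),
      n_strata_ok = sum(strata$status == "ok"),
      status = if (any(strata$status == "ok")) "ok" else "no_usable_stratum",
      strata = list(strata)
    )
  })
  dplyr::bind_cols(genotypes[, c("marker", "chrom", "pos")], res)
}

#' Inverse-variance fixed-effects pooling of per-stratum estimates
#'
#' Combines per-stratum genotype coefficients with weights
#' \eqn{w_k = 1/se_k^2}: the pooled coefficient is
#' \eqn{\sum w_k \beta_k / \sum w_k} and its standard error
#' \eqn{\sqrt{1/\sum w_k}}.
#'
#' @param estimates A tibble (or data frame) with columns `beta`, `se` and
#'   optionally `status` (only rows with `status == "ok"` are pooled; absent
#'   a status column, rows with finite `beta` and `se > 0` are used).
#' @return A list with `pooled_beta` and `pooled_se` (both `NA` when no
#'   stratum is usable).
#' @examples
#' pool_fixed_effects(data.frame(beta = c(1, 3), se = c(1, 1)))
#' @export
pool_fixed_effects <- function(estimates) {
  ok <- if ("status" %in% names(estimates)) {
    estimates$status == "ok"
  } else {
    is.finite(estimates$beta) & is.finite(estimates$se) & estimates$se > 0
  }
  ok <- ok & is.finite(estimates$beta) & is.finite(estimates$se) &
    estimates$se > 0
  if (!any(ok)) {
    return(list(pooled_beta = NA_real_, pooled_se = NA_real_))
  }
  w <- 1 / estimates$se[ok]^2
  list(
    pooled_beta = sum(w * estimates$beta[ok]) / sum(w),
    pooled_se = sqrt(1 / sum(w))
  )
}

#' Two-sided association p-value from a pooled estimate
#'
#' The pooled test statistic `beta/se` follows the standard normal
#' distribution under the null.
#'
#' @param pooled_beta,pooled_se Pooled coefficient and standard error.
#' @return Two-sided p-values.
#' @export
association_pvalue <- function(pooled_beta, pooled_se) {
  if (any(!is.finite(pooled_se) | pooled_se <= 0)) {
    abort("`pooled_se` must be positive and finite.")
  }
  2 * pnorm(-abs(pooled_beta / pooled_se))
}

#' Genomic-control inflation factor
#'
#' The ratio of the median of the chi-square statistics implied by the
#' p-values to the null chi-square(1) median (0.4549...). Values near 1
#' indicate no residual stratification.
#'
#' @param pvalues At least 100 finite p-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
genomic_control_lambda <- function(pvalues) {
  pvalues <- pvalues[is.finite(pvalues)]
  if (length(pvalues) < 100) {
    abort("Need at least 100 finite p-values to estimate lambda.")
  }
  .assert_prob(pvalues, "pvalues", open_left = TRUE, open_right = FALSE)
  median(qchisq(pvalues, 1, lower.tail = FALSE)) /
    qchisq(0.5, 1, lower.tail = FALSE)
}

# --- internal helpers -------------------------------------------------------

.align_individuals <- function(data, panel, id_col) {
  if (!id_col %in% names(data)) {
    abort(sprintf("`data` has no id column `%s`.", id_col))
  }
  ids_panel <- panel_individuals(panel)
  ids_data <- as.character(data[[id_col]])
  ids <- intersect(ids_data, ids_panel)
  if (length(ids) == 0) {
    abort("No individuals shared between `data` and the panel.")
  }
  n_dropped <- length(unique(c(ids_data, ids_panel))) - length(ids)
  data <- data[match(ids, ids_data), , drop = FALSE]
  list(data = data, ids = ids, n_dropped = n_dropped)
}

.covariate_matrix <- function(data, covariates, global_ancestry = NULL) {
  cols <- list()
  if (!is.null(global_ancestry)) cols$global_ancestry <- global_ancestry
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(sprintf("Covariate `%s` not in data.", cv))
    v <- data[[cv]]
    if (!is.numeric(v)) v <- as.numeric(as.factor(v)) - 1
    cols[[cv]] <- v
  }
  if (length(cols) == 0) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  do.call(cbind, cols)
}

.check_phenotype <- function(y, family) {
  if (!is.numeric(y)) abort("Phenotype must be numeric.")
  if (family == "binomial" && !all(y[!is.na(y)] %in% c(0, 1))) {
    abort("Binomial phenotypes must be coded 0/1.")
  }
}
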