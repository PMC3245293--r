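# Marker panels are plain tibbles with markers in rows: three metadata
# columns (`marker`, `chrom`, `pos`) followed by one integer 0/1/2 column per
# individual. Local-ancestry panels count chromosome copies inherited from
# the first parental population; genotype panels count copies of the counted
# (minor) allele.

#' Validate a marker panel
#'
#' Checks the panel layout used throughout the package: columns `marker`,
#' `chrom`, `pos` followed by one column per individual; values 0, 1, 2 or
#' `NA`; unique marker ids; positions strictly increasing within chromosome.
#'
#' @param panel A tibble (markers in rows).
#' @return The validated panel (invisibly usable in pipes).
#' @export
validate_panel <- function(panel) {
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(panel))) {
    abort(sprintf("Panel must have columns %s.",
                  paste(sprintf("`%s`", need), collapse = ", ")))
  }
  ids <- setdiff(names(panel), need)
  if (length(ids) == 0) abort("Panel has no individual columns.")
  if (anyDuplicated(panel$marker)) {
    dup <- panel$marker[duplicated(panel$marker)][1]
    abort(sprintf("Duplicate marker id: %s.", dup))
  }
  for (chr in unique(panel$chrom)) {
    pos <- panel$pos[panel$chrom == chr]
    if (any(diff(pos) <= 0)) {
      abort(sprintf(
        "Positions on chromosome %s are not strictly increasing.", chr
      ), class = "bmix_ordering_error")
    }
  }
  for (id in ids) {
    v <- panel[[id]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad)) {
      abort(sprintf(
        "Invalid value %s at marker %s, individual %s (allowed: 0, 1, 2, NA).",
        v[bad[1]], panel$marker[bad[1]], id
      ))
    }
  }
  tibble::as_tibble(panel)
}

#' Individual ids of a marker panel
#' @param panel A validated marker panel.
#' @return Character vector of individual column names.
#' @export
panel_individuals <- function(panel) {
  setdiff(names(panel), c("marker", "chrom", "pos"))
}

#' Panel values as a markers x individuals matrix
#' @param panel A validated marker panel.
#' @return Numeric matrix with marker ids as row names.
#' @export
panel_matrix <- function(panel) {
  ids <- panel_individuals(panel)
  m <- as.matrix(panel[, ids, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- panel$marker
  m
}

#' Global ancestry from a local-ancestry panel
#'
#' Global (individual) ancestry is local ancestry averaged across all
#' markers, rescaled from copy counts to a proportion in `[0, 1]`.
#'
#' @param local_ancestry A local-ancestry panel.
#' @return Named numeric vector of admixture proportions, one per individual.
#' @export
global_ancestry <- function(local_ancestry) {
  m <- panel_matrix(local_ancestry)
  colMeans(m, na.rm = TRUE) / 2
}
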