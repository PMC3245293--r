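# File formats: marker panels are tab-delimited with markers in rows and
# header `marker  chrom  pos  <id1> <id2> ...`; values 0/1/2 or NA.
# Genotypes may also come as a biallelic VCF (GT field), recoded to counts
# of the minor allele in the analysed sample.

#' Read a local-ancestry panel (LAMP-style TSV)
#'
#' @param path Path to a tab-delimited file with columns `marker`, `chrom`,
#'   `pos` and one 0/1/2 column per individual (`NA` for missing).
#' @return A validated marker panel tibble.
#' @export
read_local_ancestry <- function(path) {
  .read_panel_tsv(path)
}

#' Read a genotype panel (TSV or VCF)
#'
#' TSV input uses the same layout as [read_local_ancestry()], already coded
#' as minor-allele counts. VCF input must be biallelic with GT fields;
#' genotypes are recoded to 0/1/2 copies of the minor allele as observed in
#' the sample, with frequency ties at 0.5 broken in favour of the
#' alphabetically first allele string; the counted allele per marker is
#' recorded in the `allele_info` attribute. Markers with all genotypes
#' missing are dropped with a warning.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return A validated marker panel tibble (genotype kind). For VCF input
#'   the attribute `allele_info` is a tibble with `marker`, `ref`, `alt`,
#'   `counted`.
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  format <- match.arg(format, c("tsv", "vcf"))
  if (format == "tsv") {
    return(.read_panel_tsv(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == ""
  if (any(multi)) {
    warn(sprintf("Dropping %d non-biallelic site(s).", sum(multi)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- which(!multi)
  rows <- list()
  alleles <- list()
  for (i in keep) {
    codes <- gt[i, ]
    alt_count <- vapply(codes, function(code) {
      if (is.na(code) || code %in% c(".", "./.", ".|.")) return(NA_real_)
      parts <- strsplit(code, "[/|]")[[1]]
      if (any(parts == ".")) return(NA_real_)
      sum(as.integer(parts))
    }, numeric(1))
    if (all(is.na(alt_count))) {
      warn(sprintf("Dropping marker %s: all genotypes missing.", fix$ID[i]))
      next
    }
    af_alt <- mean(alt_count, na.rm = TRUE) / 2
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    count_alt <- if (af_alt < 0.5) {
      TRUE
    } else if (af_alt > 0.5) {
      FALSE
    } else {
      # tie: count the alphabetically first allele
      alt < ref
    }
    counts <- if (count_alt) alt_count else 2 - alt_count
    id <- if (is.na(fix$ID[i]) || fix$ID[i] == ".") {
      paste0(fix$CHROM[i], ":", fix$POS[i])
    } else {
      fix$ID[i]
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker = id, chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
      !!!setNames(as.list(counts), colnames(gt))
    )
    alleles[[length(alleles) + 1]] <- tibble::tibble(
      marker = id, ref = ref, alt = alt,
      counted = if (count_alt) alt else ref
    )
  }
  if (length(rows) == 0) abort("No usable biallelic markers in VCF.")
  panel <- validate_panel(dplyr::bind_rows(rows))
  attr(panel, "allele_info") <- dplyr::bind_rows(alleles)
  panel
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited, one row per individual, with an id column; binary
#' phenotypes coded 0/1.
#'
#' @param path Input file.
#' @param id_col Name of the id column (default `"id"`).
#' @return A tibble.
#' @export
read_phenotypes <- function(path, id_col = "id") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!id_col %in% names(tbl)) {
    abort(sprintf("Phenotype file has no `%s` column.", id_col))
  }
  tbl[[id_col]] <- as.character(tbl[[id_col]])
  if (anyDuplicated(tbl[[id_col]])) abort("Duplicate individual ids.")
  tbl
}

#' Write a marker panel as TSV
#'
#' Writers and readers are closed under round-trip: a written panel reads
#' back identically.
#'
#' @param panel A validated marker panel.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}

#' Write a per-marker results table as TSV
#'
#' Fixed column order as produced by [bmix()]; floating-point columns are
#' written with 6 significant digits and posteriors with 6 decimals.
#'
#' @param results Results tibble (e.g. `tidy(fit)`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  fmt <- results
  for (nm in names(fmt)) {
    if (grepl("posterior", nm)) {
      fmt[[nm]] <- ifelse(is.na(fmt[[nm]]), NA, sprintf("%.6f", fmt[[nm]]))
    } else if (is.double(fmt[[nm]])) {
      fmt[[nm]] <- ifelse(is.na(fmt[[nm]]), NA,
                          formatC(fmt[[nm]], digits = 6, format = "g"))
    }
  }
  readr::write_tsv(fmt, path, progress = FALSE)
  invisible(path)
}

.read_panel_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("NA", "")),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path,
                                      conditionMessage(e)))
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("Parse error in %s at line %d: %s",
                  path, prob$row[1] + 1, prob$expected[1]))
  }
  validate_panel(tbl)
}
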