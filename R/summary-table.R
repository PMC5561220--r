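#' Read a GWAS summary-statistic table
#'
#' Reads a tab-delimited file of per-SNP summary associations (one row per
#' SNP) into a validated tibble. The canonical header is
#' `rsid effect_allele other_allele eaf beta se pvalue n`; files with other
#' column names are mapped via `column_map`. `NA` is accepted for the
#' optional fields `eaf` and `n`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(rsid = "SNP", beta = "Effect")`.
#'   Names not listed are assumed to match the canonical header.
#' @param trait Optional trait label attached as the `"trait"` attribute.
#'
#' @return A tibble of class `mr_summary` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   Alleles are upper-cased. Invalid rows abort with an informative error.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tn",
#'              "rs1\ta\tg\t0.3\t0.12\t0.02\t2e-9\t10000"), tf)
#' read_summary_table(tf, trait = "hsCRP")
read_summary_table <- function(path, column_map = NULL, trait = NULL) {
  # base parser: correctly-rounded strtod, so printed values round-trip
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  canonical <- c("rsid", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "pvalue", "n")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad) > 0)
      abort(paste0("Unknown canonical column(s) in `column_map`: ",
                   paste(bad, collapse = ", ")))
    map[names(column_map)] <- unname(column_map)
  }
  required <- canonical[!canonical %in% c("eaf", "n")]
  missing_cols <- setdiff(unname(map[required]), names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("Column(s) not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrpipe_config_error")
  get_col <- function(nm) {
    if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else NA
  }
  out <- tibble::tibble(
    rsid          = as.character(get_col("rsid")),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele  = toupper(as.character(get_col("other_allele"))),
    eaf           = suppressWarnings(as.numeric(get_col("eaf"))),
    beta          = suppressWarnings(as.numeric(get_col("beta"))),
    se            = suppressWarnings(as.numeric(get_col("se"))),
    pvalue        = suppressWarnings(as.numeric(get_col("pvalue"))),
    n             = suppressWarnings(as.numeric(get_col("n")))
  )
  new_summary_table(out, trait = trait)
}

#' Construct and validate a summary table
#'
#' Validates per-SNP summary associations and returns them as an
#' `mr_summary` tibble. Useful when associations are already in memory
#' (e.g. from a simulation) rather than on disk.
#'
#' @param data A data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `eaf`, `n`.
#' @param trait Optional trait label.
#' @return A validated `mr_summary` tibble.
#' @export
new_summary_table <- function(data, trait = NULL) {
  data <- tibble::as_tibble(data)
  for (col in c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue"))
    if (!col %in% names(data))
      abort(paste0("Summary table lacks required column `", col, "`"),
            class = "mrpipe_config_error")
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  if (!"n" %in% names(data)) data$n <- NA_real_
  data <- dplyr::relocate(data, "rsid", "effect_allele", "other_allele",
                          "eaf", "beta", "se", "pvalue", "n")

  dup <- unique(data$rsid[duplicated(data$rsid)])
  if (length(dup) > 0)
    abort(paste0("Duplicate rsid(s) in summary table: ",
                 paste(dup, collapse = ", ")),
          class = "mrpipe_validation_error")
  bad_allele <- !(data$effect_allele %in% c("A", "C", "G", "T")) |
    !(data$other_allele %in% c("A", "C", "G", "T")) |
    data$effect_allele == data$other_allele
  if (any(bad_allele))
    abort(paste0("Invalid allele pair for: ",
                 paste(data$rsid[bad_allele], collapse = ", "),
                 " (alleles must be distinct A/C/G/T)"),
          class = "mrpipe_validation_error")
  bad_se <- !is.finite(data$se) | data$se <= 0
  if (any(bad_se))
    abort(paste0("Non-positive or missing se for: ",
                 paste(data$rsid[bad_se], collapse = ", ")),
          class = "mrpipe_validation_error")
  bad_beta <- !is.finite(data$beta)
  if (any(bad_beta))
    abort(paste0("Missing beta for: ",
                 paste(data$rsid[bad_beta], collapse = ", ")),
          class = "mrpipe_validation_error")
  bad_p <- !is.finite(data$pvalue) | data$pvalue <= 0 | data$pvalue > 1
  if (any(bad_p))
    abort(paste0("p-value outside (0, 1] for: ",
                 paste(data$rsid[bad_p], collapse = ", ")),
          class = "mrpipe_validation_error")
  bad_eaf <- !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1)
  if (any(bad_eaf))
    abort(paste0("eaf outside [0, 1] for: ",
                 paste(data$rsid[bad_eaf], collapse = ", ")),
          class = "mrpipe_validation_error")

  class(data) <- c("mr_summary", class(data))
  attr(data, "trait") <- trait
  data
}

#' Write a summary table to a tab-delimited file
#'
#' Inverse of [read_summary_table()]; numeric fields are written at full
#' precision so a read/write cycle round-trips exactly.
#'
#' @param data An `mr_summary` tibble (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(data, path) {
  out <- as.data.frame(data)[, c("rsid", "effect_allele", "other_allele",
                                 "eaf", "beta", "se", "pvalue", "n")]
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a signed LD correlation matrix
#'
#' Reads a square tab-delimited matrix of signed pairwise correlations
#' (r, not r-squared) keyed by rsID on both the header row and the first
#' column. Asymmetries up to 1e-10 are symmetrized by averaging; anything
#' larger, a non-unit diagonal, entries outside [-1, 1], or a matrix that
#' is not positive semi-definite (minimum eigenvalue below -1e-8) is a
#' validation error.
#'
#' @param path Path to the tab-delimited matrix file.
#' @return A numeric matrix with rsID dimnames, validated as above.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  r <- as.matrix(raw)
  storage.mode(r) <- "double"
  new_ld_matrix(r, rsids = rownames(raw))
}

#' Construct and validate an LD matrix
#'
#' @param r Square numeric matrix of signed correlations.
#' @param rsids Character vector of rsIDs; defaults to `rownames(r)`.
#' @return The validated, exactly symmetric matrix with rsID dimnames.
#' @export
new_ld_matrix <- function(r, rsids = rownames(r)) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    abort("LD matrix must be square", class = "mrpipe_validation_error")
  if (is.null(rsids) || length(rsids) != nrow(r) || anyDuplicated(rsids) > 0)
    abort("LD matrix needs unique rsIDs on rows and columns",
          class = "mrpipe_validation_error")
  asym <- max(abs(r - t(r)))
  if (asym > 1e-10)
    abort(sprintf("LD matrix asymmetric beyond tolerance (max |r - t(r)| = %.3g)",
                  asym),
          class = "mrpipe_validation_error")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-10)
    abort("LD matrix diagonal must be 1", class = "mrpipe_validation_error")
  if (max(abs(r)) > 1 + 1e-12)
    abort("LD correlations must lie in [-1, 1]",
          class = "mrpipe_validation_error")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort(sprintf("LD matrix not positive semi-definite (min eigenvalue %.3g)",
                  min(ev)),
          class = "mrpipe_validation_error")
  dimnames(r) <- list(rsids, rsids)
  r
}

#' Write an LD matrix to a tab-delimited file
#'
#' @param r LD matrix with rsID dimnames (see [new_ld_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  out <- as.data.frame(r)
  utils::write.table(cbind(rsid = rownames(r), out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
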