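#' Prune correlated instruments, keeping the smallest p-values
#'
#' Greedy LD pruning: SNPs are visited in order of ascending p-value (ties
#' broken by rsID) and a SNP is accepted only if its squared correlation
#' with every already-accepted SNP is below `r2_threshold`. Output rows
#' keep their input order.
#'
#' @param data An `mr_summary` tibble.
#' @param ld LD matrix (signed r) with rsID dimnames covering every rsID in
#'   `data`.
#' @param r2_threshold Squared-correlation threshold in (0, 1]; SNP pairs
#'   at or above it are considered redundant. Default 0.8.
#' @return The pruned summary tibble; discarded SNPs are recorded in
#'   `attr(, "pruned")` as a tibble of `rsid` and the kept `rsid` that
#'   displaced it.
#' @export
ld_prune <- function(data, ld, r2_threshold = 0.8) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  missing <- setdiff(data$rsid, rownames(ld))
  if (length(missing) > 0)
    abort(paste0("rsID(s) absent from LD matrix: ",
                 paste(missing, collapse = ", ")),
          class = "mrpipe_validation_error")
  ord <- order(data$pvalue, data$rsid)
  accepted <- character(0)
  pruned <- list()
  for (i in ord) {
    rs <- data$rsid[i]
    r2 <- ld[rs, accepted, drop = TRUE]^2
    if (length(accepted) == 0 || all(r2 < r2_threshold)) {
      accepted <- c(accepted, rs)
    } else {
      pruned[[length(pruned) + 1]] <- tibble::tibble(
        rsid = rs, displaced_by = accepted[which(r2 >= r2_threshold)[1]])
    }
  }
  out <- data[data$rsid %in% accepted, ]
  attr(out, "trait") <- attr(data, "trait")
  attr(out, "pruned") <- if (length(pruned)) dplyr::bind_rows(pruned) else
    tibble::tibble(rsid = character(), displaced_by = character())
  out
}

#' Substitute proxy SNPs for instruments missing from the outcome data
#'
#' Each instrument absent from `available` (typically the outcome study's
#' rsID set) is replaced by its highest-r-squared proxy that is available
#' and meets `proxy_r2_threshold`; instruments with no eligible proxy are
#' dropped. When `proxy_stats` contains the proxy SNP, its published
#' association replaces the original row wholesale; otherwise only the
#' rsID is substituted and the original effect and SE are retained (the
#' two are nearly interchangeable at high r-squared).
#'
#' @param data An `mr_summary` tibble of instruments.
#' @param available Character vector of rsIDs present in the outcome data.
#' @param proxies Data frame with columns `original_rsid`, `proxy_rsid`,
#'   `r2` (see [read_proxy_table()]).
#' @param proxy_r2_threshold Minimum r-squared for an acceptable proxy
#'   (default 0.8).
#' @param proxy_stats Optional `mr_summary` table holding the proxies' own
#'   exposure associations.
#' @return The summary tibble after substitution; the substitution log —
#'   one row per input SNP with `action` in
#'   `kept`/`substituted`/`dropped` — is in `attr(, "substitutions")`.
#' @export
apply_proxies <- function(data, available, proxies,
                          proxy_r2_threshold = 0.8, proxy_stats = NULL) {
  log <- vector("list", nrow(data))
  rows <- vector("list", nrow(data))
  for (j in seq_len(nrow(data))) {
    rs <- data$rsid[j]
    if (rs %in% available) {
      rows[[j]] <- data[j, ]
      log[[j]] <- tibble::tibble(rsid = rs, action = "kept",
                                 proxy_rsid = NA_character_, r2 = NA_real_)
      next
    }
    cand <- proxies[proxies$original_rsid == rs &
                      proxies$r2 >= proxy_r2_threshold &
                      proxies$proxy_rsid %in% available, , drop = FALSE]
    if (nrow(cand) == 0) {
      log[[j]] <- tibble::tibble(rsid = rs, action = "dropped",
                                 proxy_rsid = NA_character_, r2 = NA_real_)
      next
    }
    best <- cand[which.max(cand$r2), ]
    if (!is.null(proxy_stats) && best$proxy_rsid %in% proxy_stats$rsid) {
      rows[[j]] <- proxy_stats[proxy_stats$rsid == best$proxy_rsid, ]
    } else {
      rows[[j]] <- dplyr::mutate(data[j, ], rsid = best$proxy_rsid)
    }
    log[[j]] <- tibble::tibble(rsid = rs, action = "substituted",
                               proxy_rsid = best$proxy_rsid, r2 = best$r2)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out <- new_summary_table(out, trait = attr(data, "trait"))
  attr(out, "substitutions") <- dplyr::bind_rows(log)
  out
}

#' Read a proxy-substitution table
#'
#' Tab-delimited file with header `original_rsid proxy_rsid r2`.
#'
#' @param path File path.
#' @return A tibble with those three columns; `r2` validated to [0, 1].
#' @export
read_proxy_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("original_rsid", "proxy_rsid", "r2"))
    if (!col %in% names(x))
      abort(paste0("Proxy table lacks column `", col, "`"),
            class = "mrpipe_config_error")
  if (any(x$r2 < 0 | x$r2 > 1))
    abort("Proxy r2 must lie in [0, 1]", class = "mrpipe_validation_error")
  x
}

#' Read a pleiotropy-flag annotation table
#'
#' Tab-delimited file with header `rsid label`, one row per flagged
#' phenotype per SNP (e.g. an obesity-related trait found for the SNP in a
#' genome-annotation search).
#'
#' @param path File path.
#' @return A tibble with columns `rsid`, `label`.
#' @export
read_flags_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("rsid", "label"))
    if (!col %in% names(x))
      abort(paste0("Flags table lacks column `", col, "`"),
            class = "mrpipe_config_error")
  if (any(is.na(x$label) | x$label == ""))
    abort("Every flagged rsid needs a non-empty label",
          class = "mrpipe_validation_error")
  x
}

#' Exclude potentially pleiotropic SNPs
#'
#' Removes instruments whose rsID is listed in `exclude` directly, or whose
#' pleiotropy flag carries a label listed in `exclude`. Typical use: a
#' sensitivity analysis excluding SNPs annotated with phenotypes that could
#' affect the outcome other than via the exposure.
#'
#' @param data An `mr_summary` tibble.
#' @param flags Optional flags tibble (`rsid`, `label`); see
#'   [read_flags_table()].
#' @param exclude Character vector of rsIDs and/or flag labels to exclude.
#' @return The filtered tibble; removed rsIDs in `attr(, "removed")`.
#'   Excluding an rsID not present leaves the table unchanged with a
#'   warning.
#' @export
exclude_flagged <- function(data, flags = NULL, exclude = character(0)) {
  exclude <- as.character(exclude)
  by_rsid <- data$rsid %in% exclude
  by_label <- rep(FALSE, nrow(data))
  if (!is.null(flags) && length(exclude) > 0) {
    flagged <- unique(flags$rsid[flags$label %in% exclude])
    by_label <- data$rsid %in% flagged
  }
  drop <- by_rsid | by_label
  unknown <- setdiff(exclude,
                     c(data$rsid, if (!is.null(flags)) flags$label))
  if (length(unknown) > 0)
    warn(paste0("Exclusion(s) not found in table or flags: ",
                paste(unknown, collapse = ", ")))
  out <- data[!drop, ]
  attr(out, "trait") <- attr(data, "trait")
  attr(out, "removed") <- data$rsid[drop]
  out
}

#' Instrument strength: variance explained and F-statistic
#'
#' For a variance-standardized trait, a SNP with effect-allele frequency
#' `p` and per-allele effect `beta` explains R2 = 2 p (1 - p) beta^2 of the
#' trait variance, and its single-instrument F-statistic is
#' F = R2 (n - 2) / (1 - R2). F below 10 is conventionally taken to signal
#' weak-instrument bias. The formula assumes `beta` is on a standardized
#' trait scale (SD units or comparable); for unstandardized effects divide
#' beta by the trait SD first.
#'
#' @param data An `mr_summary` tibble (or any data frame with `rsid`,
#'   `eaf`, `beta`, `n`).
#' @return A tibble with one row per SNP: `rsid`, `r2`, `f_statistic`,
#'   `weak` (TRUE iff F < 10).
#' @export
#' @examples
#' tab <- new_summary_table(data.frame(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G",
#'   eaf = 0.5, beta = 0.1, se = 0.01, pvalue = 1e-20, n = 10000))
#' f_statistic(tab)  # R2 = 0.005, F ~ 50.2
f_statistic <- function(data) {
  if (any(is.na(data$eaf)))
    abort(paste0("F-statistic needs eaf; missing for: ",
                 paste(data$rsid[is.na(data$eaf)], collapse = ", ")),
          class = "mrpipe_missing_eaf_error")
  if (any(is.na(data$n)))
    abort(paste0("F-statistic needs sample size n; missing for: ",
                 paste(data$rsid[is.na(data$n)], collapse = ", ")),
          class = "mrpipe_missing_n_error")
  r2 <- 2 * data$eaf * (1 - data$eaf) * data$beta^2
  if (any(r2 >= 1))
    abort(paste0("R2 >= 1 (inconsistent eaf/beta inputs) for: ",
                 paste(data$rsid[r2 >= 1], collapse = ", ")),
          class = "mrpipe_validation_error")
  f <- r2 * (data$n - 2) / (1 - r2)
  tibble::tibble(rsid = data$rsid, r2 = r2, f_statistic = f, weak = f < 10)
}
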