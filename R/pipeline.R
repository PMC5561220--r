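#' Configure a full MR analysis
#'
#' Bundles the inputs and tuning parameters for [run_mr_analysis()]. Each
#' exposure is a list with elements `name`, `data` (an `mr_summary` tibble
#' or a file path), and optionally `ld` (matrix or path), `proxies` (proxy
#' table or path), `flags` (flags table or path) and `exclude` (rsIDs or
#' flag labels for the sensitivity variant). Each outcome is a list with
#' `name` and `data`.
#'
#' The significance threshold defaults to 0.05 divided by the number of
#' exposures — the Bonferroni-style rule for testing several candidate
#' exposures (0.0125 for four inflammatory markers).
#'
#' @param exposures,outcomes Lists of exposure/outcome specs (above).
#' @param methods Estimators to run: subset of `c("ivw", "wm", "egger")`.
#' @param effects_model IVW effects model rule (default `"auto"`: fixed
#'   with <= 3 SNPs, random with >= 4; re-evaluated per analysis variant).
#' @param alpha Significance threshold; default `0.05 / length(exposures)`.
#' @param r2_threshold LD-pruning threshold (default 0.8).
#' @param proxy_r2_threshold Minimum proxy r-squared (default 0.8).
#' @param palindrome_policy,eaf_window Harmonization controls; see
#'   [harmonize()].
#' @param ld_r_threshold Residual-correlation trigger: after pruning, the
#'   LD-aware GLS replaces plain IVW when any remaining off-diagonal |r|
#'   exceeds this (default 0.1).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Integer seed driving every stochastic step; required.
#' @return An `mr_analysis_config` list.
#' @export
mr_config <- function(exposures, outcomes,
                      methods = c("ivw", "wm", "egger"),
                      effects_model = "auto", alpha = NULL,
                      r2_threshold = 0.8, proxy_r2_threshold = 0.8,
                      palindrome_policy = "frequency", eaf_window = 0.08,
                      ld_r_threshold = 0.1, n_boot = 2000, seed) {
  if (missing(seed) || is.null(seed))
    abort("Analysis config needs an explicit `seed`",
          class = "mrpipe_config_error")
  if (length(exposures) == 0 || length(outcomes) == 0)
    abort("Need at least one exposure and one outcome",
          class = "mrpipe_config_error")
  alpha <- alpha %||% (0.05 / length(exposures))
  if (alpha <= 0 || alpha >= 1)
    abort("alpha must lie in (0, 1)", class = "mrpipe_config_error")
  name_of <- function(x, i, what)
    x$name %||% abort(paste0(what, " ", i, " needs a `name`"),
                      class = "mrpipe_config_error")
  for (i in seq_along(exposures)) name_of(exposures[[i]], i, "Exposure")
  for (i in seq_along(outcomes)) name_of(outcomes[[i]], i, "Outcome")
  structure(list(exposures = exposures, outcomes = outcomes,
                 methods = methods, effects_model = effects_model,
                 alpha = alpha, r2_threshold = r2_threshold,
                 proxy_r2_threshold = proxy_r2_threshold,
                 palindrome_policy = palindrome_policy,
                 eaf_window = eaf_window, ld_r_threshold = ld_r_threshold,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "mr_analysis_config")
}

resolve_table <- function(x, trait, reader = read_summary_table) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    if (identical(reader, read_summary_table))
      return(reader(x, trait = trait))
    return(reader(x))
  }
  x
}

#' Run the full MR study design
#'
#' For every exposure x outcome pair: LD-prune the instruments, substitute
#' proxies for SNPs absent from the outcome data, harmonize alleles, and
#' run the requested estimators twice — once on all surviving SNPs and
#' once excluding the flagged (potentially pleiotropic) SNPs. Infeasible
#' estimators (weighted median and MR-Egger need more than two SNPs)
#' appear as NA rows rather than being dropped, so the report keeps its
#' full shape. Deterministic given the config seed.
#'
#' @param config An `mr_analysis_config` from [mr_config()].
#' @return A tibble of class `mr_report`, one row per
#'   exposure x outcome x variant x method, with columns `exposure`,
#'   `outcome`, `variant` (`"all"` or `"excluded"`), `method`, `n_snps`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pvalue`, `significant`
#'   (pvalue < alpha), `effects_model`, `intercept`, `intercept_se`,
#'   `intercept_pvalue`, `feasible`. The per-SNP audit trail — every
#'   pruning, proxy, harmonization and exclusion event — is in
#'   `attr(, "audit")`; `attr(, "alpha")` records the threshold used.
#' @export
run_mr_analysis <- function(config) {
  stopifnot(inherits(config, "mr_analysis_config"))
  rows <- list()
  audit <- list()
  log_event <- function(expo, outc, rsid, stage, detail = NA_character_) {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      exposure = expo, outcome = outc, rsid = rsid, stage = stage,
      detail = detail)
  }

  for (ei in seq_along(config$exposures)) {
    ex <- config$exposures[[ei]]
    expo_name <- ex$name
    expo <- resolve_table(ex$data, expo_name)
    ld <- if (!is.null(ex$ld)) resolve_table(ex$ld, NULL, read_ld_matrix)
    proxies <- if (!is.null(ex$proxies))
      resolve_table(ex$proxies, NULL, read_proxy_table)
    flags <- if (!is.null(ex$flags))
      resolve_table(ex$flags, NULL, read_flags_table)
    exclude <- ex$exclude %||% character(0)

    if (!is.null(ld)) {
      pruned <- ld_prune(expo, ld, config$r2_threshold)
      plog <- attr(pruned, "pruned")
      if (nrow(plog) > 0)
        log_event(expo_name, NA_character_, plog$rsid, "pruned",
                  paste0("r2 >= ", config$r2_threshold, " with ",
                         plog$displaced_by))
      expo <- pruned
    }

    for (oi in seq_along(config$outcomes)) {
      ou <- config$outcomes[[oi]]
      out_name <- ou$name
      outc <- resolve_table(ou$data, out_name)
      tab <- expo
      if (!is.null(proxies)) {
        tab <- apply_proxies(tab, outc$rsid, proxies,
                             config$proxy_r2_threshold)
        slog <- attr(tab, "substitutions")
        subbed <- slog[slog$action == "substituted", ]
        dropped <- slog[slog$action == "dropped", ]
        if (nrow(subbed) > 0)
          log_event(expo_name, out_name, subbed$rsid, "proxied",
                    paste0("replaced by ", subbed$proxy_rsid))
        if (nrow(dropped) > 0)
          log_event(expo_name, out_name, dropped$rsid, "dropped",
                    "absent from outcome, no eligible proxy")
      }
      h <- harmonize(tab, outc,
                     palindrome_policy = config$palindrome_policy,
                     eaf_window = config$eaf_window)
      hx <- attr(h, "excluded")
      if (nrow(hx) > 0)
        log_event(expo_name, out_name, hx$rsid, "harmonization_excluded",
                  hx$reason)

      sub_ld <- NULL
      if (!is.null(ld)) {
        if (all(h$rsid %in% rownames(ld))) {
          sub_ld <- new_ld_matrix(ld[h$rsid, h$rsid, drop = FALSE])
        } else {
          inform(paste0("LD matrix lacks some analysed rsIDs for ",
                        expo_name, " x ", out_name,
                        "; treating instruments as uncorrelated"))
        }
      }
      variants <- list(all = h)
      keep_tab <- exclude_flagged(tab, flags, exclude)
      removed <- attr(keep_tab, "removed")
      if (length(removed) > 0)
        log_event(expo_name, out_name, removed, "pleiotropy_excluded",
                  "flagged")
      variants$excluded <- h[!h$rsid %in% removed, ]

      for (vn in names(variants)) {
        hv <- variants[[vn]]
        if (nrow(hv) == 0)
          abort(paste0("No SNPs left for ", expo_name, " x ", out_name,
                       " (variant ", vn, ")"),
                class = "mrpipe_empty_error")
        log_event(expo_name, out_name, hv$rsid, "used",
                  paste0("variant ", vn))
        use_ld <- FALSE
        if (!is.null(sub_ld)) {
          r_off <- sub_ld[hv$rsid, hv$rsid, drop = FALSE]
          diag(r_off) <- 0
          use_ld <- max(abs(r_off)) > config$ld_r_threshold
        }
        # bootstrap seed fixed per exposure x outcome cell, so the two
        # variants differ only through the exclusion list
        cell_seed <- as.integer((as.numeric(config$seed) +
                                   7919 * ei + 104729 * oi) %%
                                  .Machine$integer.max)
        est <- mr_estimates(
          if (use_ld) attach_ld(hv, sub_ld) else hv,
          methods = config$methods,
          effects_model = config$effects_model,
          n_boot = config$n_boot,
          seed = cell_seed)
        rows[[length(rows) + 1]] <- dplyr::mutate(
          est, exposure = expo_name, outcome = out_name, variant = vn,
          .before = 1)
      }
    }
  }

  report <- dplyr::bind_rows(rows)
  report <- dplyr::mutate(report,
                          significant = .data$pvalue < config$alpha,
                          .after = "pvalue")
  class(report) <- c("mr_report", class(report))
  attr(report, "audit") <- dplyr::bind_rows(audit)
  attr(report, "alpha") <- config$alpha
  attr(report, "config") <- config
  report
}

#' Write an analysis report, audit log, and plot data
#'
#' Writes the report table (`report.tsv`) and the per-SNP audit log
#' (`audit.tsv`) as tab-delimited files.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_mr_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.tsv"),
             audit = file.path(dir, "audit.tsv"))
  readr::write_tsv(as.data.frame(report), paths[["report"]])
  readr::write_tsv(attr(report, "audit"), paths[["audit"]])
  invisible(paths)
}

#' Funnel-plot data: per-SNP ratio against precision
#'
#' One row per SNP with its Wald ratio and the ratio's precision (1/SE).
#' Under no directional pleiotropy the scatter is symmetric about the
#' pooled estimate; asymmetry (small-precision SNPs drifting to one side)
#' suggests directional pleiotropy, as in a meta-analysis funnel plot.
#'
#' @param h An `mr_harmonized` tibble.
#' @return A tibble with `rsid`, `ratio`, `precision`.
#' @export
funnel_data <- function(h) {
  check_harmonized(h, 1, "funnel_data")
  wr <- wald_ratio(h$beta_exposure, h$se_exposure,
                   h$beta_outcome, h$se_outcome, h$rsid)
  tibble::tibble(rsid = h$rsid, ratio = wr$estimate, precision = 1 / wr$se)
}

#' Scatter-plot data: SNP effects with fitted method lines
#'
#' Per-SNP points (exposure effect, outcome effect, 95% error bars) plus
#' one fitted line per estimated method: slope = causal estimate,
#' intercept 0 for IVW and the weighted median, the Egger intercept for
#' MR-Egger.
#'
#' @param h An `mr_harmonized` tibble.
#' @param estimates A tibble of estimates as returned by [mr_estimates()]
#'   (or `tidy()` rows bound together) computed on the same set.
#' @return A tibble of points with `rsid`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `outcome_low`, `outcome_high`;
#'   per-method lines in `attr(, "lines")` (`method`, `slope`,
#'   `intercept`).
#' @export
scatter_data <- function(h, estimates) {
  check_harmonized(h, 1, "scatter_data")
  pts <- tibble::tibble(
    rsid = h$rsid, beta_exposure = h$beta_exposure,
    se_exposure = h$se_exposure, beta_outcome = h$beta_outcome,
    se_outcome = h$se_outcome,
    outcome_low = h$beta_outcome - 1.96 * h$se_outcome,
    outcome_high = h$beta_outcome + 1.96 * h$se_outcome)
  est <- estimates[!is.na(estimates$estimate), ]
  lines <- tibble::tibble(
    method = est$method, slope = est$estimate,
    intercept = ifelse(is.na(est$intercept), 0, est$intercept))
  attr(pts, "lines") <- lines
  pts
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis report: %d rows (alpha = %g)\n",
              nrow(x), attr(x, "alpha")))
  NextMethod()
}

#' Tidy an MR report
#'
#' Returns the report as a plain tibble (it already is one row per
#' estimate); provided so reports compose with broom-style workflows.
#'
#' @param x An `mr_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mr_report
#' @export
tidy.mr_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mr_report")
  attr(out, "audit") <- NULL
  attr(out, "config") <- NULL
  tibble::as_tibble(out)
}

#' Glance at an MR report
#'
#' @param x An `mr_report`.
#' @param ... Unused.
#' @return One-row tibble: counts of rows, feasible estimates and
#'   significant findings, and the alpha used.
#' @method glance mr_report
#' @export
glance.mr_report <- function(x, ...) {
  tibble::tibble(n_rows = nrow(x), n_feasible = sum(x$feasible),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 alpha = attr(x, "alpha"))
}
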