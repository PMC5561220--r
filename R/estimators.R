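#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: SNP-outcome effect divided by
#' SNP-exposure effect, with the first-order standard error
#' se(outcome) / |beta(exposure)| (exposure uncertainty ignored, the usual
#' two-sample convention for strong instruments).
#'
#' @param beta_exposure,se_exposure SNP-exposure effect(s) and SE(s).
#' @param beta_outcome,se_outcome SNP-outcome effect(s) and SE(s).
#' @param rsid Optional identifiers used in error messages.
#' @return A tibble with columns `estimate` and `se`, one row per SNP.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                       rsid = NULL) {
  zero <- beta_exposure == 0
  if (any(zero)) {
    who <- if (is.null(rsid)) paste0("SNP ", which(zero)) else rsid[zero]
    abort(paste0("Zero exposure effect, Wald ratio undefined for: ",
                 paste(who, collapse = ", ")),
          class = "mrpipe_division_error")
  }
  tibble::tibble(estimate = beta_outcome / beta_exposure,
                 se = se_outcome / abs(beta_exposure))
}

mr_result <- function(method, estimate, se, pvalue, n_snps,
                      effects_model = NA_character_,
                      intercept = NA_real_, intercept_se = NA_real_,
                      intercept_pvalue = NA_real_, extra = list()) {
  structure(
    c(list(method = method, estimate = estimate, se = se,
           ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
           pvalue = pvalue, n_snps = n_snps, effects_model = effects_model,
           intercept = intercept, intercept_se = intercept_se,
           intercept_pvalue = intercept_pvalue), extra),
    class = "mr_result")
}

check_harmonized <- function(h, min_snps = 1, caller = "estimator") {
  for (col in c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome"))
    if (!col %in% names(h))
      abort(paste0("Harmonized data lacks column `", col, "`"),
            class = "mrpipe_config_error")
  if (nrow(h) == 0)
    abort("No SNPs in harmonized set", class = "mrpipe_empty_error")
  if (nrow(h) < min_snps)
    abort(sprintf("%s needs at least %d SNPs, got %d",
                  caller, min_snps, nrow(h)),
          class = "mrpipe_infeasible_error")
  if (any(h$se_exposure <= 0) || any(h$se_outcome <= 0))
    abort("Standard errors must be positive",
          class = "mrpipe_validation_error")
  invisible(h)
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted average of the per-SNP Wald ratios, assuming
#' uncorrelated instruments. With weights w_j = se_j^-2 on ratios b_j, the
#' estimate is sum(w b) / sum(w) with fixed-effects SE (sum w)^-1/2. The
#' multiplicative random-effects model inflates that SE by
#' max(1, phi), phi^2 = sum(w (b - est)^2) / (J - 1), so heterogeneity can
#' widen but never narrow the interval. `effects_model = "auto"` follows
#' the common small-set rule: fixed with three or fewer SNPs, random with
#' four or more. p-values use a normal reference; the 95% CI is
#' estimate +/- 1.96 SE.
#'
#' @param h An `mr_harmonized` tibble (see [harmonize()]); must not carry
#'   an LD matrix — use [mr_ivw_correlated()] for correlated instruments.
#' @param effects_model `"auto"` (default), `"fixed"` or `"random"`.
#' @return An object of class `mr_result`; see [tidy.mr_result()].
#' @export
#' @examples
#' h <- harmonized_set(c("rs1", "rs2"), beta_exposure = c(1, 1),
#'                     se_exposure = c(0.01, 0.01),
#'                     beta_outcome = c(0.5, 1), se_outcome = c(0.1, 0.2))
#' mr_ivw(h, "fixed")  # estimate 0.6, SE 1/sqrt(125)
mr_ivw <- function(h, effects_model = c("auto", "fixed", "random")) {
  effects_model <- match.arg(effects_model)
  check_harmonized(h, 1, "IVW")
  if (!is.null(attr(h, "ld")))
    abort("LD matrix attached; use mr_ivw_correlated() for correlated SNPs",
          class = "mrpipe_config_error")
  j <- nrow(h)
  if (effects_model == "auto")
    effects_model <- if (j <= 3) "fixed" else "random"
  wr <- wald_ratio(h$beta_exposure, h$se_exposure,
                   h$beta_outcome, h$se_outcome, h$rsid)
  w <- wr$se^-2
  est <- sum(w * wr$estimate) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  se <- se_fixed
  phi <- NA_real_
  if (effects_model == "random") {
    phi <- if (j > 1) sqrt(sum(w * (wr$estimate - est)^2) / (j - 1)) else 1
    se <- se_fixed * max(1, phi)
  }
  p <- 2 * pnorm(-abs(est / se))
  mr_result("IVW", est, se, p, j, effects_model = effects_model,
            extra = list(heterogeneity_scale = phi))
}

#' IVW for correlated instruments (generalized least squares)
#'
#' When instruments are in linkage disequilibrium their outcome-effect
#' sampling errors are correlated, and the plain IVW overstates precision.
#' This estimator runs a generalized weighted regression of the outcome
#' effects on the exposure effects through the origin with covariance
#' Omega_jk = se_outcome_j * se_outcome_k * r_jk built from the signed LD
#' matrix: estimate = (g' Omega^-1 g)^-1 g' Omega^-1 G with SE
#' (g' Omega^-1 g)^-1/2. The system is solved through a Cholesky
#' factorization, never an explicit inverse; if the condition number of
#' Omega exceeds 1e12 a ridge of 1e-10 is added to its diagonal (logged
#' via a message). With `intercept = TRUE` a free intercept is estimated
#' alongside the slope (an LD-aware analogue of MR-Egger regression;
#' experimental).
#'
#' @param h An `mr_harmonized` tibble carrying an LD matrix (see
#'   [attach_ld()]).
#' @param ld Optional LD matrix overriding `attr(h, "ld")`.
#' @param intercept Estimate a free intercept? Default `FALSE`
#'   (origin-constrained).
#' @return An `mr_result`; with `intercept = TRUE` the intercept term and
#'   its t-test (J - 2 df) are filled in.
#' @export
mr_ivw_correlated <- function(h, ld = attr(h, "ld"), intercept = FALSE) {
  check_harmonized(h, if (intercept) 3 else 1, "Correlated-instrument IVW")
  if (is.null(ld))
    abort("No LD matrix attached; use attach_ld() or pass `ld`",
          class = "mrpipe_config_error")
  if (!identical(rownames(ld), h$rsid))
    ld <- new_ld_matrix(ld[h$rsid, h$rsid, drop = FALSE])
  j <- nrow(h)
  omega <- tcrossprod(h$se_outcome) * ld
  if (kappa(omega, exact = TRUE) > 1e12) {
    inform("Omega near-singular; adding ridge 1e-10 to its diagonal")
    diag(omega) <- diag(omega) + 1e-10
  }
  ch <- tryCatch(chol(omega), error = function(e)
    abort("Omega not positive definite after ridge",
          class = "mrpipe_numerical_error"))
  x <- if (intercept) cbind(`(Intercept)` = 1, slope = h$beta_exposure)
  else cbind(slope = h$beta_exposure)
  # whiten: solve L z = v with L = t(ch)
  xw <- backsolve(ch, x, transpose = TRUE)
  yw <- backsolve(ch, h$beta_outcome, transpose = TRUE)
  fit <- qr(xw)
  b <- qr.coef(fit, yw)
  xtx_inv <- chol2inv(qr.R(fit))
  ses <- sqrt(diag(xtx_inv))
  if (intercept) {
    est <- b["slope"]; se <- ses[2]
    p <- 2 * pt(-abs(est / se), df = j - 2)
    ip <- 2 * pt(-abs(b[1] / ses[1]), df = j - 2)
    mr_result("MR-Egger", unname(est), se, unname(p), j,
              effects_model = "fixed",
              intercept = unname(b[1]), intercept_se = ses[1],
              intercept_pvalue = unname(ip))
  } else {
    est <- unname(b); se <- ses[1]
    p <- 2 * pnorm(-abs(est / se))
    mr_result("IVW", est, se, p, j, effects_model = "fixed")
  }
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median estimate
#'
#' The causal estimate at the 50th percentile of the precision-weight
#' ordered Wald ratios, consistent as long as valid instruments carry more
#' than half of the total weight (up to 50% of SNPs may be invalid).
#' Ratios are ordered ascending; with normalized weights w'_j the
#' cumulative midpoints are s_j = sum_{k<=j} w'_k - w'_j / 2 and the
#' estimate interpolates linearly between the two ratios bracketing
#' s = 0.5. The SE is the standard deviation of the estimate over `n_boot`
#' parametric-bootstrap replicates that redraw each beta from a normal
#' with its reported SE; the p-value uses a normal reference.
#'
#' Not supported for correlated instruments: an attached LD matrix is a
#' hard error.
#'
#' @param h An `mr_harmonized` tibble with at least 3 SNPs.
#' @param n_boot Number of bootstrap replicates for the SE (default 2000).
#' @param seed Integer seed for the bootstrap; required, so pipelines are
#'   reproducible by construction.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(h, n_boot = 2000, seed) {
  check_harmonized(h, 3, "Weighted median")
  if (!is.null(attr(h, "ld")))
    abort("Weighted median does not support correlated instruments",
          class = "mrpipe_unsupported_error")
  if (missing(seed) || is.null(seed))
    abort("Weighted median needs an explicit bootstrap `seed`",
          class = "mrpipe_config_error")
  j <- nrow(h)
  wr <- wald_ratio(h$beta_exposure, h$se_exposure,
                   h$beta_outcome, h$se_outcome, h$rsid)
  est <- weighted_median_point(wr$estimate, wr$se^-2)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      g <- rnorm(j, h$beta_exposure, h$se_exposure)
      G <- rnorm(j, h$beta_outcome, h$se_outcome)
      ok <- g != 0
      weighted_median_point(G[ok] / g[ok], (abs(g[ok]) / h$se_outcome[ok])^2)
    }, numeric(1))
  })
  se <- sd(boot)
  p <- 2 * pnorm(-abs(est / se))
  mr_result("WM", est, se, p, j)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept: the slope is the causal estimate, the
#' intercept the average directional pleiotropic effect per SNP, and the
#' intercept's p-value the directional-pleiotropy test. Valid when
#' instrument strength is independent of the direct effects (InSIDE), even
#' if every instrument is pleiotropic. Each SNP is first oriented so its
#' exposure effect is non-negative (flipping both effects when needed),
#' which the intercept's interpretation requires. Weights are
#' se_outcome^-2; SEs carry a multiplicative scale floored at 1 (under- but
#' not over-dispersion is ignored); p-values use a t reference with J - 2
#' degrees of freedom.
#'
#' @param h An `mr_harmonized` tibble with at least 3 SNPs.
#' @return An `mr_result` with `intercept`, `intercept_se`,
#'   `intercept_pvalue` filled in.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3, "MR-Egger")
  j <- nrow(h)
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  g <- h$beta_exposure * flip
  G <- h$beta_outcome * flip
  if (diff(range(g)) == 0)
    abort("All exposure effects equal after orientation; Egger slope undefined",
          class = "mrpipe_collinear_error")
  w <- h$se_outcome^-2
  fit <- lm(G ~ g, weights = w)
  sigma <- sqrt(sum(w * fit$residuals^2) / (j - 2))
  r <- qr.R(fit$qr)
  vcov_unscaled <- chol2inv(r)
  piv <- fit$qr$pivot
  se_unscaled <- sqrt(diag(vcov_unscaled))[order(piv)]
  names(se_unscaled) <- colnames(r)[order(piv)]
  ses <- se_unscaled * max(1, sigma)
  est <- coef(fit)[["g"]]
  b0 <- coef(fit)[["(Intercept)"]]
  p <- 2 * pt(-abs(est / ses[["g"]]), df = j - 2)
  ip <- 2 * pt(-abs(b0 / ses[["(Intercept)"]]), df = j - 2)
  mr_result("MR-Egger", est, ses[["g"]], p, j,
            intercept = b0, intercept_se = ses[["(Intercept)"]],
            intercept_pvalue = ip)
}

#' Run the full estimator suite on a harmonized set
#'
#' Convenience wrapper running the requested methods and returning one
#' tidy row per method. Infeasible methods (weighted median and MR-Egger
#' need more than two SNPs) yield an NA row rather than an error, so
#' report tables keep their shape.
#'
#' @param h An `mr_harmonized` tibble.
#' @param methods Subset of `c("ivw", "wm", "egger")`.
#' @param effects_model IVW effects model (`"auto"`, `"fixed"`,
#'   `"random"`).
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @return A tibble with one row per method, columns as in
#'   [tidy.mr_result()] plus `feasible`.
#' @export
mr_estimates <- function(h, methods = c("ivw", "wm", "egger"),
                         effects_model = "auto", n_boot = 2000,
                         seed = NULL) {
  methods <- match.arg(methods, c("ivw", "wm", "egger"), several.ok = TRUE)
  use_ld <- !is.null(attr(h, "ld"))
  run <- function(method) {
    res <- tryCatch({
      switch(method,
        ivw = if (use_ld) mr_ivw_correlated(h) else
          mr_ivw(h, effects_model),
        wm = mr_weighted_median(h, n_boot = n_boot, seed = seed),
        egger = if (use_ld)
          # LD-aware Egger: GLS with a free intercept (experimental)
          mr_ivw_correlated(h, intercept = TRUE)
        else mr_egger(h))
    }, mrpipe_infeasible_error = function(e) NULL,
       mrpipe_unsupported_error = function(e) NULL)
    if (is.null(res)) {
      lab <- c(ivw = "IVW", wm = "WM", egger = "MR-Egger")[[method]]
      return(tibble::tibble(method = lab, estimate = NA_real_, se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            pvalue = NA_real_, n_snps = nrow(h),
                            effects_model = NA_character_,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_pvalue = NA_real_, feasible = FALSE))
    }
    dplyr::mutate(as_tidy_row(res), feasible = TRUE)
  }
  dplyr::bind_rows(lapply(methods, run))
}

as_tidy_row <- function(x) {
  tibble::tibble(method = x$method, estimate = x$estimate, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
                 n_snps = x$n_snps, effects_model = x$effects_model,
                 intercept = x$intercept, intercept_se = x$intercept_se,
                 intercept_pvalue = x$intercept_pvalue)
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs%s)\n", x$method, x$n_snps,
              if (!is.na(x$effects_model))
                paste0(", ", x$effects_model, " effects") else ""))
  cat(sprintf("  beta = %.4f  se = %.4f  95%% CI [%.4f, %.4f]  p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept = %.4f  se = %.4f  p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}

#' Tidy an MR estimate
#'
#' Broom-style one-row-per-term summary: the causal slope, plus the
#' intercept term for methods that estimate one.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  out <- tibble::tibble(method = x$method, term = "causal_effect",
                        estimate = x$estimate, std.error = x$se,
                        conf.low = x$ci_low, conf.high = x$ci_high,
                        p.value = x$pvalue)
  if (!is.na(x$intercept))
    out <- dplyr::bind_rows(out, tibble::tibble(
      method = x$method, term = "intercept", estimate = x$intercept,
      std.error = x$intercept_se,
      conf.low = x$intercept - 1.96 * x$intercept_se,
      conf.high = x$intercept + 1.96 * x$intercept_se,
      p.value = x$intercept_pvalue))
  out
}

#' Glance at an MR estimate
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_snps`, `effects_model`,
#'   `estimate`, `se`, `pvalue`.
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snps = x$n_snps,
                 effects_model = x$effects_model, estimate = x$estimate,
                 se = x$se, pvalue = x$pvalue)
}
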