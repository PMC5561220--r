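COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses SNP-outcome effects on the exposure's effect allele for every
#' SNP shared between the two tables. Outcome records whose alleles are
#' swapped relative to the exposure have their beta sign-flipped and eaf
#' replaced by 1 - eaf; records on the opposite strand are complemented
#' first. Palindromic SNPs (A/T or C/G) cannot be resolved by allele
#' letters and are handled per `palindrome_policy`:
#' \describe{
#'   \item{`"frequency"`}{(default) align by effect-allele frequency
#'     agreement; exclude the SNP as ambiguous when both frequencies lie
#'     within `eaf_window` of 0.5. Requires eaf in both tables.}
#'   \item{`"drop"`}{exclude all palindromic SNPs.}
#'   \item{`"keep"`}{assume both studies report the same strand and align
#'     by allele letters alone.}
#' }
#' SNPs with irreconcilable allele pairs (e.g. A/C vs A/G) are excluded
#' with a reason, not a fatal error.
#'
#' @param exposure,outcome `mr_summary` tibbles (see
#'   [read_summary_table()]).
#' @param palindrome_policy One of `"frequency"`, `"drop"`, `"keep"`.
#' @param eaf_window Half-width of the ambiguity window around eaf = 0.5
#'   for the frequency policy.
#' @param ld Optional LD matrix covering (at least) the shared rsIDs; it is
#'   restricted and reordered to the harmonized set and attached.
#'
#' @return A tibble of class `mr_harmonized` with one row per retained SNP:
#'   `rsid`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `pval_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `pval_outcome`, `eaf_outcome`. Excluded SNPs and their
#'   reasons are in `attr(, "excluded")`; the restricted LD matrix, if
#'   supplied, in `attr(, "ld")`.
#' @export
#' @examples
#' exp <- new_summary_table(data.frame(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G",
#'   beta = 0.1, se = 0.01, pvalue = 1e-10))
#' out <- new_summary_table(data.frame(
#'   rsid = "rs1", effect_allele = "G", other_allele = "A",
#'   beta = 0.05, se = 0.02, pvalue = 0.01))
#' harmonize(exp, out)$beta_outcome  # -0.05: alleles were swapped
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("frequency", "drop", "keep"),
                      eaf_window = 0.08, ld = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0)
    abort("No rsIDs shared between exposure and outcome tables",
          class = "mrpipe_empty_error")

  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  cea_y <- unname(COMPLEMENT[ea_y]); coa_y <- unname(COMPLEMENT[oa_y])
  palin <- is_palindromic(ea_x, oa_x)

  same <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  # non-palindromic only: strand complement then match
  c_same <- cea_y == ea_x & coa_y == oa_x
  c_swap <- cea_y == oa_x & coa_y == ea_x

  flip <- rep(FALSE, length(shared))
  reason <- rep(NA_character_, length(shared))

  np <- !palin
  flip[np & swapped] <- TRUE
  flip[np & !same & !swapped & c_swap] <- TRUE
  reason[np & !(same | swapped | c_same | c_swap)] <- "incompatible alleles"

  if (any(palin)) {
    if (palindrome_policy == "drop") {
      reason[palin] <- "palindromic SNP (policy = drop)"
    } else {
      # letters alone only decide swapped vs unswapped for palindromes
      flip[palin & swapped] <- TRUE
      reason[palin & !same & !swapped] <- "incompatible alleles"
      if (palindrome_policy == "frequency") {
        active <- palin & is.na(reason)
        if (any(active & (is.na(ex$eaf) | is.na(ou$eaf))))
          abort(paste0("Palindromic SNP(s) need eaf in both tables for ",
                       "palindrome_policy = \"frequency\": ",
                       paste(shared[active & (is.na(ex$eaf) | is.na(ou$eaf))],
                             collapse = ", ")),
                class = "mrpipe_missing_eaf_error")
        eaf_al <- ifelse(flip, 1 - ou$eaf, ou$eaf)
        ambiguous <- active & abs(ex$eaf - 0.5) <= eaf_window &
          abs(eaf_al - 0.5) <= eaf_window
        reason[ambiguous] <- "ambiguous palindrome (both eaf near 0.5)"
        # frequency overrides letters when the sides of 0.5 disagree
        refl <- active & !ambiguous & ((ex$eaf < 0.5) != (eaf_al < 0.5))
        flip[refl] <- !flip[refl]
      }
    }
  }

  ok <- is.na(reason)
  sgn <- ifelse(flip, -1, 1)
  h <- tibble::tibble(
    rsid = shared,
    effect_allele = ea_x, other_allele = oa_x,
    beta_exposure = ex$beta, se_exposure = ex$se,
    pval_exposure = ex$pvalue, eaf_exposure = ex$eaf,
    beta_outcome = sgn * ou$beta, se_outcome = ou$se,
    pval_outcome = ou$pvalue,
    eaf_outcome = ifelse(flip, 1 - ou$eaf, ou$eaf)
  )[ok, ]
  excluded <- tibble::tibble(rsid = shared, reason = reason)[!ok, ]
  if (nrow(h) == 0)
    abort("No SNPs survived harmonization", class = "mrpipe_empty_error")

  class(h) <- c("mr_harmonized", class(h))
  attr(h, "excluded") <- excluded
  attr(h, "exposure_trait") <- attr(exposure, "trait")
  attr(h, "outcome_trait") <- attr(outcome, "trait")
  if (!is.null(ld)) h <- attach_ld(h, ld)
  h
}

#' Attach an LD matrix to a harmonized set
#'
#' Restricts and reorders `ld` to the rsIDs of `h` and stores it as the
#' `"ld"` attribute, where the correlated-instrument estimator
#' [mr_ivw_correlated()] finds it.
#'
#' @param h An `mr_harmonized` tibble.
#' @param ld LD matrix with rsID dimnames covering all rsIDs of `h`.
#' @return `h` with the restricted LD matrix attached.
#' @export
attach_ld <- function(h, ld) {
  missing <- setdiff(h$rsid, rownames(ld))
  if (length(missing) > 0)
    abort(paste0("rsID(s) absent from LD matrix: ",
                 paste(missing, collapse = ", ")),
          class = "mrpipe_validation_error")
  attr(h, "ld") <- new_ld_matrix(ld[h$rsid, h$rsid, drop = FALSE])
  h
}

#' Construct a harmonized set directly
#'
#' Builds an `mr_harmonized` tibble from already-aligned effect vectors,
#' bypassing allele bookkeeping — convenient for simulations and for
#' summary data known to share an effect-allele orientation.
#'
#' @param rsid Character vector of SNP identifiers.
#' @param beta_exposure,se_exposure SNP-exposure effects and their SEs.
#' @param beta_outcome,se_outcome SNP-outcome effects and their SEs.
#' @param ld Optional LD matrix to attach.
#' @return An `mr_harmonized` tibble.
#' @export
harmonized_set <- function(rsid, beta_exposure, se_exposure,
                           beta_outcome, se_outcome, ld = NULL) {
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    abort("Standard errors must be positive",
          class = "mrpipe_validation_error")
  h <- tibble::tibble(
    rsid = as.character(rsid),
    effect_allele = NA_character_, other_allele = NA_character_,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    pval_exposure = NA_real_, eaf_exposure = NA_real_,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    pval_outcome = NA_real_, eaf_outcome = NA_real_
  )
  class(h) <- c("mr_harmonized", class(h))
  attr(h, "excluded") <- tibble::tibble(rsid = character(),
                                        reason = character())
  if (!is.null(ld)) h <- attach_ld(h, ld)
  h
}
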