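#' Configure a two-sample summary-statistic simulation
#'
#' Defines the generative model for a synthetic two-sample MR study with
#' known ground truth. True per-SNP exposure effects gamma_j are drawn
#' from `gamma_range`, effect-allele frequencies from `maf_range`, and the
#' standard errors follow the variance-standardized-trait approximation
#' se = 1 / sqrt(2 p (1 - p) n), so instrument strength grows with sample
#' size as it does in real GWAS. True outcome effects are
#' theta * gamma_j + alpha_j, where the direct (pleiotropic) effects
#' alpha_j follow `pleiotropy`; observed effects add normal sampling noise
#' with the stated SEs, correlated within LD blocks (via the Cholesky
#' square root of the block correlation) independently in the exposure and
#' outcome samples — two-sample studies share no subjects, so only the LD
#' structure, not the noise, is shared. Direct effects are drawn
#' independently of gamma_j, so the InSIDE condition holds by
#' construction.
#'
#' @param n_snps Number of instruments J.
#' @param theta True causal effect of the exposure on the outcome.
#' @param n_exposure,n_outcome GWAS sample sizes governing the SEs.
#' @param gamma_range Range of true exposure effects (uniform draw).
#' @param maf_range Range of effect-allele frequencies (uniform draw).
#' @param pleiotropy One of `pleiotropy_none()`, `pleiotropy_balanced()`,
#'   `pleiotropy_directional()`.
#' @param ld_blocks Optional list of `list(size =, r =)` blocks of
#'   equicorrelated SNPs (|r| < 1); SNPs beyond the blocks are
#'   uncorrelated.
#' @param outcomes Character vector of outcome names; each gets an
#'   independent outcome sample. `n_outcome` may be a vector of the same
#'   length.
#' @param seed Integer seed; required, the simulation is deterministic
#'   given it.
#' @return A `sim_config` list, input to [simulate_two_sample()].
#' @export
sim_config <- function(n_snps = 20, theta = 0, n_exposure = 50000,
                       n_outcome = 50000, gamma_range = c(0.05, 0.3),
                       maf_range = c(0.1, 0.5),
                       pleiotropy = pleiotropy_none(),
                       ld_blocks = NULL, outcomes = "outcome", seed) {
  if (missing(seed) || is.null(seed))
    abort("Simulation needs an explicit `seed`",
          class = "mrpipe_config_error")
  stopifnot(n_snps >= 1, length(outcomes) >= 1)
  n_outcome <- rep_len(n_outcome, length(outcomes))
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, `[[`, numeric(1), "size")
    rs <- vapply(ld_blocks, `[[`, numeric(1), "r")
    if (sum(sizes) > n_snps)
      abort("LD blocks cover more SNPs than n_snps",
            class = "mrpipe_config_error")
    if (any(abs(rs) >= 1))
      abort("Within-block |r| must be < 1", class = "mrpipe_config_error")
    # equicorrelation with r <= -1/(size-1) is not a correlation matrix
    if (any(rs < 0 & rs <= -1 / (sizes - 1)))
      abort("Block correlation not positive definite",
            class = "mrpipe_config_error")
  }
  structure(list(n_snps = n_snps, theta = theta, n_exposure = n_exposure,
                 n_outcome = n_outcome, gamma_range = gamma_range,
                 maf_range = maf_range, pleiotropy = pleiotropy,
                 ld_blocks = ld_blocks, outcomes = outcomes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pleiotropy laws for the simulator
#'
#' `pleiotropy_none()`: all direct effects zero (every instrument valid).
#' `pleiotropy_balanced(tau)`: alpha_j ~ N(0, tau^2) — pleiotropy present
#' but averaging out. `pleiotropy_directional(mu, tau, frac)`: a fraction
#' `frac` of SNPs (all by default) draw alpha_j ~ N(mu, tau^2) with mu
#' typically nonzero, biasing ratio-based estimators; the rest are valid.
#'
#' @param tau SD of the direct effects (>= 0).
#' @param mu Mean direct effect of affected SNPs.
#' @param frac Fraction of SNPs affected, in (0, 1].
#' @return A pleiotropy-law list consumed by [sim_config()].
#' @export
pleiotropy_none <- function() list(type = "none")

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(tau) {
  stopifnot(tau >= 0)
  list(type = "balanced", tau = tau)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mu, tau = 0, frac = 1) {
  stopifnot(tau >= 0, frac > 0, frac <= 1)
  list(type = "directional", mu = mu, tau = tau, frac = frac)
}

block_ld_matrix <- function(n_snps, ld_blocks, rsids) {
  r <- diag(n_snps)
  if (!is.null(ld_blocks)) {
    start <- 1
    for (b in ld_blocks) {
      idx <- seq(start, start + b$size - 1)
      r[idx, idx] <- b$r
      start <- start + b$size
    }
    diag(r) <- 1
  }
  dimnames(r) <- list(rsids, rsids)
  r
}

draw_correlated <- function(chol_u, n) {
  # z ~ N(0, R) given the upper Cholesky factor of R (NULL = identity)
  if (is.null(chol_u)) return(rnorm(n))
  drop(crossprod(chol_u, rnorm(n)))
}

#' Simulate a two-sample GWAS summary-statistic study
#'
#' Draws a synthetic exposure GWAS and one outcome GWAS per configured
#' outcome under the generative model of [sim_config()], returning the
#' observed summary tables together with the ground truth. Alleles are
#' assigned from non-palindromic pairs with a shared orientation, so the
#' tables harmonize without exclusions.
#'
#' @param config A `sim_config`.
#' @return An object of class `mr_simulation`: a list with elements
#'   `exposure` (an `mr_summary` tibble), `outcomes` (named list of
#'   `mr_summary` tibbles), `ld` (LD matrix, identity when no blocks are
#'   configured), `truth` (tibble of `rsid`, `gamma`, `alpha`, per-outcome
#'   true effects), and `config`.
#' @export
#' @examples
#' sim <- simulate_two_sample(sim_config(n_snps = 5, theta = 0.3, seed = 7))
#' sim$truth
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    j <- config$n_snps
    rsids <- sprintf("rs%d", seq_len(j) + 1000L)
    gamma <- runif(j, config$gamma_range[1], config$gamma_range[2])
    eaf <- runif(j, config$maf_range[1], config$maf_range[2])
    pl <- config$pleiotropy
    alpha <- switch(pl$type,
      none = rep(0, j),
      balanced = rnorm(j, 0, pl$tau),
      directional = {
        k <- ceiling(pl$frac * j)
        invalid <- sample.int(j, k)
        a <- rep(0, j)
        a[invalid] <- rnorm(k, pl$mu, pl$tau)
        a
      },
      abort("Unknown pleiotropy type", class = "mrpipe_config_error"))

    ld <- block_ld_matrix(j, config$ld_blocks, rsids)
    # identity LD needs no factorization; keeps large block-free draws cheap
    chol_u <- if (is.null(config$ld_blocks)) NULL else chol(ld)
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(4, j, replace = TRUE)
    ea <- pairs[pick, 1]; oa <- pairs[pick, 2]

    se_gamma <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
    gamma_hat <- gamma + se_gamma * draw_correlated(chol_u, j)
    exposure <- new_summary_table(tibble::tibble(
      rsid = rsids, effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = gamma_hat, se = se_gamma,
      pvalue = pmax(2 * pnorm(-abs(gamma_hat / se_gamma)), 1e-300),
      n = config$n_exposure), trait = "exposure")

    outcomes <- list()
    truth <- tibble::tibble(rsid = rsids, gamma = gamma, alpha = alpha)
    for (k in seq_along(config$outcomes)) {
      nm <- config$outcomes[k]
      n_out <- config$n_outcome[k]
      se_Gamma <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out)
      Gamma <- config$theta * gamma + alpha
      Gamma_hat <- Gamma + se_Gamma * draw_correlated(chol_u, j)
      outcomes[[nm]] <- new_summary_table(tibble::tibble(
        rsid = rsids, effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = Gamma_hat, se = se_Gamma,
        pvalue = pmax(2 * pnorm(-abs(Gamma_hat / se_Gamma)), 1e-300),
        n = n_out), trait = nm)
      truth[[paste0("Gamma_", nm)]] <- Gamma
    }

    structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                   truth = tibble::tibble(truth, theta = config$theta),
                   config = config),
              class = "mr_simulation")
  })
}

#' Named simulation scenarios
#'
#' Fully specified presets covering the situations the estimator suite is
#' designed for. All use J = 20 instruments and GWAS sample sizes of
#' 50 000 unless noted:
#' \describe{
#'   \item{`"null"`}{theta = 0, no pleiotropy.}
#'   \item{`"causal"`}{theta = 0.3, no pleiotropy.}
#'   \item{`"balanced"`}{theta = 0.3, balanced pleiotropy (tau = 0.05).}
#'   \item{`"directional"`}{theta = 0.3, directional pleiotropy on every
#'     SNP (mu = 0.05, tau = 0.01), InSIDE holding.}
#'   \item{`"thirty-percent-invalid"`}{theta = 0.3; 6 of 20 SNPs carry a
#'     directional direct effect (mu = 0.1).}
#'   \item{`"correlated-blocks"`}{theta = 0.3; four LD blocks of five SNPs
#'     at r = 0.5.}
#'   \item{`"paper-shaped"`}{an hsCRP-like instrument set: J = 20,
#'     theta = 0, exposure n = 200 000, three bone-density outcome samples
#'     (forearm n = 8000, femoral neck n = 32 000, lumbar spine
#'     n = 28 000).}
#' }
#'
#' @param name Scenario name.
#' @param seed Seed override; each scenario has a fixed default (42).
#' @return A `sim_config`.
#' @export
scenario <- function(name, seed = 42) {
  known <- c("null", "causal", "balanced", "directional",
             "thirty-percent-invalid", "correlated-blocks", "paper-shaped")
  if (!name %in% known)
    abort(paste0("Unknown scenario \"", name, "\". Available: ",
                 paste(known, collapse = ", ")),
          class = "mrpipe_config_error")
  switch(name,
    "null" = sim_config(theta = 0, seed = seed),
    "causal" = sim_config(theta = 0.3, seed = seed),
    "balanced" = sim_config(theta = 0.3,
                            pleiotropy = pleiotropy_balanced(0.05),
                            seed = seed),
    "directional" = sim_config(theta = 0.3,
                               pleiotropy = pleiotropy_directional(0.05, 0.01),
                               seed = seed),
    "thirty-percent-invalid" = sim_config(
      theta = 0.3, pleiotropy = pleiotropy_directional(0.1, 0, frac = 0.3),
      seed = seed),
    "correlated-blocks" = sim_config(
      theta = 0.3,
      ld_blocks = replicate(4, list(size = 5, r = 0.5), simplify = FALSE),
      seed = seed),
    "paper-shaped" = sim_config(
      theta = 0, n_exposure = 200000,
      n_outcome = c(8000, 32000, 28000),
      outcomes = c("forearm", "femoral_neck", "lumbar_spine"),
      seed = seed))
}

#' Write a simulated study to disk
#'
#' Writes the exposure table, one file per outcome, and the LD matrix in
#' the package's tab-delimited formats. Deterministic: the same simulation
#' writes byte-identical files.
#'
#' @param sim An `mr_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(exposure = file.path(dir, "exposure.tsv"))
  write_summary_table(sim$exposure, files[["exposure"]])
  for (nm in names(sim$outcomes)) {
    f <- file.path(dir, paste0("outcome_", nm, ".tsv"))
    files[[paste0("outcome_", nm)]] <- f
    write_summary_table(sim$outcomes[[nm]], f)
  }
  files[["ld"]] <- file.path(dir, "ld.tsv")
  write_ld_matrix(sim$ld, files[["ld"]])
  invisible(files)
}
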