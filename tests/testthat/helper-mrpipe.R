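# Builders for small in-memory fixtures used across the suite.

toy_summary <- function(rsid, ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                        se = 0.01, pvalue = 1e-9, n = 10000, trait = NULL) {
  k <- length(rsid)
  new_summary_table(tibble::tibble(
    rsid = rsid,
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = rep_len(beta, k), se = rep_len(se, k),
    pvalue = rep_len(pvalue, k), n = rep_len(n, k)), trait = trait)
}

# Relabel a table's alleles (effect <-> other) and negate beta: the same
# association stated for the opposite allele.
swap_alleles <- function(tab) {
  out <- tab
  ea <- out$effect_allele
  out$effect_allele <- out$other_allele
  out$other_allele <- ea
  out$beta <- -out$beta
  out$eaf <- 1 - out$eaf
  out
}

random_summary <- function(j, seed, palindromic = FALSE) {
  withr::with_seed(seed, {
    pairs <- if (palindromic) matrix(c("A", "T", "C", "G"), 2, byrow = TRUE)
    else matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), 4, byrow = TRUE)
    pick <- sample.int(nrow(pairs), j, replace = TRUE)
    toy_summary(sprintf("rs%03d", seq_len(j)),
                ea = pairs[pick, 1], oa = pairs[pick, 2],
                eaf = runif(j, 0.05, 0.95), beta = rnorm(j, 0, 0.2),
                se = runif(j, 0.005, 0.05),
                pvalue = runif(j, 1e-12, 1), n = 10000)
  })
}

random_harmonized <- function(j, seed, theta = 0.3) {
  withr::with_seed(seed, {
    g <- runif(j, 0.05, 0.3)
    sg <- runif(j, 0.005, 0.02)
    sG <- runif(j, 0.01, 0.05)
    harmonized_set(sprintf("rs%03d", seq_len(j)),
                   beta_exposure = g + rnorm(j, 0, sg), se_exposure = sg,
                   beta_outcome = theta * g + rnorm(j, 0, sG),
                   se_outcome = sG)
  })
}

# Random correlation matrix that is strictly positive definite.
random_corr <- function(j, seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(j * (j + 2)), j + 2, j)
    s <- crossprod(a)
    d <- 1 / sqrt(diag(s))
    r <- s * tcrossprod(d)
    diag(r) <- 1
    dimnames(r) <- list(sprintf("rs%03d", seq_len(j)),
                        sprintf("rs%03d", seq_len(j)))
    r
  })
}
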