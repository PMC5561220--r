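test_that("Wald ratios and their first-order SEs are exact", {
  expect_equal(wald_ratio(1, 0.01, 0.5, 0.1),
               tibble::tibble(estimate = 0.5, se = 0.1))
  expect_equal(wald_ratio(-2, 0.01, 1, 0.2),
               tibble::tibble(estimate = -0.5, se = 0.1))
  # random triples match the delta-method formula computed directly
  withr::with_seed(42, {
    g <- rnorm(50, 0, 1); g[g == 0] <- 1
    G <- rnorm(50); sG <- runif(50, 0.01, 1)
    wr <- wald_ratio(g, runif(50), G, sG)
    expect_equal(wr$estimate, G / g)
    expect_equal(wr$se, sG / abs(g))
  })
  expect_error(wald_ratio(c(1, 0), c(1, 1), c(1, 1), c(1, 1),
                          rsid = c("rsA", "rsB")),
               "rsB", class = "mrpipe_division_error")
})

test_that("IVW reproduces the hand-computed weighted mean", {
  h <- harmonized_set(c("rs1", "rs2"), c(1, 1), c(0.01, 0.01),
                      c(0.5, 1), c(0.1, 0.2))
  fit <- mr_ivw(h, "fixed")
  # weights 100 and 25: estimate 75/125, SE 1/sqrt(125)
  expect_equal(fit$estimate, 0.6)
  expect_equal(fit$se, 1 / sqrt(125))
  expect_equal(fit$ci_low, 0.6 - 1.96 / sqrt(125))
  expect_equal(fit$pvalue, 2 * pnorm(-0.6 * sqrt(125)))
  expect_equal(fit$n_snps, 2)
})

test_that("IVW reduces to the Wald ratio for a single SNP", {
  h <- harmonized_set("rs1", 2, 0.05, 0.8, 0.12)
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, 0.4)
  expect_equal(fit$se, 0.06)
  expect_equal(fit$effects_model, "fixed")  # auto: J <= 3
})

test_that("the auto rule is fixed up to 3 SNPs, random from 4", {
  h3 <- random_harmonized(3, seed = 1)
  h4 <- random_harmonized(4, seed = 2)
  expect_equal(mr_ivw(h3)$effects_model, "fixed")
  expect_equal(mr_ivw(h4)$effects_model, "random")
})

test_that("random-effects SE is never below fixed-effects SE", {
  hits_floor <- 0
  for (seed in 1:20) {
    h <- random_harmonized(20, seed = seed)
    se_f <- mr_ivw(h, "fixed")$se
    fit_r <- mr_ivw(h, "random")
    expect_gte(fit_r$se, se_f)
    if (fit_r$heterogeneity_scale <= 1) {
      expect_equal(fit_r$se, se_f)
      hits_floor <- hits_floor + 1
    }
  }
  # under an exact model the inflation floor binds about half the time
  expect_gt(hits_floor, 0)
})

test_that("GLS with identity LD equals fixed-effects IVW", {
  for (seed in 1:20) {
    h <- random_harmonized(8, seed = seed)
    id <- diag(8); dimnames(id) <- list(h$rsid, h$rsid)
    a <- mr_ivw_correlated(h, ld = id)
    b <- mr_ivw(h, "fixed")
    expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
    expect_equal(a$se, b$se, tolerance = 1e-10)
  }
})

test_that("a duplicated SNP at r ~ 1 is not double counted", {
  h <- harmonized_set(c("rs1", "rs1b"), c(0.2, 0.2), c(0.01, 0.01),
                      c(0.06, 0.06), c(0.1, 0.1))
  r <- matrix(c(1, 1 - 1e-9, 1 - 1e-9, 1), 2,
              dimnames = list(h$rsid, h$rsid))
  single <- mr_ivw(harmonized_set("rs1", 0.2, 0.01, 0.06, 0.1), "fixed")
  suppressMessages(dup <- mr_ivw_correlated(h, ld = r))
  expect_equal(dup$se, single$se, tolerance = 1e-3)
  expect_equal(dup$estimate, single$estimate, tolerance = 1e-6)
})

test_that("GLS matches brute-force normal equations on random Omega", {
  for (seed in 1:10) {
    h <- random_harmonized(4, seed = seed)
    r <- random_corr(4, seed = seed + 50)
    rownames(r) <- colnames(r) <- h$rsid
    fit <- mr_ivw_correlated(h, ld = r)
    omega <- tcrossprod(h$se_outcome) * r
    oi <- solve(omega)
    g <- h$beta_exposure
    expect_equal(fit$estimate,
                 drop(crossprod(g, oi %*% h$beta_outcome)) /
                   drop(crossprod(g, oi %*% g)),
                 tolerance = 1e-9)
    expect_equal(fit$se, 1 / sqrt(drop(crossprod(g, oi %*% g))),
                 tolerance = 1e-9)
  }
})

test_that("weighted median interpolates the weighted 50th percentile", {
  h <- harmonized_set(paste0("rs", 1:3), c(1, 1, 1), rep(0.01, 3),
                      c(1, 2, 3), c(1, 1, 1))
  fit <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(fit$estimate, 2)

  h4 <- harmonized_set(paste0("rs", 1:4), rep(1, 4), rep(0.01, 4),
                       c(1, 2, 3, 100), rep(1, 4))
  est <- mr_weighted_median(h4, n_boot = 100, seed = 1)$estimate
  expect_gt(est, 2); expect_lt(est, 3)
  # unmoved by the outlier's magnitude
  h4b <- harmonized_set(paste0("rs", 1:4), rep(1, 4), rep(0.01, 4),
                        c(1, 2, 3, 1e6), rep(1, 4))
  expect_equal(mr_weighted_median(h4b, n_boot = 100, seed = 1)$estimate, est)

  # deterministic given the seed
  a <- mr_weighted_median(h4, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h4, n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)

  expect_error(mr_weighted_median(harmonized_set("rs1", 1, 1, 1, 1),
                                  n_boot = 10, seed = 1),
               class = "mrpipe_infeasible_error")
  expect_error(mr_weighted_median(h, n_boot = 10),
               class = "mrpipe_config_error")
  id <- diag(3); dimnames(id) <- list(h$rsid, h$rsid)
  expect_error(mr_weighted_median(attach_ld(h, id), n_boot = 10, seed = 1),
               class = "mrpipe_unsupported_error")
})

test_that("MR-Egger recovers slope and intercept exactly on collinear data", {
  h <- harmonized_set(paste0("rs", 1:3), c(1, 2, 3), rep(0.01, 3),
                      c(2.5, 4.5, 6.5), c(0.3, 0.1, 0.2))
  fit <- mr_egger(h)
  expect_equal(fit$estimate, 2)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$n_snps, 3)  # minimal feasible case, 1 residual df

  expect_error(mr_egger(harmonized_set(c("a", "b"), c(1, 2), c(1, 1),
                                       c(1, 2), c(1, 1))),
               class = "mrpipe_infeasible_error")
  expect_error(mr_egger(harmonized_set(paste0("rs", 1:3), c(1, 1, -1),
                                       rep(0.1, 3), c(1, 1, 1), rep(1, 3))),
               class = "mrpipe_collinear_error")
})

test_that("Egger orientation flips negative exposure effects internally", {
  h <- harmonized_set(paste0("rs", 1:4), c(1, 2, -1.5, 3), rep(0.01, 4),
                      c(0.4, 0.7, -0.5, 1.0), runif(4, 0.05, 0.2))
  flipped <- h
  flipped$beta_exposure <- -flipped$beta_exposure
  flipped$beta_outcome <- -flipped$beta_outcome
  a <- mr_egger(h); b <- mr_egger(flipped)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$intercept, b$intercept)
  expect_equal(a$se, b$se)
})

test_that("Egger matches a weighted lm with scaled SEs when overdispersed", {
  h <- random_harmonized(12, seed = 5)
  # inject heterogeneity so the residual scale exceeds 1
  h$beta_outcome <- h$beta_outcome + rep(c(-1, 1), 6) * 0.2
  fit <- mr_egger(h)
  w <- h$se_outcome^-2
  lmfit <- lm(beta_outcome ~ beta_exposure, data = h, weights = w)
  expect_equal(fit$estimate, unname(coef(lmfit)[2]))
  s <- summary(lmfit)
  expect_gt(s$sigma, 1)
  expect_equal(fit$se, s$coefficients[2, 2])
  expect_equal(fit$pvalue, 2 * pt(-abs(fit$estimate / fit$se), df = 10))
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  for (seed in 1:5) {
    h <- random_harmonized(10, seed = seed)
    perm <- withr::with_seed(seed, sample(10))
    hp <- h[perm, ]
    flip <- h
    sgn <- rep(c(-1, 1), 5)
    flip$beta_exposure <- sgn * flip$beta_exposure
    flip$beta_outcome <- sgn * flip$beta_outcome
    for (f in list(function(x) mr_ivw(x, "random"), mr_egger)) {
      base <- f(h)
      expect_equal(f(hp)$estimate, base$estimate)
      expect_equal(f(flip)$estimate, base$estimate)
      expect_equal(f(flip)$se, base$se)
    }
    wm0 <- mr_weighted_median(h, n_boot = 50, seed = 9)$estimate
    expect_equal(mr_weighted_median(hp, n_boot = 50, seed = 9)$estimate, wm0)
    expect_equal(mr_weighted_median(flip, n_boot = 50, seed = 9)$estimate,
                 wm0)
  }
})

test_that("tidy and glance summarise estimates broom-style", {
  h <- random_harmonized(5, seed = 8)
  td <- tidy(mr_egger(h))
  expect_equal(td$term, c("causal_effect", "intercept"))
  expect_true(all(c("estimate", "std.error", "conf.low", "p.value")
                  %in% names(td)))
  gl <- glance(mr_ivw(h))
  expect_equal(gl$method, "IVW")
  expect_equal(gl$n_snps, 5)
  expect_equal(nrow(tidy(mr_ivw(h))), 1)
})

test_that("mr_estimates returns NA rows for infeasible methods", {
  h2 <- random_harmonized(2, seed = 3)
  est <- mr_estimates(h2, seed = 1, n_boot = 50)
  expect_equal(est$method, c("IVW", "WM", "MR-Egger"))
  expect_true(est$feasible[est$method == "IVW"])
  expect_false(any(est$feasible[est$method != "IVW"]))
  expect_true(all(is.na(est$estimate[!est$feasible])))
})
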