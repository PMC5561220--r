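test_that("summary tables read from disk, validate, and round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tn",
    "rs1\ta\tg\t0.30\t0.12\t0.02\t2e-9\t10000",
    "rs2\tT\tC\tNA\t-0.08\t0.01\t5e-10\tNA",
    "rs3\tC\tG\t0.45\t0.05\t0.015\t1e-8\t20000"), tf)
  tab <- read_summary_table(tf, trait = "hsCRP")
  expect_s3_class(tab, "mr_summary")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$effect_allele, c("A", "T", "C"))  # upper-cased
  expect_true(is.na(tab$eaf[2]) && is.na(tab$n[2]))
  expect_identical(attr(tab, "trait"), "hsCRP")

  # full-precision round trip
  tab$beta <- tab$beta + pi * 1e-8
  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(tab, out)
  back <- read_summary_table(out)
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    expect_identical(back[[col]], tab[[col]], info = col)
})

test_that("summary-table validation names the offending SNP", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tn",
    "rs123\tA\tG\t0.3\t0.1\t0.02\t1e-9\t1000",
    "rs123\tA\tG\t0.3\t0.1\t0.02\t1e-9\t1000"), tf)
  expect_error(read_summary_table(tf), "rs123",
               class = "mrpipe_validation_error")

  writeLines(c(
    "rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tn",
    "rs9\tA\tG\t0.3\t0.1\t0\t1e-9\t1000"), tf)
  expect_error(read_summary_table(tf), "rs9",
               class = "mrpipe_validation_error")

  expect_error(
    read_summary_table(tf, column_map = c(beta = "no_such_column")),
    class = "mrpipe_config_error")

  expect_error(toy_summary("rs1", ea = "A", oa = "A"),
               class = "mrpipe_validation_error")
  expect_error(toy_summary("rs1", pvalue = 0),
               class = "mrpipe_validation_error")
  expect_error(toy_summary("rs1", eaf = 1.2),
               class = "mrpipe_validation_error")
})

test_that("column_map renames file columns to the canonical schema", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tNEA\tfreq\tb\tstderr\tp\tN",
               "rs1\tA\tG\t0.2\t0.1\t0.02\t1e-9\t5000"), tf)
  tab <- read_summary_table(tf, column_map = c(
    rsid = "SNP", effect_allele = "EA", other_allele = "NEA",
    eaf = "freq", beta = "b", se = "stderr", pvalue = "p", n = "N"))
  expect_equal(tab$beta, 0.1)
  expect_equal(tab$n, 5000)
})

test_that("LD matrices read, validate, and symmetrize", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\trsA\trsB", "rsA\t1\t0", "rsB\t0\t1"), tf)
  r <- read_ld_matrix(tf)
  expect_equal(unname(r), diag(2))
  expect_identical(rownames(r), c("rsA", "rsB"))

  writeLines(c("rsid\trsA\trsB", "rsA\t1\t1.2", "rsB\t1.2\t1"), tf)
  expect_error(read_ld_matrix(tf), class = "mrpipe_validation_error")

  writeLines(c("rsid\trsA\trsB", "rsA\t1\t0.9", "rsB\t0.9\t1"), tf)
  r <- read_ld_matrix(tf)
  expect_equal(r["rsA", "rsB"], 0.9)
  expect_identical(r, t(r))

  # tiny asymmetry is averaged away; a large one is an error
  m <- matrix(c(1, 0.5 + 4e-11, 0.5 - 4e-11, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(new_ld_matrix(m)["a", "b"], 0.5)
  m[1, 2] <- 0.6
  expect_error(new_ld_matrix(m), class = "mrpipe_validation_error")

  # not positive semi-definite
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  dimnames(m) <- list(letters[1:3], letters[1:3])
  expect_error(new_ld_matrix(m), class = "mrpipe_validation_error")

  expect_error(new_ld_matrix(matrix(1, 2, 3)),
               class = "mrpipe_validation_error")
  # LD files round-trip
  big <- random_corr(4, seed = 11)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(big, out)
  expect_equal(read_ld_matrix(out), big, tolerance = 1e-6)
})

test_that("harmonization keeps, flips, complements, and excludes correctly", {
  exp <- toy_summary("rs1", ea = "A", oa = "G", beta = 0.1)
  same <- toy_summary("rs1", ea = "A", oa = "G", beta = 0.05, se = 0.02)
  h <- harmonize(exp, same)
  expect_equal(h$beta_exposure, 0.1)
  expect_equal(h$beta_outcome, 0.05)

  swapped <- toy_summary("rs1", ea = "G", oa = "A", beta = 0.05, se = 0.02)
  expect_equal(harmonize(exp, swapped)$beta_outcome, -0.05)

  # strand complement: A/G reported as T/C is the same orientation
  comp <- toy_summary("rs1", ea = "T", oa = "C", beta = 0.05, se = 0.02)
  expect_equal(harmonize(exp, comp)$beta_outcome, 0.05)
  # complement of the swapped pair flips
  comp_sw <- toy_summary("rs1", ea = "C", oa = "T", beta = 0.05, se = 0.02)
  expect_equal(harmonize(exp, comp_sw)$beta_outcome, -0.05)

  # irreconcilable pair is excluded with a reason, not fatal
  two <- new_summary_table(dplyr::bind_rows(
    toy_summary("rs1", ea = "A", oa = "G"),
    toy_summary("rs2", ea = "A", oa = "C")))
  out2 <- new_summary_table(dplyr::bind_rows(
    toy_summary("rs1", ea = "A", oa = "G", beta = 0.05),
    toy_summary("rs2", ea = "A", oa = "G", beta = 0.05)))
  h <- harmonize(two, out2)
  expect_equal(h$rsid, "rs1")
  excl <- attr(h, "excluded")
  expect_equal(excl$rsid, "rs2")
  expect_match(excl$reason, "incompatible")

  # no shared SNPs, or nothing surviving, is an empty-set error
  expect_error(harmonize(toy_summary("rsX"), toy_summary("rsY")),
               class = "mrpipe_empty_error")
})

test_that("palindromic SNPs follow the configured policy", {
  exp <- toy_summary("rs2", ea = "A", oa = "T", eaf = 0.49)
  out <- toy_summary("rs2", ea = "A", oa = "T", eaf = 0.51, beta = 0.05)

  expect_error(harmonize(exp, out, palindrome_policy = "drop"),
               class = "mrpipe_empty_error")  # only SNP dropped
  expect_equal(harmonize(exp, out, palindrome_policy = "keep")$beta_outcome,
               0.05)

  # both eaf within the window of 0.5: ambiguous under frequency policy
  expect_error(harmonize(exp, out, palindrome_policy = "frequency",
                         eaf_window = 0.08),
               class = "mrpipe_empty_error")
  two <- new_summary_table(dplyr::bind_rows(
    toy_summary("rs1", ea = "A", oa = "G"), exp))
  htwo <- harmonize(two,
                    new_summary_table(dplyr::bind_rows(
                      toy_summary("rs1", ea = "A", oa = "G", beta = 0.05),
                      out)),
                    palindrome_policy = "frequency", eaf_window = 0.08)
  expect_match(attr(htwo, "excluded")$reason, "ambiguous palindrome")

  # frequencies on clearly opposite sides of 0.5: outcome allele is the
  # complementary one, so the effect flips
  expf <- toy_summary("rs2", ea = "A", oa = "T", eaf = 0.2)
  outf <- toy_summary("rs2", ea = "A", oa = "T", eaf = 0.8, beta = 0.05)
  hf <- harmonize(expf, outf, palindrome_policy = "frequency")
  expect_equal(hf$beta_outcome, -0.05)
  expect_equal(hf$eaf_outcome, 0.2)
  # agreeing frequencies keep the sign
  outk <- toy_summary("rs2", ea = "A", oa = "T", eaf = 0.25, beta = 0.05)
  expect_equal(harmonize(expf, outk,
                         palindrome_policy = "frequency")$beta_outcome, 0.05)

  # frequency policy without eaf is a targeted error
  expna <- toy_summary("rs2", ea = "A", oa = "T", eaf = NA)
  expect_error(harmonize(expna, out, palindrome_policy = "frequency"),
               class = "mrpipe_missing_eaf_error")
})

test_that("allele swap is an involution and self-harmonization is identity", {
  for (seed in 1:5) {
    tab <- random_summary(12, seed = seed)
    back <- swap_alleles(swap_alleles(tab))
    # sign flips and allele relabels invert exactly; eaf up to rounding
    expect_identical(back$beta, tab$beta)
    expect_identical(back$effect_allele, tab$effect_allele)
    expect_identical(back$other_allele, tab$other_allele)
    expect_equal(back$eaf, tab$eaf)

    h <- harmonize(tab, tab, palindrome_policy = "keep")
    expect_equal(h$beta_outcome, h$beta_exposure)
    expect_equal(nrow(h), 12)

    # the swapped table states the same associations, so harmonizing
    # against it recovers the exposure effects too
    hs <- harmonize(tab, swap_alleles(tab), palindrome_policy = "keep")
    expect_equal(hs$beta_outcome, hs$beta_exposure)
  }
})

test_that("attach_ld restricts and reorders the LD matrix", {
  h <- random_harmonized(4, seed = 3)
  r <- random_corr(6, seed = 4)
  rownames(r) <- colnames(r) <- c(h$rsid[c(3, 1, 4, 2)], "rsX", "rsY")
  h2 <- attach_ld(h, r)
  expect_identical(rownames(attr(h2, "ld")), h$rsid)
  expect_error(attach_ld(h, r[1:3, 1:3]), "rs",
               class = "mrpipe_validation_error")
})
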