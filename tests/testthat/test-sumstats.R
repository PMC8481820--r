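test_that("read_sumstats converts odds ratios, fills p from z, and flags bad maps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchr\tbp\tA1\tA2\tfreq\tOR\tSE",
               "rs1\t1\t1000\tA\tG\t0.3\t1.05\t0.01"), path)
  cm <- c(snp = "rsid", chrom = "chr", pos = "bp", effect_allele = "A1",
          other_allele = "A2", eaf = "freq", or = "OR", se = "SE")
  ss <- read_sumstats(path, cm, "oa")
  expect_equal(ss$records$beta, log(1.05), tolerance = 1e-10)
  expect_equal(round(ss$records$beta, 5), 0.04879)

  # no p-value column: accepted, p recomputed from z after standardization
  ss <- to_zscores(ss)
  expect_equal(ss$records$pval, 2 * pnorm(-abs(log(1.05) / 0.01)))

  expect_error(
    read_sumstats(path, c(cm, pval = "P"), "oa"),
    "absent", class = "pleioscan_config_error")
  expect_error(
    read_sumstats(path, cm[setdiff(names(cm), c("or", "se"))], "oa"),
    "effect", class = "pleioscan_config_error")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tchr", empty)
  expect_error(read_sumstats(empty, cm, "oa"), class = "pleioscan_input_error")
})

test_that("read_sumstats reads gzipped files and drops unparseable rows", {
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "w")
  writeLines(c("rsid\tchr\tbp\tA1\tA2\tbeta\tse",
               "rs1\t1\t1000\tA\tG\t0.1\t0.05",
               "rs2\t1\tnot_a_number\tA\tG\t0.1\t0.05"), con)
  close(con)
  cm <- c(snp = "rsid", chrom = "chr", pos = "bp", effect_allele = "A1",
          other_allele = "A2", beta = "beta", se = "se")
  expect_message(ss <- read_sumstats(path, cm, "toy"), "dropped 1")
  expect_equal(nrow(ss$records), 1)
  expect_equal(attr(ss, "n_dropped"), 1)
})

test_that("to_zscores sets z = beta/se, fills p, and drops invalid se", {
  ss <- sumstats(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = 1L, pos = c(1, 2, 3) * 1000,
    effect_allele = "A", other_allele = "G",
    beta = c(0.1, 0, 0.1), se = c(0.05, 0.05, -1),
    stringsAsFactors = FALSE), "toy")
  expect_message(out <- to_zscores(ss), "se <= 0")
  expect_equal(out$records$z, c(2, 0))
  expect_equal(out$records$pval[1], 0.0455, tolerance = 1e-4)
  expect_equal(out$records$pval[2], 1)
  expect_equal(attr(out, "n_dropped_se"), 1)
})

test_that("harmonize matches the 8-case allele/strand orientation truth table", {
  panel <- one_snp_panel(ref = "A", alt = "G", af = 0.3)
  # hand-enumerated truth: (EA, OA) -> (expected outcome, sign multiplier)
  cases <- list(
    list(ea = "G", oa = "A", out = "keep", mult = +1),  # direct, alt first
    list(ea = "A", oa = "G", out = "keep", mult = -1),  # direct, swapped
    list(ea = "C", oa = "T", out = "keep", mult = +1),  # complement strand
    list(ea = "T", oa = "C", out = "keep", mult = -1),  # complement + swapped
    list(ea = "G", oa = "T", out = "incompatible_alleles"),
    list(ea = "A", oa = "C", out = "incompatible_alleles"),
    list(ea = "C", oa = "A", out = "incompatible_alleles"),
    list(ea = "T", oa = "G", out = "incompatible_alleles")
  )
  for (cs in cases) {
    # the study reports the frequency of ITS effect allele: ~0.28 when that
    # allele is alt-like, ~0.72 when it is ref-like
    eaf_in <- if (identical(cs$out, "keep") && cs$mult < 0) 0.72 else 0.28
    ss <- mk_ss("rs1", cs$ea, cs$oa, beta = 0.1, eaf = eaf_in)
    if (identical(cs$out, "keep")) {
      h <- harmonize(ss, panel)
      expect_equal(h$report$n_output, 1)
      expect_equal(h$sumstats$records$beta, cs$mult * 0.1,
                   info = paste(cs$ea, cs$oa))
      expect_equal(h$sumstats$records$z, cs$mult * 5)
      expect_equal(h$sumstats$records$eaf, 0.28)
      expect_equal(h$sumstats$records$effect_allele, "G")
      expect_equal(h$sumstats$records$other_allele, "A")
      expect_equal(h$report$n_sign_flipped, as.integer(cs$mult < 0))
    } else {
      expect_error(harmonize(ss, panel), class = "pleioscan_pipeline_error")
      # with a surviving companion SNP the removal is itemized, not fatal
      panel2 <- ref_panel(
        data.frame(snp_id = c("rs1", "rs2"), chrom = 1L, pos = c(100L, 200L),
                   ref_allele = "A", alt_allele = "G", alt_freq = 0.3,
                   block_id = c("1", "2"), stringsAsFactors = FALSE),
        blocks = list("1" = matrix(1, 1, 1), "2" = matrix(1, 1, 1)))
      ss2 <- mk_ss(c("rs1", "rs2"), c(cs$ea, "G"), c(cs$oa, "A"),
                   beta = c(0.1, 0.1), eaf = 0.28, pos = c(100L, 200L))
      h <- harmonize(ss2, panel2)
      expect_equal(unname(h$report$removals["incompatible_alleles"]), 1L,
                   info = paste(cs$ea, cs$oa))
    }
  }
})

test_that("QC filters: rare, palindromic-ambiguous, frequency-discordant", {
  pal_panel <- one_snp_panel(ref = "A", alt = "T", af = 0.75)

  # ambiguous palindrome: frequency near 0.5
  h <- harmonize(rbind_ss(mk_ss("rs1", "T", "A", 0.1, eaf = 0.45),
                          keeper(pal_panel)), pal_panel2(pal_panel))
  expect_equal(unname(h$report$removals["palindromic_ambiguous"]), 1L)

  # resolvable palindrome: oriented by frequency match (0.8 vs panel 0.75)
  h <- harmonize(mk_ss("rs1", "T", "A", 0.1, eaf = 0.8), pal_panel)
  expect_equal(h$sumstats$records$beta, 0.1)
  expect_equal(h$report$n_sign_flipped, 0L)
  # mirrored frequency: flipped
  h <- harmonize(mk_ss("rs1", "T", "A", 0.1, eaf = 0.2), pal_panel)
  expect_equal(h$sumstats$records$beta, -0.1)
  expect_equal(h$sumstats$records$eaf, 0.8)

  # rare variant
  panel <- one_snp_panel()
  ss <- rbind_ss(mk_ss("rs1", "G", "A", 0.1, eaf = 0.005), NULL)
  expect_error(harmonize(ss, panel), class = "pleioscan_pipeline_error")
  # and itemized when others survive
  panel2 <- pal_panel2(panel)
  h <- harmonize(rbind_ss(mk_ss("rs1", "G", "A", 0.1, eaf = 0.005),
                          keeper(panel)), panel2)
  expect_equal(unname(h$report$removals["rare"]), 1L)

  # allele-frequency discordance after orientation
  disc_panel <- one_snp_panel(ref = "A", alt = "G", af = 0.9)
  h <- harmonize(rbind_ss(mk_ss("rs1", "G", "A", 0.1, eaf = 0.2),
                          keeper(disc_panel)), pal_panel2(disc_panel))
  expect_equal(unname(h$report$removals["af_discordant"]), 1L)
})

test_that("duplicates keep the smallest-se record; conservation always holds", {
  panel <- one_snp_panel()
  ss <- suppressWarnings(
    mk_ss(c("rs1", "rs1"), "G", "A", beta = c(0.1, 0.2), se = c(0.05, 0.02)))
  h <- harmonize(ss, panel)
  expect_equal(h$report$n_output, 1)
  expect_equal(h$sumstats$records$beta, 0.2)  # se = 0.02 record wins
  expect_equal(unname(h$report$removals["duplicate"]), 1L)
  expect_equal(h$report$n_input,
               h$report$n_output + sum(h$report$removals))
})

test_that("harmonize is idempotent and allele-flip-equivariant on simulated data", {
  pan <- make_reference_panel(panel_config(m_snps = 400, block_size = 10,
                                           ld_rho = 0.4, seed = 5))
  pair <- simulate_pair(sim_config(pi1 = 0.02, pi2 = 0.02, pi12 = 0.01,
                                   sigma_b1_sq = 1e-4, sigma_b2_sq = 1e-4,
                                   n1 = 5e4, n2 = 5e4, seed = 9), pan)
  ss <- pair$ss1
  # scramble: swap alleles and negate effects on a random half of records
  set.seed(1)
  flip <- sample(c(TRUE, FALSE), nrow(ss$records), replace = TRUE)
  sc <- ss
  sc$records[flip, c("effect_allele", "other_allele")] <-
    sc$records[flip, c("other_allele", "effect_allele")]
  sc$records$beta[flip] <- -sc$records$beta[flip]
  sc$records$z[flip] <- -sc$records$z[flip]
  sc$records$eaf[flip] <- 1 - sc$records$eaf[flip]

  h1 <- harmonize(ss, pan)
  h2 <- harmonize(sc, pan)
  # allele-flip equivalence: identical harmonized output
  expect_equal(h2$sumstats$records, h1$sumstats$records)

  # idempotence: second pass removes and flips nothing
  h3 <- harmonize(h1$sumstats, pan)
  expect_equal(sum(h3$report$removals), 0L)
  expect_equal(h3$report$n_sign_flipped, 0L)
  expect_equal(h3$sumstats$records, h1$sumstats$records)

  # conservation
  expect_equal(h1$report$n_input, h1$report$n_output + sum(h1$report$removals))
})

test_that("non-autosomal and non-rsID records are filtered", {
  panel <- one_snp_panel()
  panel2 <- pal_panel2(panel)
  ss <- mk_ss(c("rs1", "chr_snp", "rs1000"), "G", "A", beta = 0.1,
              chrom = c(1L, 1L, 23L), pos = c(100L, 150L, 200L))
  h <- harmonize(ss, panel2)
  expect_equal(unname(h$report$removals["missing_rsid"]), 1L)
  expect_equal(unname(h$report$removals["non_autosomal"]), 1L)
  expect_equal(h$report$n_output, 1)
})

test_that("sumstats round-trip through the TSV dialect", {
  pan <- make_reference_panel(panel_config(m_snps = 50, block_size = 5, seed = 2))
  pair <- simulate_pair(sim_config(pi1 = 0.1, pi2 = 0.1, pi12 = 0.05,
                                   sigma_b1_sq = 1e-3, sigma_b2_sq = 1e-3,
                                   n1 = 1e4, n2 = 1e4, seed = 2), pan)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(pair$ss1, path)
  back <- read_sumstats(path, default_column_map_test(), "trait1")
  expect_equal(back$records$beta, pair$ss1$records$beta, tolerance = 1e-12)
  expect_equal(back$records$snp_id, pair$ss1$records$snp_id)
})
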