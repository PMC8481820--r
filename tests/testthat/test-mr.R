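test_that("instrument selection: inclusive threshold, pruning oracle, shortage", {
  v <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = 1L, pos = c(1000, 2000, 9e6),
    ref_allele = "A", alt_allele = "G", alt_freq = 0.3,
    block_id = c("1", "1", "2"), stringsAsFactors = FALSE)
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, 2)
  pan <- ref_panel(v, list("1" = r, "2" = matrix(1, 1, 1)))

  z_at <- function(p) qnorm(p / 2, lower.tail = FALSE)
  # rs1 exactly at 5e-8 (inclusive), rs2 stronger but r2 = 0.5 with rs1,
  # rs3 distant and strong
  betas <- 0.02 * z_at(c(5e-8, 1e-9, 1e-9))
  expo <- mk_ss(c("rs1", "rs2", "rs3"), "G", "A", beta = betas,
                pos = v$pos, trait = "expo")
  outc <- mk_ss(c("rs1", "rs2", "rs3"), "G", "A", beta = betas * 0.3,
                pos = v$pos, trait = "outc")
  inst <- select_instruments(expo, outc, pan,
                             mr_params(min_instruments = 1))
  # best-p of the correlated pair (rs2) kept, rs1 pruned; rs3 independent
  expect_setequal(inst$snp_id, c("rs2", "rs3"))

  # boundary: exactly 5e-8 retained when alone
  solo <- select_instruments(
    mk_ss("rs3", "G", "A", beta = 0.02 * z_at(5e-8), pos = 9e6),
    outc, pan, mr_params(min_instruments = 1))
  expect_equal(solo$snp_id, "rs3")

  weak <- mk_ss(c("rs1", "rs2", "rs3"), "G", "A", beta = 1e-4, pos = v$pos)
  expect_error(select_instruments(weak, outc, pan, mr_params()),
               "shortage", class = "pleioscan_estimation_error")
})

test_that("Wald ratio and delta-method SE match independent evaluations", {
  inst <- data.frame(snp_id = c("a", "b", "c"),
                     b_zx = c(0.1, 0.10, 0.1), se_zx = c(0.02, 0.01, 0.01),
                     b_zy = c(0.05, 0.02, 0), se_zy = c(0.01, 0.005, 0.004))
  w <- wald_ratio(inst)
  expect_equal(w$wald_ratio, c(0.5, 0.2, 0))
  expect_equal(w$wald_se[2], 0.0538516, tolerance = 1e-6)
  expect_equal(w$wald_se[3], 0.004 / 0.1)  # null outcome effect

  zz <- rbind(inst, data.frame(snp_id = "z", b_zx = 0, se_zx = 0.01,
                               b_zy = 0.01, se_zy = 0.01))
  expect_message(w2 <- wald_ratio(zz), "zero exposure")
  expect_equal(nrow(w2), 3)
})

test_that("IVW estimate: degenerate cases and weighted-regression oracle", {
  one <- wald_ratio(data.frame(snp_id = "a", b_zx = 0.1, se_zx = 0.01,
                               b_zy = 0.03, se_zy = 0.01))
  expect_equal(mr_estimate(one)$beta_xy, 0.3)

  two <- data.frame(snp_id = c("a", "b"), b_zx = 1, se_zx = 0,
                    b_zy = c(0.1, 0.3), se_zy = 0.05)
  expect_equal(mr_estimate(wald_ratio(two))$beta_xy, 0.2)

  # with first-order wald SE (se_zy / |b_zx|), IVW equals WLS of b_zy on
  # b_zx through the origin with weights 1 / se_zy^2
  set.seed(3)
  inst <- data.frame(snp_id = sprintf("rs%d", 1:30),
                     b_zx = rnorm(30, 0.2, 0.05), se_zx = 0.01,
                     b_zy = rnorm(30, 0.05, 0.02),
                     se_zy = runif(30, 0.005, 0.02))
  inst$wald_ratio <- inst$b_zy / inst$b_zx
  inst$wald_se <- inst$se_zy / abs(inst$b_zx)   # first-order term only
  got <- mr_estimate(inst)$beta_xy
  wls <- sum(inst$b_zx * inst$b_zy / inst$se_zy^2) /
    sum(inst$b_zx^2 / inst$se_zy^2)
  expect_equal(got, wls, tolerance = 1e-10)

  expect_error(mr_estimate(inst[0, ]), class = "pleioscan_input_error")
})

test_that("MR is exactly scale-equivariant in the outcome", {
  set.seed(4)
  inst <- wald_ratio(data.frame(
    snp_id = sprintf("rs%d", 1:20), b_zx = rnorm(20, 0.2, 0.03),
    se_zx = 0.01, b_zy = rnorm(20, 0.04, 0.02), se_zy = 0.01))
  base <- mr_estimate(inst)
  sc <- inst
  sc$b_zy <- 5 * sc$b_zy
  sc$se_zy <- 5 * sc$se_zy
  scaled <- mr_estimate(wald_ratio(sc[, c("snp_id", "b_zx", "se_zx",
                                          "b_zy", "se_zy")]))
  expect_equal(scaled$beta_xy, 5 * base$beta_xy, tolerance = 1e-10)
  expect_equal(scaled$se_xy, 5 * base$se_xy, tolerance = 1e-10)
})

test_that("HEIDI: no removals when homogeneous, exact removal of a planted outlier", {
  same <- wald_ratio(data.frame(
    snp_id = sprintf("rs%d", 1:10), b_zx = 0.2, se_zx = 0.01,
    b_zy = 0.04, se_zy = 0.01))
  hf <- heidi_filter(same)
  expect_equal(nrow(hf$removed), 0)

  # 20 concordant instruments plus one displaced by ~10 combined SEs
  set.seed(5)
  base <- data.frame(snp_id = sprintf("rs%d", 1:21),
                     b_zx = 0.2, se_zx = 1e-6,
                     b_zy = 0.2 * 0.2 + rnorm(21, 0, 0.002), se_zy = 0.01)
  inst <- wald_ratio(base)
  comb <- sqrt(inst$wald_se[21]^2 + (1 / sqrt(sum(1 / inst$wald_se[-21]^2)))^2)
  inst$wald_ratio[21] <- mean(inst$wald_ratio[-21]) + 10 * comb
  hf <- heidi_filter(inst)
  expect_equal(hf$removed$snp_id, "rs21")

  # boundary: heidi_p exactly at the threshold is retained (strict <)
  probe <- heidi_filter(inst, mr_params(heidi_p_threshold = 0))$retained
  p21 <- probe$heidi_p[probe$snp_id == "rs21"]
  at_thr <- heidi_filter(inst, mr_params(heidi_p_threshold = p21))
  expect_true("rs21" %in% at_thr$retained$snp_id)

  expect_error(heidi_filter(same[1:2, ]), class = "pleioscan_input_error")
})

test_that("HEIDI detection p-value is monotone in outlier displacement", {
  set.seed(6)
  base <- wald_ratio(data.frame(
    snp_id = sprintf("rs%d", 1:15), b_zx = 0.2, se_zx = 1e-6,
    b_zy = 0.04 + rnorm(15, 0, 0.001), se_zy = 0.01))
  comb <- sqrt(base$wald_se[15]^2 + (1 / sqrt(sum(1 / base$wald_se[-15]^2)))^2)
  p_at <- vapply(c(3, 5, 10), function(d) {
    x <- base
    x$wald_ratio[15] <- mean(x$wald_ratio[-15]) + d * comb
    hf <- heidi_filter(x, mr_params(heidi_p_threshold = 0))
    hf$retained$heidi_p[hf$retained$snp_id == "rs15"]
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
  expect_lt(p_at[3], 0.01)   # a 10-SE outlier is flagged at the default threshold
})

test_that("bidirectional MR recovers a one-way causal effect and swaps labels", {
  pan <- make_reference_panel(panel_config(m_snps = 20000, block_size = 50,
                                           ld_rho = 0.5, seed = 7))
  cfg <- sim_config(pi1 = 0.002, pi2 = 0.002, pi12 = 0,
                    sigma_b1_sq = 5e-4, sigma_b2_sq = 5e-4,
                    rho_beta = 0, n1 = 1e5, n2 = 1e5, b_xy = 0.2, seed = 8)
  pair <- simulate_pair(cfg, pan)
  mr <- bidirectional_mr(pair$ss1, pair$ss2, pan)
  expect_s3_class(mr$forward, "mr_result")
  expect_lt(mr$forward$pval, 1e-6)
  expect_lt(abs(mr$forward$beta_xy - 0.2), 3 * mr$forward$se_xy)

  swapped <- bidirectional_mr(pair$ss2, pair$ss1, pan)
  expect_equal(swapped$forward$beta_xy, mr$reverse$beta_xy)
  expect_equal(swapped$reverse$beta_xy, mr$forward$beta_xy)
  expect_equal(swapped$forward$direction, "trait2->trait1")

  # per-direction failures do not abort the other direction
  weak <- pair$ss2
  weak$records$pval <- pmax(weak$records$pval, 0.5)
  mr2 <- bidirectional_mr(pair$ss1, weak, pan)
  expect_s3_class(mr2$forward, "mr_result")
  expect_s3_class(mr2$reverse, "condition")
})

test_that("under a null architecture both directions are non-significant", {
  pan <- make_reference_panel(panel_config(m_snps = 10000, block_size = 50,
                                           ld_rho = 0.5, seed = 9))
  hits <- 0; runs <- 0
  for (s in 1:10) {
    cfg <- sim_config(pi1 = 0.003, pi2 = 0.003, pi12 = 0,
                      sigma_b1_sq = 5e-4, sigma_b2_sq = 5e-4,
                      rho_beta = 0, n1 = 1e5, n2 = 1e5, b_xy = 0, seed = 500 + s)
    pair <- simulate_pair(cfg, pan)
    mr <- bidirectional_mr(pair$ss1, pair$ss2, pan,
                           mr_params(min_instruments = 3))
    for (r in list(mr$forward, mr$reverse)) {
      if (inherits(r, "mr_result")) {
        runs <- runs + 1
        hits <- hits + (r$pval < 0.05)
      }
    }
  }
  expect_gt(runs, 10)
  expect_lte(hits / runs, 0.1 + 2 * sqrt(0.05 * 0.95 / runs))
})

test_that("HEIDI reduces pleiotropy-induced bias under shared architecture", {
  pan <- make_reference_panel(panel_config(m_snps = 20000, block_size = 50,
                                           ld_rho = 0.5, seed = 10))
  raw <- c(); filt <- c()
  for (s in 1:8) {
    # trait-1 instruments: mostly specific (ratio ~ 0), a minority shared
    # with strongly correlated effects (ratio ~ rho * s2/s1)
    cfg <- sim_config(pi1 = 0.002, pi2 = 0.002, pi12 = 4e-4,
                      sigma_b1_sq = 5e-4, sigma_b2_sq = 5e-4,
                      rho_beta = 0.9, n1 = 1e5, n2 = 1e5, b_xy = 0,
                      seed = 600 + s)
    pair <- simulate_pair(cfg, pan)
    inst <- tryCatch(
      wald_ratio(select_instruments(pair$ss1, pair$ss2, pan,
                                    mr_params(min_instruments = 5))),
      pleioscan_error = function(e) NULL)
    if (is.null(inst) || nrow(inst) < 5) next
    raw <- c(raw, mr_estimate(inst)$beta_xy)
    kept <- tryCatch(heidi_filter(inst)$retained, error = function(e) inst)
    filt <- c(filt, mr_estimate(kept)$beta_xy)
  }
  expect_gt(mean(abs(raw)), 0)          # bias away from zero with HEIDI off
  expect_lte(mean(abs(filt)), mean(abs(raw)))  # reduced with HEIDI on
})
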