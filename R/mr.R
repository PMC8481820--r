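#' Mendelian-randomization parameters
#'
#' @param instrument_p_threshold genome-wide significance threshold for
#'   instrument selection, inclusive (default 5e-8).
#' @param instrument_r2 pairwise LD ceiling for instruments (default 0.05).
#' @param instrument_window_kb pruning window in kb (default 1000).
#' @param heidi_p_threshold instruments with heterogeneity p below this are
#'   removed; strictly-less-than (default 0.01).
#' @param min_instruments minimum surviving instruments (default 10, the
#'   convention of the reference method; lower for toy runs).
#' @return A list of class `mr_params`.
#' @export
mr_params <- function(instrument_p_threshold = 5e-8, instrument_r2 = 0.05,
                      instrument_window_kb = 1000, heidi_p_threshold = 0.01,
                      min_instruments = 10) {
  if (instrument_p_threshold <= 0 || instrument_p_threshold > 1 ||
      instrument_r2 <= 0 || instrument_r2 > 1 ||
      heidi_p_threshold < 0 || heidi_p_threshold > 1 || min_instruments < 1) {
    abort_config("invalid MR parameter value")
  }
  structure(list(instrument_p_threshold = instrument_p_threshold,
                 instrument_r2 = instrument_r2,
                 instrument_window_kb = instrument_window_kb,
                 heidi_p_threshold = heidi_p_threshold,
                 min_instruments = min_instruments),
            class = "mr_params")
}

#' Select LD-independent instruments for two-sample MR
#'
#' Exposure SNPs at `p <= instrument_p_threshold` (threshold inclusive) are
#' greedily pruned best-p first to pairwise `r2 < instrument_r2` within
#' `instrument_window_kb`, then intersected with the outcome SNP set.
#' Instruments with a zero exposure effect are dropped, never imputed.
#'
#' @param exposure,outcome harmonized [sumstats] objects on the same panel.
#' @param panel a [ref_panel].
#' @param params an [mr_params].
#' @return data.frame of instruments: `snp_id`, `b_zx`, `se_zx`, `b_zy`,
#'   `se_zy` (plus `chrom`, `pos`).
#' @export
select_instruments <- function(exposure, outcome, panel, params = mr_params()) {
  ex <- exposure$records
  sig <- ex[!is.na(ex$pval) & ex$pval <= params$instrument_p_threshold, ,
            drop = FALSE]
  sig <- sig[sig$snp_id %in% outcome$records$snp_id, , drop = FALSE]
  sig <- sig[sig$beta != 0, , drop = FALSE]
  sig <- sig[order(sig$pval, sig$chrom, sig$pos, sig$snp_id), , drop = FALSE]

  kept <- integer(0)
  win <- params$instrument_window_kb * 1000
  for (i in seq_len(nrow(sig))) {
    ok <- TRUE
    for (j in kept) {
      near <- sig$chrom[i] == sig$chrom[j] & abs(sig$pos[i] - sig$pos[j]) <= win
      if (near && panel_r2(panel, sig$snp_id[i], sig$snp_id[j]) >= params$instrument_r2) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sig <- sig[kept, , drop = FALSE]
  if (nrow(sig) < params$min_instruments) {
    abort_estimation(sprintf(
      "instrument shortage: %d LD-independent genome-wide significant SNP(s), need >= %d",
      nrow(sig), params$min_instruments))
  }
  om <- outcome$records[match(sig$snp_id, outcome$records$snp_id), ]
  data.frame(snp_id = sig$snp_id, chrom = sig$chrom, pos = sig$pos,
             b_zx = sig$beta, se_zx = sig$se,
             b_zy = om$beta, se_zy = om$se,
             stringsAsFactors = FALSE)
}

#' Wald ratios and delta-method standard errors
#'
#' `ratio = b_zy / b_zx`;
#' `se = sqrt((se_zy^2 + ratio^2 * se_zx^2) / b_zx^2)`. Instruments with
#' `b_zx = 0` are dropped with a message.
#'
#' @param instruments data.frame from [select_instruments()] (columns `b_zx`,
#'   `se_zx`, `b_zy`, `se_zy`).
#' @return The data.frame with `wald_ratio` and `wald_se` columns added.
#' @export
wald_ratio <- function(instruments) {
  zero <- instruments$b_zx == 0
  if (any(zero)) {
    message(sprintf("wald_ratio: dropped %d instrument(s) with zero exposure effect",
                    sum(zero)))
    instruments <- instruments[!zero, , drop = FALSE]
  }
  instruments$wald_ratio <- instruments$b_zy / instruments$b_zx
  instruments$wald_se <- sqrt((instruments$se_zy^2 +
                                 instruments$wald_ratio^2 * instruments$se_zx^2) /
                                instruments$b_zx^2)
  instruments
}

#' Inverse-variance-weighted causal estimate over Wald ratios
#'
#' `beta_xy = sum(ratio_i / se_i^2) / sum(1 / se_i^2)`,
#' `se_xy = 1 / sqrt(sum(1 / se_i^2))`, two-sided normal p-value. Used in
#' place of the generalized least-squares estimator over LD-correlated
#' instruments: with instruments pruned to pairwise `r2 < 0.05` the LD
#' correction term is second-order (the deviation is recorded in the result's
#' `method` field).
#'
#' @param instruments data.frame with `wald_ratio` and `wald_se` set.
#' @param direction label such as `"trait1->trait2"`.
#' @return list of class `mr_result`: `direction`, `beta_xy`, `se_xy`,
#'   `pval`, `n_instruments_initial`, `n_instruments_final`, `removed_snps`,
#'   `method`.
#' @export
mr_estimate <- function(instruments, direction = "exposure->outcome") {
  if (is.null(instruments) || nrow(instruments) == 0) {
    abort_input("no instruments with Wald ratios supplied")
  }
  if (is.null(instruments$wald_ratio)) abort_config("run wald_ratio() first")
  w <- 1 / instruments$wald_se^2
  beta <- sum(instruments$wald_ratio * w) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(
    direction = direction, beta_xy = beta, se_xy = se,
    pval = p_from_z(beta / se),
    n_instruments_initial = nrow(instruments),
    n_instruments_final = nrow(instruments),
    removed_snps = data.frame(snp_id = character(0), heidi_p = numeric(0)),
    method = "IVW over LD-pruned instruments"
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result %s> beta=%.4f (SE %.4f, p=%.3g), instruments %d -> %d [%s]\n",
              x$direction, x$beta_xy, x$se_xy, x$pval,
              x$n_instruments_initial, x$n_instruments_final, x$method))
  invisible(x)
}

#' HEIDI-style single-pass outlier removal
#'
#' For each instrument, the deviation of its Wald ratio from the leave-one-out
#' IVW estimate is tested: `z_i = (ratio_i - beta(-i)) /
#' sqrt(wald_se_i^2 + se(beta(-i))^2)` with a two-sided normal p. Instruments
#' with `heidi_p < heidi_p_threshold` (strict) are removed in a single pass.
#' The leave-one-out reference (rather than a top-instrument reference) keeps
#' the test symmetric across instruments.
#'
#' @param instruments data.frame with Wald fields set (at least 3 rows).
#' @param params an [mr_params].
#' @return list with `retained` and `removed` data.frames, both carrying a
#'   `heidi_p` column.
#' @export
heidi_filter <- function(instruments, params = mr_params()) {
  n <- nrow(instruments)
  if (n < 3) abort_input("HEIDI filtering needs at least 3 instruments")
  w <- 1 / instruments$wald_se^2
  sw <- sum(w)
  swr <- sum(w * instruments$wald_ratio)
  beta_loo <- (swr - w * instruments$wald_ratio) / (sw - w)
  se_loo <- 1 / sqrt(sw - w)
  zi <- (instruments$wald_ratio - beta_loo) /
    sqrt(instruments$wald_se^2 + se_loo^2)
  instruments$heidi_p <- p_from_z(zi)
  drop <- instruments$heidi_p < params$heidi_p_threshold
  if (all(drop)) {
    abort_estimation("HEIDI removed every instrument; review heidi_p_threshold")
  }
  list(retained = instruments[!drop, , drop = FALSE],
       removed = instruments[drop, , drop = FALSE])
}

run_mr_direction <- function(exposure, outcome, panel, params, direction) {
  inst <- select_instruments(exposure, outcome, panel, params)
  inst <- wald_ratio(inst)
  n_init <- nrow(inst)
  removed <- data.frame(snp_id = character(0), heidi_p = numeric(0))
  if (n_init >= 3) {
    hf <- heidi_filter(inst, params)
    inst <- hf$retained
    removed <- hf$removed[, c("snp_id", "heidi_p")]
  }
  res <- mr_estimate(inst, direction = direction)
  res$n_instruments_initial <- n_init
  res$n_instruments_final <- nrow(inst)
  res$removed_snps <- removed
  res$instruments <- inst
  res
}

#' Bidirectional two-sample Mendelian randomization
#'
#' Runs instrument selection, Wald ratios, HEIDI outlier removal and IVW
#' estimation in each direction independently. A failure in one direction
#' (e.g. instrument shortage) is recorded without aborting the other.
#'
#' @param ss_a,ss_b harmonized [sumstats] objects.
#' @param panel a [ref_panel].
#' @param params an [mr_params].
#' @return list of class `mr_bidirectional` with elements `forward`
#'   (`a -> b`) and `reverse` (`b -> a`), each an `mr_result` or a condition
#'   object if that direction failed, plus `summary` (a data.frame with one
#'   row per successful direction).
#' @export
bidirectional_mr <- function(ss_a, ss_b, panel, params = mr_params()) {
  lab <- function(x, y) paste0(x$trait_label, "->", y$trait_label)
  fwd <- tryCatch(run_mr_direction(ss_a, ss_b, panel, params, lab(ss_a, ss_b)),
                  pleioscan_error = function(e) e)
  rev <- tryCatch(run_mr_direction(ss_b, ss_a, panel, params, lab(ss_b, ss_a)),
                  pleioscan_error = function(e) e)
  rows <- lapply(list(fwd, rev), function(r) {
    if (inherits(r, "mr_result")) {
      data.frame(direction = r$direction, beta = r$beta_xy, se = r$se_xy,
                 pval = r$pval, n_initial = r$n_instruments_initial,
                 n_final = r$n_instruments_final, stringsAsFactors = FALSE)
    }
  })
  structure(list(forward = fwd, reverse = rev,
                 summary = do.call(rbind, rows[!vapply(rows, is.null, logical(1))])),
            class = "mr_bidirectional")
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  for (r in list(x$forward, x$reverse)) {
    if (inherits(r, "mr_result")) print(r) else cat("  direction failed:",
                                                    conditionMessage(r), "\n")
  }
  invisible(x)
}
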