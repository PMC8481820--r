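#' @title Genetic-architecture estimation
#' @description LD-score-regression heritability and genetic correlation with
#'   delete-one-block jackknife errors, liability-scale conversion, a
#'   Gaussian-mixture ("MiXeR-lite") estimator of polygenicity and
#'   discoverability, and a binomial sign-concordance test.
#' @name architecture
NULL

# Align a sumstats object with panel LD scores, in genomic order.
align_ld <- function(ss, panel) {
  rec <- ss$records
  l2 <- panel$ld_scores[rec$snp_id]
  keep <- !is.na(l2)
  rec <- rec[keep, , drop = FALSE]
  l2 <- l2[keep]
  ord <- order(rec$chrom, rec$pos, rec$snp_id)
  list(rec = rec[ord, , drop = FALSE], l2 = as.numeric(l2)[ord])
}

# Full and leave-one-block WLS fits from per-block sufficient statistics.
wls_with_jackknife <- function(stats_blocks) {
  tot <- lapply(stats_blocks, sum)
  full <- wls_coef(tot$sw, tot$swx, tot$swxx, tot$swy, tot$swxy)
  nb <- length(stats_blocks$sw)
  del <- matrix(NA_real_, nb, 2)
  for (b in seq_len(nb)) {
    del[b, ] <- wls_coef(tot$sw - stats_blocks$sw[b],
                         tot$swx - stats_blocks$swx[b],
                         tot$swxx - stats_blocks$swxx[b],
                         tot$swy - stats_blocks$swy[b],
                         tot$swxy - stats_blocks$swxy[b])
  }
  list(full = full, delete_one = del)
}

#' SNP heritability by LD score regression
#'
#' Weighted least-squares fit of `z^2` on the LD score `l` under
#' `E[z^2] = intercept + n * h2 * l / M`, with heteroskedasticity weights
#' `1 / max(1, l)` (single pass, no iterative reweighting). The intercept is
#' free: under pure polygenicity it sits at 1, and uncorrected confounding
#' inflates it above 1. Standard errors come from a delete-one-block jackknife
#' over contiguous genomic blocks.
#'
#' @param ss a harmonized, standardized [sumstats] object.
#' @param panel a [ref_panel] providing LD scores.
#' @param n sample size; defaults to the median of the records' `n` column.
#' @param n_jackknife_blocks number of contiguous jackknife blocks (default 200).
#' @param pop_prev,sample_prev optional population and sample prevalences; when
#'   both are given, `h2_liability` is filled via [liability_scale()].
#' @param chisq_max optional cap: SNPs with `z^2` above it are excluded
#'   (default `Inf`, i.e. no exclusion).
#' @return list of class `ldsc_h2`: `h2_obs`, `h2_se`, `intercept`,
#'   `intercept_se`, `h2_liability`, `n_snps`, `m`.
#' @export
ldsc_h2 <- function(ss, panel, n = NULL, n_jackknife_blocks = 200,
                    pop_prev = NULL, sample_prev = NULL, chisq_max = Inf) {
  al <- align_ld(ss, panel)
  n <- n %||% stats::median(al$rec$n, na.rm = TRUE)
  if (!is.finite(n) || n <= 0) {
    abort_config("sample size n unavailable; supply n or a per-file constant")
  }
  y <- al$rec$z^2
  keep <- y <= chisq_max
  y <- y[keep]
  l2 <- al$l2[keep]
  m <- length(y)
  if (stats::sd(l2) == 0) abort_estimation("LD scores constant across SNPs: design degenerate")
  blocks <- contiguous_blocks(m, n_jackknife_blocks)
  w <- 1 / pmax(1, l2)
  fits <- wls_with_jackknife(wls_block_stats(l2, y, w, blocks))
  h2 <- fits$full[["slope"]] * m / n
  h2_del <- fits$delete_one[, 2] * m / n
  h2_lia <- NULL
  if (!is.null(pop_prev) && !is.null(sample_prev)) {
    h2_lia <- liability_scale(h2, pop_prev, sample_prev)
  }
  structure(list(
    h2_obs = h2, h2_se = jackknife_se(h2_del),
    intercept = fits$full[["intercept"]],
    intercept_se = jackknife_se(fits$delete_one[, 1]),
    h2_liability = h2_lia, n_snps = m, m = m, n = n
  ), class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("<ldsc_h2> h2_obs=%.4f (SE %.4f), intercept=%.4f (SE %.4f), %d SNPs\n",
              x$h2_obs, x$h2_se, x$intercept, x$intercept_se, x$n_snps))
  if (!is.null(x$h2_liability)) cat(sprintf("  h2_liability=%.4f\n", x$h2_liability))
  invisible(x)
}

#' Genetic correlation by cross-trait LD score regression
#'
#' Regresses `z1 * z2` on the LD score with slope
#' `sqrt(n1 * n2) * rho_g / M` and a free intercept (which absorbs sample
#' overlap), combines with the two univariate fits into
#' `rg = rho_g / sqrt(h2_1 * h2_2)`, and jackknifes the full rg functional
#' over contiguous blocks. `rg` is not clamped to `[-1, 1]`; out-of-range
#' estimates set `warning_flag`.
#'
#' @param ss1,ss2 harmonized, standardized [sumstats] objects.
#' @param panel a [ref_panel].
#' @param n1,n2 sample sizes (defaults: per-trait medians of `n`).
#' @param n_jackknife_blocks jackknife blocks (default 200).
#' @param min_shared_snps minimum shared SNP count (default 1000).
#' @return list of class `ldsc_rg`: `rg`, `rg_se`, `pval`, `gencov`,
#'   `cross_intercept`, `h2_1`, `h2_2`, `n_snps`, `warning_flag`.
#' @export
ldsc_rg <- function(ss1, ss2, panel, n1 = NULL, n2 = NULL,
                    n_jackknife_blocks = 200, min_shared_snps = 1000) {
  a1 <- align_ld(ss1, panel)
  a2 <- align_ld(ss2, panel)
  shared <- intersect(a1$rec$snp_id, a2$rec$snp_id)
  if (length(shared) < min_shared_snps) {
    abort_input(sprintf("only %d shared SNPs with LD scores (need >= %d)",
                        length(shared), min_shared_snps))
  }
  i1 <- match(shared, a1$rec$snp_id)
  r1 <- a1$rec[i1, ]
  l2 <- a1$l2[i1]
  r2 <- a2$rec[match(shared, a2$rec$snp_id), ]
  ord <- order(r1$chrom, r1$pos, r1$snp_id)
  z1 <- r1$z[ord]
  z2 <- r2$z[ord]
  l2 <- l2[ord]
  n1 <- n1 %||% stats::median(r1$n, na.rm = TRUE)
  n2 <- n2 %||% stats::median(r2$n, na.rm = TRUE)
  m <- length(shared)
  blocks <- contiguous_blocks(m, n_jackknife_blocks)
  w <- 1 / pmax(1, l2)

  f11 <- wls_with_jackknife(wls_block_stats(l2, z1^2, w, blocks))
  f22 <- wls_with_jackknife(wls_block_stats(l2, z2^2, w, blocks))
  f12 <- wls_with_jackknife(wls_block_stats(l2, z1 * z2, w, blocks))

  h2_1 <- f11$full[["slope"]] * m / n1
  h2_2 <- f22$full[["slope"]] * m / n2
  gencov <- f12$full[["slope"]] * m / sqrt(n1 * n2)
  if (h2_1 <= 0 || h2_2 <= 0) {
    abort_estimation(sprintf(
      "rg undefined: nonpositive heritability estimate (h2_1=%.4g, h2_2=%.4g)",
      h2_1, h2_2))
  }
  rg <- gencov / sqrt(h2_1 * h2_2)
  rg_del <- vapply(seq_len(n_jackknife_blocks), function(b) {
    h1b <- f11$delete_one[b, 2] * m / n1
    h2b <- f22$delete_one[b, 2] * m / n2
    gb <- f12$delete_one[b, 2] * m / sqrt(n1 * n2)
    if (h1b <= 0 || h2b <= 0) return(NA_real_)
    gb / sqrt(h1b * h2b)
  }, numeric(1))
  rg_del <- rg_del[is.finite(rg_del)]
  rg_se <- jackknife_se(rg_del)
  structure(list(
    rg = rg, rg_se = rg_se, pval = p_from_z(rg / rg_se), gencov = gencov,
    cross_intercept = f12$full[["intercept"]],
    cross_intercept_se = jackknife_se(f12$delete_one[, 1]),
    h2_1 = h2_1, h2_2 = h2_2,
    n_snps = m, warning_flag = abs(rg) > 1
  ), class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("<ldsc_rg> rg=%.4f (SE %.4f, p=%.3g), cross-intercept=%.4f, %d SNPs\n",
              x$rg, x$rg_se, x$pval, x$cross_intercept, x$n_snps))
  if (x$warning_flag) cat("  warning: |rg| exceeds 1\n")
  invisible(x)
}

#' Observed-to-liability-scale heritability conversion
#'
#' `h2_liab = h2_obs * [K(1-K)]^2 / (P(1-P) * phi(t)^2)` where `K` is the
#' population prevalence, `P` the sample (case) proportion, `t` the upper-K
#' standard-normal quantile and `phi` the standard-normal density.
#'
#' @param h2_obs observed-scale heritability.
#' @param pop_prev population prevalence K, in (0, 1).
#' @param sample_prev sample case proportion P, in (0, 1).
#' @return liability-scale heritability.
#' @export
liability_scale <- function(h2_obs, pop_prev, sample_prev) {
  if (pop_prev <= 0 || pop_prev >= 1 || sample_prev <= 0 || sample_prev >= 1) {
    abort_config("prevalences must lie strictly inside (0, 1)")
  }
  t <- stats::qnorm(1 - pop_prev)
  mult <- (pop_prev * (1 - pop_prev))^2 /
    (sample_prev * (1 - sample_prev) * stats::dnorm(t)^2)
  h2_obs * mult
}

#' Polygenicity and discoverability by Gaussian-mixture EM ("MiXeR-lite")
#'
#' Fits `z_j ~ (1 - pi) N(0, 1) + pi N(0, 1 + n * sigma_b_sq * l_j)` by
#' expectation-maximization, with the null variance fixed at 1 and the LD
#' score entering only the causal-component variance (no LD convolution of
#' causal effects — hence "MiXeR-lite"; estimates are not comparable to the
#' full convolution model's). The M-step for `sigma_b_sq` is a 1-D
#' maximization, so the log-likelihood is non-decreasing across iterations.
#'
#' @param ss a harmonized, standardized [sumstats] object.
#' @param panel a [ref_panel].
#' @param n sample size (default: median of records' `n`).
#' @param init named vector `c(pi = ..., sigma_b_sq = ...)`.
#' @param tol convergence tolerance on the log-likelihood gain (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @return list of class `mixture_estimate`: `pi_hat`, `sigma_b_sq_hat`,
#'   `n_causal_hat`, `loglik`, `loglik_trace`, `n_iter`, `converged`, `model`.
#' @export
mixer_em <- function(ss, panel, n = NULL,
                     init = c(pi = 1e-3, sigma_b_sq = 1e-5),
                     tol = 1e-6, max_iter = 200) {
  al <- align_ld(ss, panel)
  n <- n %||% stats::median(al$rec$n, na.rm = TRUE)
  z <- al$rec$z
  l2 <- al$l2
  m <- length(z)
  pi_hat <- init[["pi"]]
  sb <- init[["sigma_b_sq"]]
  if (pi_hat <= 0 || pi_hat >= 1 || sb < 0) abort_config("invalid mixture init")

  loglik_at <- function(pi_hat, sb) {
    sum(log((1 - pi_hat) * stats::dnorm(z) +
              pi_hat * stats::dnorm(z, sd = sqrt(1 + n * sb * l2)) +
              1e-320))
  }
  sb_upper <- max(max(z^2) / n, sb * 10, 1e-12)
  trace <- numeric(0)
  ll_old <- loglik_at(pi_hat, sb)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d0 <- (1 - pi_hat) * stats::dnorm(z)
    d1 <- pi_hat * stats::dnorm(z, sd = sqrt(1 + n * sb * l2))
    resp <- d1 / (d0 + d1 + 1e-320)
    pi_new <- mean(resp)
    q_sigma <- function(s) {
      v <- 1 + n * s * l2
      -0.5 * sum(resp * (log(v) + z^2 / v))
    }
    sb_new <- stats::optimize(q_sigma, c(0, sb_upper), maximum = TRUE,
                              tol = sb_upper * 1e-8)$maximum
    ll_new <- loglik_at(pi_new, sb_new)
    if (ll_new < ll_old - 1e-6) {
      # generalized EM: never accept a step that lowers the likelihood
      break
    }
    pi_hat <- pi_new
    sb <- sb_new
    trace <- c(trace, ll_new)
    if (ll_new - ll_old < tol) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  structure(list(
    pi_hat = pi_hat, sigma_b_sq_hat = sb, n_causal_hat = pi_hat * m,
    loglik = ll_old, loglik_trace = trace, n_iter = iter,
    converged = converged, model = "MiXeR-lite"
  ), class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("<mixture_estimate [%s]> pi=%.4g sigma_b_sq=%.4g n_causal=%.1f (%s, %d iter)\n",
              x$model, x$pi_hat, x$sigma_b_sq_hat, x$n_causal_hat,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Sign-concordance test between two traits
#'
#' Counts how many of trait A's index SNPs (genome-wide significant,
#' LD-independent) share their effect direction in trait B, and tests the
#' concordant fraction against 0.5 with the exact two-sided binomial test.
#' Trait-B Z scores of exactly zero count as discordant.
#'
#' @param index_snps data.frame with columns `snp_id` and `sign` (the trait-A
#'   effect direction, +1/-1), or `beta`/`z` from which signs are taken.
#' @param ss_b the other trait's [sumstats].
#' @return list of class `sign_test_result`: `n_index`, `n_concordant`,
#'   `pval`.
#' @export
sign_concordance <- function(index_snps, ss_b) {
  if (is.null(index_snps$sign)) {
    src <- index_snps$beta %||% index_snps$z
    if (is.null(src)) abort_config("index_snps needs a sign, beta or z column")
    index_snps$sign <- sign(src)
  }
  n_index <- nrow(index_snps)
  if (n_index == 0) abort_input("no index SNPs supplied")
  i <- match(index_snps$snp_id, ss_b$records$snp_id)
  if (anyNA(i)) {
    abort_input(sprintf("%d index SNP(s) absent from the second trait", sum(is.na(i))))
  }
  zb <- ss_b$records$z[i]
  if (any(zb == 0)) {
    message(sprintf("sign_concordance: %d zero Z score(s) in trait B counted as discordant",
                    sum(zb == 0)))
  }
  n_conc <- sum(sign(zb) == index_snps$sign & zb != 0)
  structure(list(
    n_index = n_index, n_concordant = n_conc,
    pval = stats::binom.test(n_conc, n_index, p = 0.5,
                             alternative = "two.sided")$p.value
  ), class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf("<sign_test> %d / %d concordant, exact binomial p = %.3g\n",
              x$n_concordant, x$n_index, x$pval))
  invisible(x)
}
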