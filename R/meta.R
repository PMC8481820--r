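#' Estimate the null cross-trait Z correlation from sample overlap
#'
#' The sample correlation of the two aligned Z vectors restricted to SNPs
#' where BOTH traits look null (`|z| <= truncation` in each; truncation is
#' exclusion, not winsorizing). The returned matrix `omega` is the K=2
#' correlation-form covariance with unit diagonal. No de-attenuation is
#' applied by default; `deattenuate = TRUE` numerically inverts the
#' correlation mapping of the doubly box-truncated standard bivariate normal,
#' recovering the untruncated null correlation (truncating both margins at
#' `|z| <= 1` shrinks a true correlation of 0.6 to about 0.25, so the plain
#' estimator under-corrects strong overlap).
#'
#' @param z1,z2 aligned Z vectors over the shared harmonized SNP set.
#' @param truncation absolute-Z threshold (default 1.0).
#' @param deattenuate apply the optional truncation de-attenuation (default
#'   FALSE, matching the plain estimator).
#' @return list of class `overlap_matrix`: `r_hat`, `omega`, `n_snps_used`,
#'   `truncation`.
#' @export
estimate_overlap <- function(z1, z2, truncation = 1.0, deattenuate = FALSE) {
  if (length(z1) != length(z2)) abort_input("z vectors must be aligned (equal length)")
  keep <- abs(z1) <= truncation & abs(z2) <= truncation
  n_used <- sum(keep)
  if (n_used < 100) {
    abort_estimation(sprintf(
      "only %d SNPs survive |z| <= %.3g truncation (need >= 100)", n_used, truncation))
  }
  r_hat <- stats::cor(z1[keep], z2[keep])
  if (deattenuate) {
    r_hat <- invert_truncated_cor(r_hat, truncation)
  }
  if (abs(r_hat) >= 1 || !is.finite(r_hat)) {
    abort_estimation(
      "estimated null correlation is degenerate (|r| >= 1); supply distinct studies")
  }
  omega <- matrix(c(1, r_hat, r_hat, 1), 2, 2)
  structure(list(r_hat = r_hat, omega = omega, n_snps_used = n_used,
                 truncation = truncation),
            class = "overlap_matrix")
}

# Correlation of a standard bivariate normal truncated to the box
# [-t, t] x [-t, t], by trapezoid quadrature on a fine grid.
truncated_box_cor <- function(rho, t, n_grid = 201) {
  x <- seq(-t, t, length.out = n_grid)
  xm <- matrix(x, n_grid, n_grid)
  ym <- t(xm)
  d <- exp(-(xm^2 - 2 * rho * xm * ym + ym^2) / (2 * (1 - rho^2))) /
    (2 * pi * sqrt(1 - rho^2))
  wv <- rep(1, n_grid)
  wv[c(1, n_grid)] <- 0.5
  d <- d * outer(wv, wv) * (x[2] - x[1])^2
  p <- sum(d)
  exy <- sum(xm * ym * d) / p
  ex2 <- sum(xm^2 * d) / p
  exy / ex2   # means are zero by symmetry; both margins share ex2
}

# Invert rho -> truncated correlation; monotone, so uniroot suffices.
invert_truncated_cor <- function(r_obs, t) {
  if (abs(r_obs) < 1e-12) return(r_obs)
  stats::uniroot(function(r) truncated_box_cor(r, t) - r_obs,
                 interval = c(-0.999, 0.999), tol = 1e-9)$root
}

#' Lin-Sullivan optimal weights for overlap-aware meta-analysis
#'
#' `w = Omega^{-1} e / (e' Omega^{-1} e)`, so the weights sum to 1 exactly.
#'
#' @param omega a K x K covariance/correlation matrix of the studies' null Z
#'   scores (an `overlap_matrix` is also accepted).
#' @return numeric weight vector of length K.
#' @export
lin_sullivan_weights <- function(omega) {
  if (inherits(omega, "overlap_matrix")) omega <- omega$omega
  k <- nrow(omega)
  e <- rep(1, k)
  x <- tryCatch(solve(omega, e),
                error = function(err) abort_estimation("omega is singular"))
  w <- x / sum(x)
  w
}

#' Overlap-corrected weighted-Z meta-analysis
#'
#' Per SNP, `Zhat = sum_k w_k Z_k / sqrt(sum_k w_k^2 +
#' sum_{k != l} w_k w_l r_kl)`, with a two-sided normal p-value attached.
#'
#' @param z_rows K x M matrix (one row per study) of aligned Z scores, or a
#'   list of K aligned vectors.
#' @param weights weight vector from [lin_sullivan_weights()].
#' @param omega the K x K null correlation matrix (or an `overlap_matrix`).
#' @param variants optional data.frame (`snp_id`, `chrom`, `pos`) aligned
#'   with the columns, carried into the result table.
#' @return list of class `meta_result`: `table` (per-SNP `z_meta`, `p_meta`,
#'   plus variant columns when given), `weights`, `omega`, `denominator`.
#' @export
meta_z <- function(z_rows, weights, omega, variants = NULL) {
  if (inherits(omega, "overlap_matrix")) omega <- omega$omega
  if (is.list(z_rows) && !is.matrix(z_rows)) z_rows <- do.call(rbind, z_rows)
  k <- nrow(z_rows)
  stopifnot(length(weights) == k, nrow(omega) == k)
  denom_sq <- sum(weights^2)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a != b) denom_sq <- denom_sq + weights[a] * weights[b] * omega[a, b]
    }
  }
  if (denom_sq <= 0) pleio_error("meta denominator non-positive", "pleioscan_numeric_error")
  zhat <- as.numeric(crossprod(weights, z_rows)) / sqrt(denom_sq)
  tab <- data.frame(z_meta = zhat, p_meta = p_from_z(zhat))
  if (!is.null(variants)) {
    stopifnot(nrow(variants) == ncol(z_rows))
    tab <- cbind(variants[, intersect(c("snp_id", "chrom", "pos"), names(variants)),
                          drop = FALSE], tab)
  }
  for (i in seq_len(k)) tab[[paste0("z_study", i)]] <- z_rows[i, ]
  structure(list(table = tab, weights = weights, omega = omega,
                 denominator = sqrt(denom_sq)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d SNPs, weights = (%s), denom = %.4f\n",
              nrow(x$table), paste(sprintf("%.3f", x$weights), collapse = ", "),
              x$denominator))
  invisible(x)
}

#' Genomic inflation factors
#'
#' `lambda_gc = median(z^2) / qchisq(0.5, 1)` and the 1,000-case /
#' 1,000-control rescaling
#' `lambda_1000 = 1 + (lambda_gc - 1) * 500 * (1/n_cases + 1/n_controls)`.
#'
#' @param z combined Z vector.
#' @param n_cases,n_controls effective case and control counts.
#' @return list with `lambda_gc` and `lambda_1000`.
#' @export
genomic_inflation <- function(z, n_cases, n_controls) {
  if (!length(z)) abort_input("empty Z vector")
  if (n_cases <= 0 || n_controls <= 0) abort_config("case/control counts must be > 0")
  lambda_gc <- stats::median(z^2) / stats::qchisq(0.5, df = 1)
  lambda_1000 <- 1 + (lambda_gc - 1) * 500 * (1 / n_cases + 1 / n_controls)
  list(lambda_gc = lambda_gc, lambda_1000 = lambda_1000)
}

#' Clumping parameters
#'
#' Defaults mirror the standard annotation-platform definition of genomic
#' risk loci: independent significant SNPs at `r2 < 0.6`, lead SNPs at
#' `r2 < 0.1`, loci merged within 250 kb.
#'
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_member SNPs with `r2 >=` this to a lead are absorbed (default 0.6).
#' @param r2_lead leads are pairwise below this `r2` (default 0.1).
#' @param merge_window_kb clumps within this distance merge (default 250).
#' @return A list of class `clump_params`.
#' @export
clump_params <- function(p_threshold = 5e-8, r2_member = 0.6, r2_lead = 0.1,
                         merge_window_kb = 250) {
  if (r2_lead > r2_member) abort_config("r2_lead must be <= r2_member")
  if (p_threshold <= 0 || p_threshold > 1) abort_config("p_threshold must lie in (0, 1]")
  if (r2_member <= 0 || r2_member > 1 || r2_lead <= 0 || r2_lead > 1) {
    abort_config("r2 thresholds must lie in (0, 1]")
  }
  structure(list(p_threshold = p_threshold, r2_member = r2_member,
                 r2_lead = r2_lead, merge_window_kb = merge_window_kb),
            class = "clump_params")
}

#' Greedy LD clumping of meta-analysis results into genomic risk loci
#'
#' Repeatedly takes the unassigned significant SNP with the smallest p-value
#' (ties broken by chromosome, position, then id). If it has `r2 >= r2_lead`
#' with an existing lead it joins that lead's clump as a member; otherwise it
#' becomes a new lead and absorbs all unassigned significant SNPs with
#' `r2 >= r2_member` to it. Clumps whose bounds lie within `merge_window_kb`
#' on the same chromosome are merged into one locus. Every significant SNP
#' ends up in exactly one locus.
#'
#' @param meta a `meta_result` whose table carries `snp_id`, `chrom`, `pos`.
#' @param panel a [ref_panel] sharing the SNP universe.
#' @param params a [clump_params].
#' @return data.frame of loci (`locus`, `chrom`, `start`, `end`, `n_leads`,
#'   `lead_snps` comma-joined best-p first, `n_members`, `min_p`), sorted by
#'   position, with the full member list in `attr(x, "members")`.
#' @export
clump_loci <- function(meta, panel, params = clump_params()) {
  tab <- meta$table
  if (is.null(tab$snp_id)) abort_config("meta result lacks variant columns")
  sig <- tab[tab$p_meta <= params$p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    message("clump_loci: no SNP passes the significance threshold")
    return(data.frame(locus = integer(0), chrom = integer(0), start = numeric(0),
                      end = numeric(0), n_leads = integer(0),
                      lead_snps = character(0), n_members = integer(0),
                      min_p = numeric(0)))
  }
  sig <- sig[order(sig$p_meta, sig$chrom, sig$pos, sig$snp_id), , drop = FALSE]

  v <- panel$variants
  pm <- match(sig$snp_id, v$snp_id)
  if (anyNA(pm)) abort_input("significant SNP absent from panel")
  blk <- v$block_id[pm]
  pos_in_block <- integer(nrow(sig))
  for (b in unique(blk)) {
    members <- which(v$block_id == b)
    sel <- which(blk == b)
    pos_in_block[sel] <- match(pm[sel], members)
  }
  r2_pair <- function(i, j) {
    if (blk[i] != blk[j]) return(0)
    panel$blocks[[blk[i]]][pos_in_block[i], pos_in_block[j]]^2
  }

  n <- nrow(sig)
  assigned <- rep(NA_integer_, n)   # clump index per significant SNP
  leads <- integer(0)               # row indices of leads, in creation order
  clump_of_lead <- integer(0)
  n_clumps <- 0
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    joined <- FALSE
    for (li in seq_along(leads)) {
      if (r2_pair(i, leads[li]) >= params$r2_lead) {
        assigned[i] <- clump_of_lead[li]
        joined <- TRUE
        break
      }
    }
    if (joined) next
    n_clumps <- n_clumps + 1
    assigned[i] <- n_clumps
    leads <- c(leads, i)
    clump_of_lead <- c(clump_of_lead, n_clumps)
    for (j in seq_len(n)) {
      if (is.na(assigned[j]) && r2_pair(i, j) >= params$r2_member) {
        assigned[j] <- n_clumps
      }
    }
  }

  clumps <- lapply(seq_len(n_clumps), function(k) {
    rows <- which(assigned == k)
    list(chrom = sig$chrom[rows[1]],
         start = min(sig$pos[rows]), end = max(sig$pos[rows]),
         leads = sig$snp_id[intersect(leads, rows)],  # leads are best-p first
         members = sig$snp_id[rows],
         min_p = min(sig$p_meta[rows]))
  })

  # merge clumps within the window on the same chromosome
  ord <- order(vapply(clumps, `[[`, numeric(1), "chrom"),
               vapply(clumps, `[[`, numeric(1), "start"))
  clumps <- clumps[ord]
  merged <- list()
  win <- params$merge_window_kb * 1000
  for (cl in clumps) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chrom == cl$chrom && cl$start - last$end <= win) {
      last$end <- max(last$end, cl$end)
      last$start <- min(last$start, cl$start)
      last$leads <- c(last$leads, cl$leads)
      last$members <- c(last$members, cl$members)
      last$min_p <- min(last$min_p, cl$min_p)
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- cl
    }
  }

  p_of <- stats::setNames(sig$p_meta, sig$snp_id)
  out <- data.frame(
    locus = seq_along(merged),
    chrom = vapply(merged, `[[`, numeric(1), "chrom"),
    start = vapply(merged, `[[`, numeric(1), "start"),
    end = vapply(merged, `[[`, numeric(1), "end"),
    n_leads = vapply(merged, function(x) length(x$leads), integer(1)),
    lead_snps = vapply(merged, function(x) {
      paste(x$leads[order(p_of[x$leads])], collapse = ",")
    }, character(1)),
    n_members = vapply(merged, function(x) length(x$members), integer(1)),
    min_p = vapply(merged, `[[`, numeric(1), "min_p"),
    stringsAsFactors = FALSE
  )
  attr(out, "members") <- lapply(merged, `[[`, "members")
  attr(out, "leads") <- lapply(merged, `[[`, "leads")
  out
}
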