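#' Read a BED-like gene annotation table
#'
#' Tab-separated columns `chrom`, `start`, `end`, `gene_id`, `strand`;
#' intervals are 1-based fully closed.
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) abort_input(paste0("annotation file not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_config(paste0("annotation lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (is.null(df$strand)) df$strand <- "+"
  if (any(df$start > df$end)) abort_input("annotation has start > end")
  df[, c("gene_id", "chrom", "start", "end", "strand")]
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, then
#' member gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors (class `gene_sets`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_input(paste0("GMT file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort_input("malformed GMT line (need id, description, members)")
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  structure(out, class = "gene_sets")
}

#' Assign SNPs to genes with a symmetric window
#'
#' A SNP is assigned to a gene iff
#' `gene.start - window <= pos <= gene.end + window` on the same chromosome;
#' a SNP inside two overlapping windows is assigned to both genes. Strand is
#' ignored (the window is symmetric).
#'
#' @param annotation data.frame as from [read_gene_annotation()].
#' @param ss a [sumstats] object supplying SNP positions.
#' @param window_kb window half-width in kb (default 20).
#' @return Named list mapping `gene_id` to character vectors of `snp_id`;
#'   genes with no assigned SNP are omitted.
#' @export
assign_snps_to_genes <- function(annotation, ss, window_kb = 20) {
  rec <- ss$records
  win <- window_kb * 1000
  out <- list()
  by_chrom <- split(rec, rec$chrom)
  for (g in seq_len(nrow(annotation))) {
    chr <- as.character(annotation$chrom[g])
    snps <- by_chrom[[chr]]
    if (is.null(snps)) next
    hit <- snps$pos >= annotation$start[g] - win &
      snps$pos <= annotation$end[g] + win
    if (any(hit)) out[[annotation$gene_id[g]]] <- snps$snp_id[hit]
  }
  if (!length(out)) {
    pleio_error("no gene received any SNP; check builds and window",
                "pleioscan_pipeline_error")
  }
  out
}

#' Eigenvalue-corrected gene-based association test
#'
#' The gene statistic is `S = sum(z_j^2)` over the gene's assigned SNPs. Under
#' the null, `S` is a mixture `sum(lambda_i chi2_1)` with `lambda_i` the
#' eigenvalues of the SNPs' LD correlation matrix; it is evaluated by
#' Satterthwaite moment matching to a scaled chi-square `a * chi2_nu` with
#' `a = Var / (2 E)`, `nu = 2 E^2 / Var`, `E = trace(R)`,
#' `Var = 2 ||R||_F^2`. With identity LD this is exactly the `chi2_m` tail.
#' A Monte-Carlo mode draws null multivariate normals instead.
#'
#' @param z numeric vector of SNP Z scores in the gene.
#' @param r_gene their LD correlation submatrix (symmetric PSD).
#' @param monte_carlo use simulation instead of moment matching.
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed seed for the Monte-Carlo mode.
#' @return The gene p-value.
#' @export
gene_test <- function(z, r_gene, monte_carlo = FALSE, n_draws = 1e5, seed = 1) {
  m <- length(z)
  r_gene <- as.matrix(r_gene)
  if (nrow(r_gene) != m || ncol(r_gene) != m) abort_input("z / r_gene dimension mismatch")
  if (max(abs(r_gene - t(r_gene))) > 1e-8) abort_input("r_gene must be symmetric")
  ev <- eigen(r_gene, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort_input("r_gene is not positive semi-definite")
  s <- sum(z^2)
  if (monte_carlo) {
    set.seed(substream_seed(seed, "gene_mc"))
    lchol <- t(chol(r_gene + diag(1e-10, m)))
    u <- matrix(stats::rnorm(m * n_draws), nrow = m)
    null_s <- colSums((lchol %*% u)^2)
    return((1 + sum(null_s >= s)) / (1 + n_draws))
  }
  e <- sum(diag(r_gene))
  v <- 2 * sum(r_gene^2)
  a <- v / (2 * e)
  nu <- 2 * e^2 / v
  stats::pchisq(s / a, df = nu, lower.tail = FALSE)
}

#' Gene p-values for meta-analysis and per-trait SNP sets
#'
#' Runs [gene_test()] per gene on the cross-disorder meta Z scores and on
#' each trait's own Z scores, reusing the same SNP-to-gene assignment and LD
#' submatrices — the three-way comparison used for pleiotropic-gene
#' prioritization.
#'
#' @param assignment named list gene -> snp ids (see [assign_snps_to_genes()]).
#' @param panel a [ref_panel].
#' @param z_meta named vector of combined Z scores (names = snp ids).
#' @param z_a,z_b optional named per-trait Z vectors.
#' @return data.frame: `gene_id`, `n_snps`, `stat`, `pval_meta`, and when the
#'   per-trait vectors are given `pval_a`, `pval_b`; plus `gene_length_kb`
#'   proxy (`n_snps`) consumers may override.
#' @export
gene_association <- function(assignment, panel, z_meta, z_a = NULL, z_b = NULL) {
  v <- panel$variants
  rows <- lapply(names(assignment), function(g) {
    ids <- intersect(assignment[[g]], names(z_meta))
    if (!length(ids)) return(NULL)
    pm <- match(ids, v$snp_id)
    # cross-block LD is zero, so the gene's LD submatrix is block-diagonal
    r <- diag(length(ids))
    for (bb in unique(v$block_id[pm])) {
      sel <- which(v$block_id[pm] == bb)
      memb <- which(v$block_id == bb)
      r[sel, sel] <- panel$blocks[[bb]][match(pm[sel], memb), match(pm[sel], memb)]
    }
    pv <- function(z) if (is.null(z)) NA_real_ else gene_test(z[ids], r)
    data.frame(gene_id = g, n_snps = length(ids),
               stat = sum(z_meta[ids]^2),
               pval_meta = gene_test(z_meta[ids], r),
               pval_a = pv(z_a), pval_b = pv(z_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) abort_input("no testable genes")
  out
}

#' Bonferroni significance threshold for gene-based tests
#'
#' @param n_genes number of genes tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  if (n_genes < 1) abort_config("n_genes must be >= 1")
  alpha / n_genes
}

#' Pleiotropic-gene prioritization filter
#'
#' Retains genes significant in the cross-disorder meta-analysis AND
#' suggestively associated with both traits individually. All comparisons are
#' inclusive (`<=`).
#'
#' @param results data.frame with `pval_meta`, `pval_a`, `pval_b`.
#' @param meta_threshold meta-analysis significance threshold (e.g. the
#'   [bonferroni_threshold()]).
#' @param per_trait_threshold suggestive per-trait threshold (default 1e-4).
#' @return The retained subset of `results`.
#' @export
pleiotropy_filter <- function(results, meta_threshold,
                              per_trait_threshold = 1e-4) {
  stopifnot(all(c("pval_meta", "pval_a", "pval_b") %in% names(results)))
  keep <- results$pval_meta <= meta_threshold &
    results$pval_a <= per_trait_threshold &
    results$pval_b <= per_trait_threshold
  results[keep & !is.na(keep), , drop = FALSE]
}

#' Competitive gene-set enrichment
#'
#' Per gene, `Z_g` is the upper-tail standard-normal quantile of the gene's
#' meta p-value (clipped to `[1e-300, 1 - 1e-16]`). For each set, ordinary
#' least squares of `Z_g` on the membership indicator plus `log(n_snps)` and
#' `log(gene_length)` covariates; the reported p-value is one-sided for a
#' positive membership coefficient (Student-t). Bonferroni-adjusted p-values
#' across the tested sets are reported alongside.
#'
#' @param results data.frame with `gene_id`, `pval_meta`, `n_snps`, and
#'   optionally `gene_length` (defaults to `n_snps` as a proxy when absent).
#' @param sets named list of member gene-id vectors (class `gene_sets` or
#'   plain list).
#' @param covariates optional data.frame overriding the per-gene covariates
#'   (`gene_id`, `n_snps`, `gene_length`).
#' @return data.frame: `set_id`, `beta_s`, `beta_se`, `pval`, `pval_bonf`,
#'   `n_in_set_tested`. Sets with fewer than 2 tested members or fewer than
#'   2 non-members are skipped with a message.
#' @export
geneset_enrichment <- function(results, sets, covariates = NULL) {
  if (!is.null(covariates)) {
    i <- match(results$gene_id, covariates$gene_id)
    results$n_snps <- covariates$n_snps[i]
    results$gene_length <- covariates$gene_length[i]
  }
  if (is.null(results$gene_length)) results$gene_length <- results$n_snps
  p <- pmin(pmax(results$pval_meta, 1e-300), 1 - 1e-16)
  if (any(results$pval_meta < 1e-300 | results$pval_meta > 1 - 1e-16,
          na.rm = TRUE)) {
    message("geneset_enrichment: gene p-value(s) clipped before probit transform")
  }
  zg <- stats::qnorm(p, lower.tail = FALSE)
  n_genes <- length(zg)
  x_cov <- cbind(1, log(results$n_snps), log(results$gene_length))
  qr_cov <- qr(x_cov)
  k_cov <- qr_cov$rank   # collapses to 2 when gene_length proxies n_snps
  z_res <- qr.resid(qr_cov, zg)

  rows <- lapply(names(sets), function(sid) {
    member <- as.numeric(results$gene_id %in% sets[[sid]])
    n_in <- sum(member)
    if (n_in < 2 || n_genes - n_in < 2) {
      message(sprintf("geneset_enrichment: set %s skipped (%d tested members)",
                      sid, n_in))
      return(NULL)
    }
    # Frisch-Waugh-Lovell: residualize membership on the covariates, then
    # the simple regression of residualized Z on residualized membership is
    # the full OLS membership coefficient
    m_res <- qr.resid(qr_cov, member)
    smm <- sum(m_res^2)
    if (smm < 1e-12) {
      message(sprintf("geneset_enrichment: set %s collinear with covariates; skipped", sid))
      return(NULL)
    }
    if (sum(z_res^2) < n_genes * 1e-20) {
      # residual gene signal is numerically zero (e.g. all-equal Z): no test
      return(data.frame(set_id = sid, beta_s = 0, beta_se = 0, pval = 0.5,
                        n_in_set_tested = n_in, stringsAsFactors = FALSE))
    }
    beta <- sum(m_res * z_res) / smm
    df <- n_genes - k_cov - 1
    sigma2 <- max(0, (sum(z_res^2) - beta^2 * smm) / df)
    se <- sqrt(sigma2 / smm)
    tstat <- if (se > 0) beta / se else 0
    data.frame(set_id = sid, beta_s = beta, beta_se = se,
               pval = stats::pt(tstat, df = df, lower.tail = FALSE),
               n_in_set_tested = n_in, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) abort_input("no testable gene sets")
  out$pval_bonf <- pmin(1, out$pval * nrow(out))
  out
}
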