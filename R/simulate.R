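#' Configuration for a simulated LD reference panel
#'
#' @param m_snps total number of variants.
#' @param block_size variants per LD block (the final block may be shorter).
#' @param ld_rho AR(1) correlation between adjacent variants within a block,
#'   in `[0, 1)`; the block correlation matrix is `r_ij = ld_rho^|i-j|`.
#' @param af_range interval from which alternate-allele frequencies are drawn.
#' @param seed integer seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(m_snps, block_size = 50, ld_rho = 0.5,
                         af_range = c(0.05, 0.95), seed = 1) {
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1) {
    abort_config("ld_rho must lie in [0, 1)")
  }
  if (m_snps < 1 || block_size < 1) abort_config("m_snps and block_size must be >= 1")
  structure(list(m_snps = as.integer(m_snps), block_size = as.integer(block_size),
                 ld_rho = ld_rho, af_range = af_range, seed = as.integer(seed)),
            class = "panel_config")
}

ar1_matrix <- function(size, rho) {
  idx <- seq_len(size)
  rho^abs(outer(idx, idx, "-"))
}

# Non-palindromic allele pairs only, so simulated data never hits the
# strand-ambiguity filter unless a test plants such variants deliberately.
ALLELE_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T")
)

#' Build a synthetic reference panel with AR(1) LD blocks
#'
#' Blocks are laid out across the 22 autosomes with 5 kb between adjacent
#' variants and a 1 Mb gap between consecutive blocks on the same chromosome,
#' so inter-block distance always exceeds typical locus-merge windows,
#' consistent with the panel's exactly-zero cross-block LD. LD scores are the
#' within-block row sums of squared correlations.
#'
#' @param cfg a [panel_config].
#' @return A [ref_panel]; deterministic given `cfg$seed`.
#' @export
make_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  m <- cfg$m_snps
  bs <- min(cfg$block_size, m)
  n_full <- m %/% bs
  rem <- m %% bs
  sizes <- c(rep(bs, n_full), if (rem > 0) rem)
  n_blocks <- length(sizes)

  chrom <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  occ <- stats::ave(seq_len(n_blocks), chrom, FUN = seq_along)
  block_span <- bs * 5000 + 1e6
  starts <- (occ - 1) * block_span + 1

  set.seed(substream_seed(cfg$seed, "panel"))
  pair_idx <- sample(nrow(ALLELE_PAIRS), m, replace = TRUE)
  af <- stats::runif(m, cfg$af_range[1], cfg$af_range[2])

  variants <- data.frame(
    snp_id = sprintf("rs%07d", seq_len(m)),
    chrom = rep(chrom, sizes),
    pos = unlist(lapply(seq_len(n_blocks), function(b) {
      starts[b] + (seq_len(sizes[b]) - 1) * 5000
    })),
    ref_allele = ALLELE_PAIRS[pair_idx, 1],
    alt_allele = ALLELE_PAIRS[pair_idx, 2],
    alt_freq = af,
    block_id = as.character(rep(seq_len(n_blocks), sizes)),
    stringsAsFactors = FALSE
  )

  r_by_size <- lapply(unique(sizes), function(s) ar1_matrix(s, cfg$ld_rho))
  names(r_by_size) <- as.character(unique(sizes))
  blocks <- lapply(sizes, function(s) r_by_size[[as.character(s)]])
  names(blocks) <- as.character(seq_len(n_blocks))

  ld_by_size <- lapply(r_by_size, function(r) rowSums(r^2))
  ld_scores <- stats::setNames(
    unlist(lapply(sizes, function(s) ld_by_size[[as.character(s)]])),
    variants$snp_id)

  ref_panel(variants, blocks, ld_scores = ld_scores, validate = FALSE)
}

#' Configuration of the bivariate polygenic generative model
#'
#' Defaults emulate the osteoarthritis / major-depression study conditions:
#' the two traits' total sample sizes, polygenicities on the order of
#' 1-2 per thousand SNPs, an effect correlation and shared-causal fraction
#' implying a genome-wide genetic correlation of 0.30, no sample overlap and
#' no directional causal effect. Effects are on the standardized-genotype
#' scale, so `se = 1/sqrt(n)` and case-control sampling is absorbed into `n`.
#'
#' @param pi1,pi2 per-trait causal fractions (polygenicity).
#' @param pi12 shared-causal fraction, at most `min(pi1, pi2)`.
#' @param sigma_b1_sq,sigma_b2_sq causal effect-size variances
#'   (discoverability) on the standardized-genotype scale.
#' @param rho_beta effect correlation among shared causal variants.
#' @param n1,n2 per-trait sample sizes.
#' @param r0 cross-trait correlation of null Z scores induced by sample
#'   overlap, in `(-1, 1)`.
#' @param b_xy directional causal effect of trait 1 liability on trait 2
#'   (0 for the purely pleiotropic scenario).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pi1 = 1.1e-3, pi2 = 1.8e-3, pi12 = NULL,
                       sigma_b1_sq = 2e-5, sigma_b2_sq = 2e-5,
                       rho_beta = 0.8, n1 = 455221, n2 = 500199,
                       r0 = 0, b_xy = 0, seed = 1) {
  if (is.null(pi12)) pi12 <- min(0.30 * sqrt(pi1 * pi2) / max(rho_beta, 1e-12),
                                 pi1, pi2)
  if (pi1 < 0 || pi1 > 1 || pi2 < 0 || pi2 > 1) abort_config("pi must lie in [0,1]")
  if (pi12 < 0 || pi12 > min(pi1, pi2) + 1e-12) {
    abort_config("pi12 must lie in [0, min(pi1, pi2)]")
  }
  if (abs(rho_beta) > 1) abort_config("rho_beta must lie in [-1, 1]")
  if (abs(r0) >= 1) abort_config("r0 must lie in (-1, 1)")
  if (sigma_b1_sq < 0 || sigma_b2_sq < 0) abort_config("sigma_b_sq must be >= 0")
  structure(list(pi1 = pi1, pi2 = pi2, pi12 = pi12,
                 sigma_b1_sq = sigma_b1_sq, sigma_b2_sq = sigma_b2_sq,
                 rho_beta = rho_beta, n1 = n1, n2 = n2, r0 = r0,
                 b_xy = b_xy, seed = as.integer(seed)),
            class = "sim_config")
}

#' Study-conditions configuration scaled to a given panel
#'
#' Computes the discoverabilities that give the requested SNP heritabilities
#' at the panel's SNP count (`sigma_b_sq = h2 / (M * pi)`), keeping all other
#' [sim_config()] defaults.
#'
#' @param panel a [ref_panel].
#' @param h2_1,h2_2 target SNP heritabilities (defaults 0.094 and 0.085).
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_study <- function(panel, h2_1 = 0.094, h2_2 = 0.085, ...) {
  m <- nrow(panel$variants)
  args <- list(...)
  pi1 <- args$pi1 %||% 1.1e-3
  pi2 <- args$pi2 %||% 1.8e-3
  args$pi1 <- pi1
  args$pi2 <- pi2
  args$sigma_b1_sq <- h2_1 / (m * pi1)
  args$sigma_b2_sq <- h2_2 / (m * pi2)
  do.call(sim_config, args)
}

# Closed-form per-SNP moments of the joint causal effects.
effect_moments <- function(cfg) {
  s1 <- cfg$sigma_b1_sq
  s2 <- cfg$sigma_b2_sq
  cross <- cfg$pi12 * cfg$rho_beta * sqrt(s1 * s2)
  var1 <- cfg$pi1 * s1
  var2 <- cfg$b_xy^2 * var1 + cfg$pi2 * s2 + 2 * cfg$b_xy * cross
  cov12 <- cfg$b_xy * var1 + cross
  list(var1 = var1, var2 = var2, cov12 = cov12)
}

#' Closed-form truth record for a simulation configuration
#'
#' Returns the implied SNP heritabilities, genetic correlation and expected
#' causal counts without drawing any data. With `b_xy = 0` the genetic
#' correlation reduces to `pi12 * rho_beta / sqrt(pi1 * pi2)`.
#'
#' @param cfg a [sim_config].
#' @param panel a [ref_panel] (supplies the SNP count M).
#' @return A list of class `truth_record`.
#' @export
truth_summary <- function(cfg, panel) {
  m <- nrow(panel$variants)
  mo <- effect_moments(cfg)
  h2_1 <- m * mo$var1
  h2_2 <- m * mo$var2
  rg <- if (mo$var1 > 0 && mo$var2 > 0) mo$cov12 / sqrt(mo$var1 * mo$var2) else 0
  p_causal2 <- if (cfg$b_xy != 0) cfg$pi1 + cfg$pi2 - cfg$pi12 else cfg$pi2
  structure(list(
    h2_1 = h2_1, h2_2 = h2_2, rg_true = rg, r0 = cfg$r0, b_xy = cfg$b_xy,
    causal_ids_1 = NULL, causal_ids_2 = NULL,
    n_causal_1 = round(m * cfg$pi1), n_causal_2 = round(m * p_causal2)
  ), class = "truth_record")
}

#' Simulate a pair of GWAS summary-statistics sets
#'
#' Per SNP, causal status is drawn from the four-cell
#' \{neither, trait-1 only, trait-2 only, both\} distribution defined by
#' `(pi1, pi2, pi12)`; shared-causal effects are bivariate normal with
#' correlation `rho_beta`, trait-specific effects independent normal. When
#' `b_xy != 0` the trait-2 joint effects become
#' `gamma2 = b_xy * gamma1 + gamma2_specific`. Marginal effects are the
#' within-block LD convolution `R gamma`; Z scores are
#' `z_i = sqrt(n_i) * (R gamma_i) + eps` with block-correlated noise whose
#' cross-trait correlation is `r0`. Finally `beta = z / sqrt(n)`,
#' `se = 1 / sqrt(n)`, and p-values are two-sided normal tails. Output is
#' already oriented to the panel (effect allele = panel alt allele).
#'
#' @param cfg a [sim_config].
#' @param panel a [ref_panel] built by [make_reference_panel()] (its blocks
#'   are AR(1) and laid out contiguously, which the batched sampler exploits).
#' @return A list of class `simulated_pair` with elements `ss1`, `ss2`
#'   ([sumstats]), `panel`, and `truth` (a `truth_record` carrying the
#'   realized causal ids and counts). Deterministic given `cfg$seed`.
#' @export
simulate_pair <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "ref_panel"))
  v <- panel$variants
  m <- nrow(v)
  mo <- effect_moments(cfg)
  if (m * mo$var1 > 1 || m * mo$var2 > 1) {
    abort_config(sprintf(
      "implied heritability exceeds 1 (h2_1=%.3f, h2_2=%.3f); reduce pi or sigma_b_sq",
      m * mo$var1, m * mo$var2))
  }

  # causal assignment
  set.seed(substream_seed(cfg$seed, "causal"))
  probs <- c(none = 1 - cfg$pi1 - cfg$pi2 + cfg$pi12,
             only1 = cfg$pi1 - cfg$pi12,
             only2 = cfg$pi2 - cfg$pi12,
             both = cfg$pi12)
  cat4 <- sample.int(4L, m, replace = TRUE, prob = pmax(probs, 0))

  # joint (causal) effects
  set.seed(substream_seed(cfg$seed, "effects"))
  g1 <- numeric(m)
  g2s <- numeric(m)
  s1 <- sqrt(cfg$sigma_b1_sq)
  s2 <- sqrt(cfg$sigma_b2_sq)
  i_both <- which(cat4 == 4L)
  if (length(i_both)) {
    u <- stats::rnorm(length(i_both))
    vv <- stats::rnorm(length(i_both))
    g1[i_both] <- s1 * u
    g2s[i_both] <- s2 * (cfg$rho_beta * u + sqrt(1 - cfg$rho_beta^2) * vv)
  }
  i1 <- which(cat4 == 2L)
  if (length(i1)) g1[i1] <- stats::rnorm(length(i1), sd = s1)
  i2 <- which(cat4 == 3L)
  if (length(i2)) g2s[i2] <- stats::rnorm(length(i2), sd = s2)
  g2 <- cfg$b_xy * g1 + g2s

  # block-local LD convolution and correlated noise, batched by block size
  set.seed(substream_seed(cfg$seed, "noise"))
  sizes <- as.integer(table(factor(v$block_id, levels = unique(v$block_id))))
  z1 <- numeric(m)
  z2 <- numeric(m)
  offsets <- cumsum(c(0L, sizes))
  r0c <- sqrt(1 - cfg$r0^2)
  for (s in unique(sizes)) {
    bsel <- which(sizes == s)
    idx <- unlist(lapply(bsel, function(b) offsets[b] + seq_len(s)))
    nb <- length(bsel)
    blk <- panel$blocks[[v$block_id[offsets[bsel[1]] + 1L]]]
    lchol <- if (s == 1) matrix(1, 1, 1) else t(chol(blk))
    gm1 <- matrix(g1[idx], nrow = s)
    gm2 <- matrix(g2[idx], nrow = s)
    u1 <- matrix(stats::rnorm(s * nb), nrow = s)
    u2 <- matrix(stats::rnorm(s * nb), nrow = s)
    e1 <- lchol %*% u1
    e2 <- lchol %*% (cfg$r0 * u1 + r0c * u2)
    z1[idx] <- sqrt(cfg$n1) * (blk %*% gm1) + e1
    z2[idx] <- sqrt(cfg$n2) * (blk %*% gm2) + e2
  }

  mk_ss <- function(z, n, label) {
    se <- 1 / sqrt(n)
    sumstats(data.frame(
      snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
      effect_allele = v$alt_allele, other_allele = v$ref_allele,
      eaf = v$alt_freq, beta = z * se, se = se, pval = p_from_z(z),
      z = z, n = n, stringsAsFactors = FALSE
    ), trait_label = label, provenance = "simulated")
  }

  truth <- truth_summary(cfg, panel)
  truth$causal_ids_1 <- v$snp_id[g1 != 0]
  truth$causal_ids_2 <- v$snp_id[g2 != 0]
  truth$n_causal_1 <- length(truth$causal_ids_1)
  truth$n_causal_2 <- length(truth$causal_ids_2)

  structure(list(ss1 = mk_ss(z1, cfg$n1, "trait1"),
                 ss2 = mk_ss(z2, cfg$n2, "trait2"),
                 panel = panel, truth = truth),
            class = "simulated_pair")
}

#' Toy gene annotation derived from a panel's LD blocks
#'
#' Creates one gene per LD block spanning that block's variants, for
#' end-to-end tests of SNP-to-gene assignment and gene-based association.
#'
#' @param panel a [ref_panel].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based closed intervals).
#' @export
make_gene_annotation <- function(panel) {
  v <- panel$variants
  sp <- split(seq_len(nrow(v)), v$block_id)
  ord <- order(as.integer(names(sp)))
  sp <- sp[ord]
  data.frame(
    gene_id = paste0("GENE", names(sp)),
    chrom = vapply(sp, function(i) v$chrom[i[1]], integer(1)),
    start = vapply(sp, function(i) min(v$pos[i]), numeric(1)),
    end = vapply(sp, function(i) max(v$pos[i]), numeric(1)),
    strand = "+",
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Random gene sets over a gene universe
#'
#' @param gene_ids character vector of gene ids.
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @param seed integer seed.
#' @return Named list of character vectors (class `gene_sets`).
#' @export
make_gene_sets <- function(gene_ids, n_sets = 10, set_size = 10, seed = 1) {
  set.seed(substream_seed(seed, "gene_sets"))
  out <- lapply(seq_len(n_sets), function(i) {
    sample(gene_ids, min(set_size, length(gene_ids)))
  })
  names(out) <- sprintf("SET%04d", seq_len(n_sets))
  structure(out, class = "gene_sets")
}

#' Write a simulated pair to disk
#'
#' Writes the two sumstats TSVs, the panel directory, and the truth record as
#' a flat `key=value` text file.
#'
#' @param pair a `simulated_pair`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(pair$ss1, file.path(dir, "trait1.sumstats.tsv"))
  write_sumstats(pair$ss2, file.path(dir, "trait2.sumstats.tsv"))
  write_ref_panel(pair$panel, file.path(dir, "panel"))
  tr <- pair$truth
  lines <- c(
    sprintf("h2_1=%.10g", tr$h2_1), sprintf("h2_2=%.10g", tr$h2_2),
    sprintf("rg_true=%.10g", tr$rg_true), sprintf("r0=%.10g", tr$r0),
    sprintf("b_xy=%.10g", tr$b_xy),
    sprintf("n_causal_1=%d", tr$n_causal_1),
    sprintf("n_causal_2=%d", tr$n_causal_2)
  )
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
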