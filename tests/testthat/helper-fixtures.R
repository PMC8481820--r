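# Shared builders for unit and acceptance tests. Everything is generated in
# code; no binary fixtures.

# A one-variant panel with chosen alleles, for orientation truth tables.
one_snp_panel <- function(ref = "A", alt = "G", af = 0.3) {
  ref_panel(
    data.frame(snp_id = "rs1", chrom = 1L, pos = 100L,
               ref_allele = ref, alt_allele = alt, alt_freq = af,
               block_id = "1", stringsAsFactors = FALSE),
    blocks = list("1" = matrix(1, 1, 1))
  )
}

# A small hand-specified panel (no LD between listed variants).
flat_panel <- function(variants) {
  n <- nrow(variants)
  variants$block_id <- as.character(seq_len(n))
  blocks <- stats::setNames(replicate(n, matrix(1, 1, 1), simplify = FALSE),
                            variants$block_id)
  ref_panel(variants, blocks)
}

# Minimal sumstats from a compact spec; beta defaults keep z = beta / se.
mk_ss <- function(snp_id, ea, oa, beta, se = 0.02, eaf = 0.25,
                  chrom = 1L, pos = 100L, n = 1e5, trait = "toy") {
  k <- length(snp_id)
  to_zscores(sumstats(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, k), pos = rep_len(pos, k),
    effect_allele = ea, other_allele = oa,
    eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
    n = rep_len(n, k), stringsAsFactors = FALSE
  ), trait_label = trait))
}

# Extend a one-variant panel with a well-behaved companion variant rs2 so a
# single filtered SNP is itemized instead of emptying the output.
pal_panel2 <- function(panel) {
  v <- panel$variants
  v2 <- rbind(v, data.frame(snp_id = "rs2", chrom = 1L, pos = 200L,
                            ref_allele = "A", alt_allele = "G", alt_freq = 0.3,
                            block_id = "2", stringsAsFactors = FALSE))
  ref_panel(v2, c(panel$blocks, list("2" = matrix(1, 1, 1))))
}

# Sumstats record matching pal_panel2's companion variant.
keeper <- function(panel) {
  mk_ss("rs2", "G", "A", beta = 0.1, eaf = 0.3, pos = 200L)
}

# Concatenate the records of two sumstats objects (second may be NULL).
rbind_ss <- function(a, b) {
  if (!is.null(b)) a$records <- rbind(a$records, b$records)
  a
}

default_column_map_test <- function() {
  c(snp = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}

# Sign-test p-value via the package surface: k of n index SNPs concordant.
sign_test_p <- function(k, n) {
  ids <- sprintf("rs%d", seq_len(n))
  ssb <- mk_ss(ids, "G", "A", beta = c(rep(1, k), rep(-1, n - k)),
               pos = seq_len(n) * 100)
  sign_concordance(data.frame(snp_id = ids, sign = 1), ssb)$pval
}

# Independent brute-force clumping oracle: a direct, unoptimized rendering of
# the locus-definition rules, used to cross-check clump_loci on small inputs.
brute_clump <- function(sig, r2_of, params) {
  # sig: data.frame snp_id, chrom, pos, p; r2_of(i, j) on row indices
  ord <- order(sig$p, sig$chrom, sig$pos, sig$snp_id)
  sig <- sig[ord, , drop = FALSE]
  n <- nrow(sig)
  r2m <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    r2_of(sig$snp_id[i], sig$snp_id[j])
  }))
  clump <- rep(NA_integer_, n)
  lead_rows <- integer(0)
  nc <- 0
  for (i in seq_len(n)) {
    if (!is.na(clump[i])) next
    hit <- lead_rows[r2m[i, lead_rows] >= params$r2_lead]
    if (length(hit)) {
      clump[i] <- clump[hit[1]]
      next
    }
    nc <- nc + 1
    clump[i] <- nc
    lead_rows <- c(lead_rows, i)
    clump[is.na(clump) & r2m[i, ] >= params$r2_member] <- nc
  }
  spans <- lapply(seq_len(nc), function(k) {
    rows <- which(clump == k)
    list(chrom = sig$chrom[rows[1]], start = min(sig$pos[rows]),
         end = max(sig$pos[rows]), members = sort(sig$snp_id[rows]),
         leads = sig$snp_id[intersect(lead_rows, rows)])
  })
  spans <- spans[order(vapply(spans, `[[`, numeric(1), "chrom"),
                       vapply(spans, `[[`, numeric(1), "start"))]
  out <- list()
  win <- params$merge_window_kb * 1000
  for (sp in spans) {
    last <- if (length(out)) out[[length(out)]] else NULL
    if (!is.null(last) && last$chrom == sp$chrom && sp$start - last$end <= win) {
      last$end <- max(last$end, sp$end)
      last$members <- sort(c(last$members, sp$members))
      last$leads <- c(last$leads, sp$leads)
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1]] <- sp
    }
  }
  out
}

# Study-condition panels for recovery runs (built once per test file load).
recovery_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference_panel(
        panel_config(m_snps = 50000, block_size = 50, ld_rho = 0.9, seed = 42))
    }
    cache
  }
})

weak_ld_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference_panel(
        panel_config(m_snps = 50000, block_size = 50, ld_rho = 0.2, seed = 42))
    }
    cache
  }
})
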