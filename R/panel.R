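#' Reference panel container
#'
#' Holds the shared genomic scaffold every stage aligns to: a variant table
#' (identity, position, ref/alt alleles, alternate-allele frequency, LD-block
#' membership), one LD correlation matrix per block (rows/columns in position
#' order), and per-SNP LD scores `l_j = sum_k r^2_jk` over the SNP's block.
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `alt_freq`, `block_id`.
#' @param blocks named list of square LD correlation matrices, one per block
#'   id; each symmetric with unit diagonal and positive semi-definite.
#' @param ld_scores optional named numeric vector (snp_id -> LD score);
#'   computed from the blocks when omitted.
#' @param validate run structural checks on the block matrices (default TRUE;
#'   turn off for very large programmatically built panels).
#' @return An object of class `ref_panel`.
#' @export
ref_panel <- function(variants, blocks, ld_scores = NULL, validate = TRUE) {
  need <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele",
            "alt_freq", "block_id")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols)) {
    abort_config(paste0("panel variants lack column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(variants$snp_id)) {
    abort_config("panel variant snp_id values must be unique")
  }
  variants$block_id <- as.character(variants$block_id)
  sizes <- table(variants$block_id)
  for (b in names(sizes)) {
    if (is.null(blocks[[b]])) abort_config(paste0("missing LD matrix for block ", b))
    if (nrow(blocks[[b]]) != sizes[[b]]) {
      abort_config(paste0("block ", b, " matrix size disagrees with variant table"))
    }
  }
  if (validate) {
    for (b in names(blocks)) {
      r <- blocks[[b]]
      if (max(abs(r - t(r))) > 1e-8) abort_config(paste0("block ", b, " not symmetric"))
      if (max(abs(diag(r) - 1)) > 1e-8) abort_config(paste0("block ", b, " diagonal not 1"))
      if (nrow(r) > 1 && min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
        abort_config(paste0("block ", b, " not positive semi-definite"))
      }
    }
  }
  if (is.null(ld_scores)) {
    ld_scores <- numeric(nrow(variants))
    names(ld_scores) <- variants$snp_id
    for (b in names(blocks)) {
      ids <- variants$snp_id[variants$block_id == b]
      ld_scores[ids] <- rowSums(blocks[[b]]^2)
    }
  }
  structure(list(variants = variants, blocks = blocks, ld_scores = ld_scores),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d variants in %d LD blocks, mean LD score %.3f\n",
              nrow(x$variants), length(x$blocks), mean(x$ld_scores)))
  invisible(x)
}

#' Squared LD between two panel variants
#'
#' Cross-block LD is exactly zero by construction.
#'
#' @param panel a [ref_panel].
#' @param id1,id2 variant ids.
#' @return r-squared between the two variants.
#' @export
panel_r2 <- function(panel, id1, id2) {
  v <- panel$variants
  i <- match(c(id1, id2), v$snp_id)
  if (anyNA(i)) abort_input("variant id not in panel")
  if (v$block_id[i[1]] != v$block_id[i[2]]) return(0)
  b <- v$block_id[i[1]]
  members <- which(v$block_id == b)
  r <- panel$blocks[[b]]
  r[match(i[1], members), match(i[2], members)]^2
}

#' Write a reference panel to a directory
#'
#' Dialect: `variants.tsv` (snp_id, chrom, pos, ref, alt, af, block_id),
#' `ld_scores.tsv` (snp_id, l2), and one whitespace-delimited square matrix
#' file `block_<id>.ld` per block (row order = position order).
#'
#' @param panel a [ref_panel].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ref_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- panel$variants
  utils::write.table(
    data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
               ref = v$ref_allele, alt = v$alt_allele, af = v$alt_freq,
               block_id = v$block_id),
    file.path(dir, "variants.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(snp_id = names(panel$ld_scores), l2 = as.numeric(panel$ld_scores)),
    file.path(dir, "ld_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in names(panel$blocks)) {
    utils::write.table(panel$blocks[[b]], file.path(dir, paste0("block_", b, ".ld")),
                       sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a reference panel from a directory written by [write_ref_panel()]
#'
#' @param dir panel directory.
#' @param validate run structural checks (default TRUE).
#' @return A [ref_panel].
#' @export
read_ref_panel <- function(dir, validate = TRUE) {
  vpath <- file.path(dir, "variants.tsv")
  if (!file.exists(vpath)) abort_input(paste0("panel variants file not found: ", vpath))
  v <- utils::read.table(vpath, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  variants <- data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                         ref_allele = v$ref, alt_allele = v$alt,
                         alt_freq = v$af, block_id = as.character(v$block_id),
                         stringsAsFactors = FALSE)
  blocks <- list()
  for (b in unique(variants$block_id)) {
    bpath <- file.path(dir, paste0("block_", b, ".ld"))
    if (!file.exists(bpath)) abort_input(paste0("missing LD matrix file: ", bpath))
    blocks[[b]] <- as.matrix(utils::read.table(bpath, header = FALSE))
    dimnames(blocks[[b]]) <- NULL
  }
  lpath <- file.path(dir, "ld_scores.tsv")
  ld <- NULL
  if (file.exists(lpath)) {
    lt <- utils::read.table(lpath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ld <- stats::setNames(lt$l2, lt$snp_id)
  }
  ref_panel(variants, blocks, ld_scores = ld, validate = validate)
}
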