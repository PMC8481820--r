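#' GWAS summary-statistics container
#'
#' A `sumstats` object holds one trait's per-SNP association records on the
#' log-odds / linear effect scale: columns `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `z`, `n`,
#' `n_cases`, `n_controls`. Optional columns may be `NA`.
#'
#' @param records data.frame with at least `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`.
#' @param trait_label short trait name used in reports.
#' @param build genome build tag (metadata only; no liftover is performed).
#' @param provenance free-text description of the source.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(records, trait_label, build = "GRCh37", provenance = "") {
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort_config(paste0("sumstats records lack column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  optional <- c("eaf", "pval", "z", "n", "n_cases", "n_controls")
  for (col in optional) if (is.null(records[[col]])) records[[col]] <- NA_real_
  records <- records[, c(required[1:5], "eaf", "beta", "se", "pval", "z",
                         "n", "n_cases", "n_controls")]
  records$chrom <- as.integer(records$chrom)
  records$pos <- as.numeric(records$pos)
  if (anyDuplicated(records$snp_id)) {
    warning("duplicate snp_id values present; harmonize() will resolve them")
  }
  structure(
    list(trait_label = trait_label, build = build, provenance = provenance,
         records = records),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait=%s  build=%s  n_snps=%d\n",
              x$trait_label, x$build, nrow(x$records)))
  invisible(x)
}

#' QC thresholds for harmonization
#'
#' @param maf_min minimum minor-allele frequency; variants rarer than this are
#'   removed (default 0.01).
#' @param palindrome_eaf_halfwidth A/T and C/G variants whose effect-allele
#'   frequency lies within this half-width of 0.5 are strand-unresolvable and
#'   removed (default 0.15).
#' @param af_discordance_max maximum tolerated absolute difference between the
#'   study effect-allele frequency (after orientation) and the panel
#'   alternate-allele frequency (default 0.15).
#' @param autosomes_only drop variants outside chromosomes 1-22 (default TRUE).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.01, palindrome_eaf_halfwidth = 0.15,
                      af_discordance_max = 0.15, autosomes_only = TRUE) {
  for (v in c(maf_min, palindrome_eaf_halfwidth, af_discordance_max)) {
    if (!is.numeric(v) || v <= 0 || v > 0.5) {
      abort_config("qc thresholds must lie in (0, 0.5]")
    }
  }
  structure(list(maf_min = maf_min,
                 palindrome_eaf_halfwidth = palindrome_eaf_halfwidth,
                 af_discordance_max = af_discordance_max,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "qc_params")
}

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file (gzip transparently supported) with a header
#' row, renames columns through `column_map`, converts odds ratios to log-odds,
#' and derives any of beta/se/z/p that the file lacks. Effect columns are
#' detected by name only, never by value magnitude.
#'
#' @param path file path (plain or `.gz`).
#' @param column_map named character vector mapping canonical field names to
#'   the file's header names. Recognised canonical names: `snp`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `or`, `se`, `z`,
#'   `pval`, `n`, `n_cases`, `n_controls`. At minimum `snp`, `chrom`, `pos`,
#'   both allele columns, and one of (`beta`,`se`), (`or`,`se`), (`z`,`n`)
#'   must resolve.
#' @param trait_label short trait name.
#' @param n_default per-file constant sample size used when the file carries
#'   no `n` column (required downstream by the LD-score regressions).
#' @param sep field separator (default tab).
#' @return A [sumstats] object. Rows whose mandatory fields fail to parse are
#'   dropped; the count is available as `attr(x, "n_dropped")`.
#' @export
read_sumstats <- function(path, column_map, trait_label, n_default = NULL,
                          sep = "\t") {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- tryCatch(
    utils::read.table(con, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = ""),
    error = function(e) abort_input(paste0("empty or unreadable file: ", path))
  )
  if (nrow(df) == 0) abort_input(paste0("empty file: ", path))

  column_map <- unlist(column_map)
  absent <- column_map[!column_map %in% names(df)]
  if (length(absent)) {
    abort_config(paste0("column_map references header(s) absent from file: ",
                        paste(absent, collapse = ", ")))
  }
  has <- function(f) f %in% names(column_map)
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele")
  lacking <- need[!vapply(need, has, logical(1))]
  if (length(lacking)) {
    abort_config(paste0("column_map must resolve mandatory column(s): ",
                        paste(lacking, collapse = ", ")))
  }
  mode <- if (has("beta") && has("se")) {
    "beta_se"
  } else if (has("or") && has("se")) {
    "or_se"
  } else if (has("z") && has("n")) {
    "z_n"
  } else {
    abort_config(
      "column_map must resolve (beta,se), (or,se) or (z,n) effect columns")
  }
  col <- function(f) df[[column_map[[f]]]]
  num <- function(f) {
    if (!has(f)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(col(f)))
  }

  chrom <- suppressWarnings(as.integer(gsub("^chr", "", as.character(col("chrom")))))
  rec <- data.frame(
    snp_id = as.character(col("snp")),
    chrom = chrom,
    pos = num("pos"),
    effect_allele = toupper(as.character(col("effect_allele"))),
    other_allele = toupper(as.character(col("other_allele"))),
    eaf = num("eaf"),
    se = num("se"),
    pval = num("pval"),
    n = num("n"),
    n_cases = num("n_cases"),
    n_controls = num("n_controls"),
    stringsAsFactors = FALSE
  )
  rec$beta <- switch(mode,
    beta_se = num("beta"),
    or_se = log(num("or")),       # odds ratios enter on the natural-log scale
    z_n = num("z") / sqrt(num("n"))
  )
  if (mode == "z_n") rec$se <- 1 / sqrt(rec$n)
  rec$z <- num("z")

  if (all(is.na(rec$n))) {
    if (!is.null(n_default)) {
      rec$n <- n_default
    } else if (!all(is.na(rec$n_cases)) && !all(is.na(rec$n_controls))) {
      rec$n <- rec$n_cases + rec$n_controls
    }
  }

  ok <- !is.na(rec$snp_id) & !is.na(rec$chrom) & !is.na(rec$pos) &
    !is.na(rec$beta) & !is.na(rec$se) & nzchar(rec$effect_allele) &
    nzchar(rec$other_allele)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("read_sumstats: dropped %d row(s) with unparseable mandatory fields",
                    n_dropped))
  }
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) == 0) abort_input("no parseable rows in file")
  out <- sumstats(rec, trait_label = trait_label,
                  provenance = paste0("read from ", path))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Standardize a sumstats object to Z scores
#'
#' Sets `z = beta / se` on every record and fills missing p-values with the
#' two-sided normal tail of `|z|`. Records with non-positive standard errors
#' are invalid and dropped (counted in `attr(x, "n_dropped_se")`).
#'
#' @param ss a [sumstats] object with `beta` and `se` on every record.
#' @return The standardized [sumstats] object.
#' @export
to_zscores <- function(ss) {
  rec <- ss$records
  bad <- !is.finite(rec$se) | rec$se <= 0
  if (any(bad)) {
    message(sprintf("to_zscores: dropped %d record(s) with se <= 0", sum(bad)))
    rec <- rec[!bad, , drop = FALSE]
  }
  rec$z <- rec$beta / rec$se
  fill <- is.na(rec$pval)
  rec$pval[fill] <- p_from_z(rec$z[fill])
  ss$records <- rec
  attr(ss, "n_dropped_se") <- sum(bad)
  ss
}

#' Harmonize summary statistics against a reference panel
#'
#' Applies the QC filters (autosomes, rsID, biallelic single-base alleles,
#' minor-allele frequency, panel presence, allele compatibility, palindrome
#' ambiguity, allele-frequency discordance, duplicates) and re-orients every
#' surviving record so that its effect allele equals the panel's alternate
#' allele, flipping the signs of `beta`/`z` and complementing `eaf` where
#' needed. Palindromic (A/T, C/G) variants far enough from frequency 0.5 are
#' oriented by frequency matching against the panel.
#'
#' @param ss a standardized [sumstats] object (see [to_zscores()]).
#' @param panel a [ref_panel] object.
#' @param qc a [qc_params] object.
#' @return list with elements `sumstats` (the harmonized object) and `report`
#'   (class `harmonization_report`: `n_input`, `n_output`, per-filter
#'   `removals`, `n_sign_flipped`).
#' @export
harmonize <- function(ss, panel, qc = qc_params()) {
  rec <- ss$records
  n_input <- nrow(rec)
  if (n_input == 0) abort_input("no records to harmonize")
  reason <- rep(NA_character_, n_input)
  mark <- function(cond, label) {
    idx <- which(cond & is.na(reason))
    reason[idx] <<- label
    reason
  }

  if (qc$autosomes_only) {
    reason <- mark(!(rec$chrom %in% 1:22), "non_autosomal")
  }
  reason <- mark(!grepl("^rs[0-9]+$", rec$snp_id), "missing_rsid")
  biallelic <- rec$effect_allele %in% BASES & rec$other_allele %in% BASES &
    rec$effect_allele != rec$other_allele
  reason <- mark(!biallelic, "non_biallelic")
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  reason <- mark(!is.na(maf) & maf < qc$maf_min, "rare")

  # duplicate rsIDs: the record with the smallest se wins
  alive <- which(is.na(reason))
  alive <- alive[order(rec$se[alive], alive)]
  dup <- alive[duplicated(rec$snp_id[alive])]
  reason[dup] <- "duplicate"

  pv <- panel$variants
  m <- match(rec$snp_id, pv$snp_id)
  reason <- mark(is.na(m), "absent_from_panel")

  ref <- pv$ref_allele[m]
  alt <- pv$alt_allele[m]
  af <- pv$alt_freq[m]
  ea <- rec$effect_allele
  oa <- rec$other_allele
  cea <- complement_allele(ea)
  coa <- complement_allele(oa)

  pal <- is_palindromic(ea, oa)
  direct_keep <- ea == alt & oa == ref
  direct_flip <- ea == ref & oa == alt
  strand_keep <- cea == alt & coa == ref
  strand_flip <- cea == ref & coa == alt
  compatible <- direct_keep | direct_flip | strand_keep | strand_flip
  reason <- mark(!is.na(m) & !compatible, "incompatible_alleles")

  ambiguous <- pal & (is.na(rec$eaf) |
                        abs(rec$eaf - 0.5) < qc$palindrome_eaf_halfwidth)
  reason <- mark(ambiguous, "palindromic_ambiguous")

  # orientation: non-palindromes by allele letters, palindromes by frequency
  flip <- ifelse(pal,
                 abs(rec$eaf - af) > abs((1 - rec$eaf) - af),
                 direct_flip | strand_flip)

  eaf_oriented <- ifelse(flip, 1 - rec$eaf, rec$eaf)
  discordant <- !is.na(eaf_oriented) & !is.na(af) &
    abs(eaf_oriented - af) > qc$af_discordance_max
  reason <- mark(discordant, "af_discordant")

  keep <- is.na(reason)
  if (!any(keep)) {
    pleio_error(paste0(
      "harmonize removed every SNP; review QC thresholds ",
      "(maf_min, palindrome_eaf_halfwidth, af_discordance_max)"),
      "pleioscan_pipeline_error")
  }

  out <- rec[keep, , drop = FALSE]
  fl <- flip[keep]
  fl[is.na(fl)] <- FALSE
  out$beta <- ifelse(fl, -out$beta, out$beta)
  out$z <- ifelse(fl, -out$z, out$z)
  out$eaf <- ifelse(fl, 1 - out$eaf, out$eaf)
  out$effect_allele <- alt[keep]
  out$other_allele <- ref[keep]
  mk <- m[keep]
  out$chrom <- pv$chrom[mk]
  out$pos <- pv$pos[mk]

  labels <- c("rare", "non_biallelic", "missing_rsid", "absent_from_panel",
              "incompatible_alleles", "palindromic_ambiguous", "af_discordant",
              "duplicate", "non_autosomal")
  removals <- stats::setNames(integer(length(labels)), labels)
  tab <- table(reason[!is.na(reason)])
  removals[names(tab)] <- as.integer(tab)

  report <- structure(
    list(n_input = n_input, n_output = nrow(out), removals = removals,
         n_sign_flipped = sum(fl)),
    class = "harmonization_report"
  )
  stopifnot(report$n_input == report$n_output + sum(report$removals))
  ss$records <- out
  list(sumstats = ss, report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat(sprintf("<harmonization_report> %d in -> %d out, %d sign-flipped\n",
              x$n_input, x$n_output, x$n_sign_flipped))
  nz <- x$removals[x$removals > 0]
  for (k in names(nz)) cat(sprintf("  removed %-22s %d\n", k, nz[[k]]))
  invisible(x)
}

#' Write summary statistics as TSV
#'
#' Canonical column order: snp_id, chrom, pos, effect_allele, other_allele,
#' eaf, beta, se, z, pval, n, n_cases, n_controls.
#'
#' @param ss a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "z", "pval", "n", "n_cases", "n_controls")
  utils::write.table(ss$records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
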