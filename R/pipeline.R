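#' Read a pipeline configuration file
#'
#' YAML with sections: `inputs` (paths `sumstats1`, `sumstats2`, `panel`,
#' `annotation`, `gene_sets`, plus `column_map1`/`column_map2`,
#' `trait_label1`/`trait_label2`), optional parameter blocks `qc`, `mr`,
#' `clump`, `thresholds`, and top-level `seed` and `out_dir`. All referenced
#' paths are validated before anything is written.
#'
#' @param path YAML file path.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  problems <- character(0)
  inp <- cfg$inputs
  if (is.null(inp)) problems <- c(problems, "inputs: section missing")
  for (f in c("sumstats1", "sumstats2", "panel")) {
    p <- inp[[f]]
    if (is.null(p)) {
      problems <- c(problems, sprintf("inputs.%s: missing", f))
    } else if (!file.exists(p)) {
      problems <- c(problems, sprintf("inputs.%s: path does not exist: %s", f, p))
    }
  }
  for (f in c("annotation", "gene_sets")) {
    p <- inp[[f]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("inputs.%s: path does not exist: %s", f, p))
    }
  }
  if (length(problems)) {
    abort_config(paste0("config validation failed:\n  ",
                        paste(problems, collapse = "\n  ")))
  }
  cfg$seed <- cfg$seed %||% 1
  cfg$out_dir <- cfg$out_dir %||% "pleioscan_out"
  structure(cfg, class = "pipeline_config")
}

stage_result <- function(expr, report, name) {
  out <- tryCatch(expr, error = function(e) e)
  if (inherits(out, "error")) {
    report$stages[[name]] <- list(status = "failed",
                                  message = conditionMessage(out))
    message(sprintf("[%s] FAILED: %s", name, conditionMessage(out)))
    list(value = NULL, report = report)
  } else {
    report$stages[[name]] <- list(status = "ok")
    list(value = out, report = report)
  }
}

#' Run the full cross-trait pleiotropy pipeline
#'
#' Stages, in fixed order: read + standardize both summary-statistics sets,
#' harmonize to the panel, LDSC heritability for each trait, genetic
#' correlation, mixture (polygenicity) fit per trait, bidirectional sign
#' tests, overlap-corrected meta-analysis with genomic-inflation reporting
#' and locus clumping, bidirectional MR, then (when annotation / gene sets
#' are configured) gene-based association, the pleiotropy filter, and
#' gene-set enrichment. A stage failure is recorded and independent later
#' stages still run. Intermediate TSVs are written to `out_dir`. Identical
#' config + seed gives identical outputs.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or a list
#'   with the same structure; in-memory objects may be supplied directly via
#'   elements `objects$ss1`, `objects$ss2`, `objects$panel`.
#' @return A list of class `run_report`: per-stage status, key estimates, the
#'   echoed config and seed.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config") && is.null(config$objects)) {
    config <- validate_pipeline_config(config)
  }
  out_dir <- config$out_dir %||% "pleioscan_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), estimates = list(),
                 seed = config$seed %||% 1,
                 version = as.character(utils::packageVersion("pleioscan")),
                 config = config[setdiff(names(config), "objects")])

  # --- load
  if (!is.null(config$objects)) {
    ss1 <- config$objects$ss1
    ss2 <- config$objects$ss2
    panel <- config$objects$panel
    report$stages$load <- list(status = "ok")
  } else {
    inp <- config$inputs
    panel <- read_ref_panel(inp$panel, validate = FALSE)
    ss1 <- read_sumstats(inp$sumstats1, inp$column_map1 %||% default_column_map(),
                         inp$trait_label1 %||% "trait1",
                         n_default = inp$n1)
    ss2 <- read_sumstats(inp$sumstats2, inp$column_map2 %||% default_column_map(),
                         inp$trait_label2 %||% "trait2",
                         n_default = inp$n2)
    report$stages$load <- list(status = "ok")
  }

  qc <- do.call(qc_params, config$qc %||% list())
  mrp <- do.call(mr_params, config$mr %||% list())
  clp <- do.call(clump_params, config$clump %||% list())
  thr <- config$thresholds %||% list()
  gw_p <- thr$genome_wide_p %||% 5e-8
  per_trait_p <- thr$per_trait_gene_p %||% 1e-4

  # --- qc / harmonization
  h1 <- harmonize(to_zscores(ss1), panel, qc)
  h2 <- harmonize(to_zscores(ss2), panel, qc)
  ss1 <- h1$sumstats
  ss2 <- h2$sumstats
  report$stages$qc <- list(status = "ok")
  report$estimates$n_snps_1 <- h1$report$n_output
  report$estimates$n_snps_2 <- h2$report$n_output
  write_sumstats(ss1, file.path(out_dir, "trait1.harmonized.tsv"))
  write_sumstats(ss2, file.path(out_dir, "trait2.harmonized.tsv"))

  njk <- config$n_jackknife_blocks %||%
    max(10, min(200, floor(min(h1$report$n_output, h2$report$n_output) / 50)))

  # --- architecture
  sr <- stage_result({
    e1 <- ldsc_h2(ss1, panel, n_jackknife_blocks = njk)
    e2 <- ldsc_h2(ss2, panel, n_jackknife_blocks = njk)
    utils::write.table(
      data.frame(trait = c(ss1$trait_label, ss2$trait_label),
                 h2_obs = c(e1$h2_obs, e2$h2_obs),
                 h2_se = c(e1$h2_se, e2$h2_se),
                 intercept = c(e1$intercept, e2$intercept)),
      file.path(out_dir, "h2.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    list(e1 = e1, e2 = e2)
  }, report, "h2")
  report <- sr$report
  if (!is.null(sr$value)) {
    report$estimates$h2_1 <- sr$value$e1$h2_obs
    report$estimates$h2_2 <- sr$value$e2$h2_obs
  }

  sr <- stage_result({
    rg <- ldsc_rg(ss1, ss2, panel, n_jackknife_blocks = njk)
    utils::write.table(
      data.frame(rg = rg$rg, rg_se = rg$rg_se, pval = rg$pval,
                 gencov = rg$gencov, cross_intercept = rg$cross_intercept),
      file.path(out_dir, "rg.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    rg
  }, report, "rg")
  report <- sr$report
  if (!is.null(sr$value)) {
    report$estimates$rg <- sr$value$rg
    report$estimates$rg_se <- sr$value$rg_se
  }

  if (isTRUE(config$run_mixture %||% TRUE)) {
    sr <- stage_result({
      m1 <- mixer_em(ss1, panel)
      m2 <- mixer_em(ss2, panel)
      utils::write.table(
        data.frame(trait = c(ss1$trait_label, ss2$trait_label),
                   model = c(m1$model, m2$model),
                   pi_hat = c(m1$pi_hat, m2$pi_hat),
                   sigma_b_sq_hat = c(m1$sigma_b_sq_hat, m2$sigma_b_sq_hat),
                   n_causal_hat = c(m1$n_causal_hat, m2$n_causal_hat),
                   converged = c(m1$converged, m2$converged)),
        file.path(out_dir, "mixture.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(m1 = m1, m2 = m2)
    }, report, "mixture")
    report <- sr$report
    if (!is.null(sr$value)) {
      report$estimates$pi_1 <- sr$value$m1$pi_hat
      report$estimates$pi_2 <- sr$value$m2$pi_hat
    }
  }

  # --- sign tests (index SNPs: LD-independent genome-wide significant)
  sr <- stage_result({
    st <- list()
    for (dir_i in 1:2) {
      ea <- if (dir_i == 1) ss1 else ss2
      eb <- if (dir_i == 1) ss2 else ss1
      idx <- tryCatch(
        select_instruments(ea, eb, panel,
                           mr_params(instrument_p_threshold = gw_p,
                                     instrument_r2 = mrp$instrument_r2,
                                     min_instruments = 1)),
        pleioscan_error = function(e) NULL)
      st[[paste0(ea$trait_label, "->", eb$trait_label)]] <-
        if (!is.null(idx) && nrow(idx) > 0) {
          sign_concordance(data.frame(snp_id = idx$snp_id, sign = sign(idx$b_zx)), eb)
        }
    }
    st <- st[!vapply(st, is.null, logical(1))]
    if (length(st)) {
      utils::write.table(
        data.frame(direction = names(st),
                   n_index = vapply(st, `[[`, numeric(1), "n_index"),
                   n_concordant = vapply(st, `[[`, numeric(1), "n_concordant"),
                   pval = vapply(st, `[[`, numeric(1), "pval")),
        file.path(out_dir, "sign_tests.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    st
  }, report, "signtest")
  report <- sr$report
  if (!is.null(sr$value) && length(sr$value)) {
    report$estimates$sign_tests <- lapply(sr$value, function(s) {
      list(n_index = s$n_index, n_concordant = s$n_concordant, pval = s$pval)
    })
  }

  # --- meta-analysis
  meta <- NULL
  sr <- stage_result({
    shared <- intersect(ss1$records$snp_id, ss2$records$snp_id)
    r1 <- ss1$records[match(shared, ss1$records$snp_id), ]
    r2 <- ss2$records[match(shared, ss2$records$snp_id), ]
    ov <- estimate_overlap(r1$z, r2$z, truncation = thr$truncation %||% 1.0)
    w <- lin_sullivan_weights(ov)
    mz <- meta_z(rbind(r1$z, r2$z), w, ov,
                 variants = data.frame(snp_id = r1$snp_id, chrom = r1$chrom,
                                       pos = r1$pos))
    ncase <- config$n_cases_eff %||% round(sum(r1$n_cases[1], r2$n_cases[1],
                                               na.rm = TRUE))
    nctrl <- config$n_controls_eff %||% ncase
    infl <- if (!is.na(ncase) && ncase > 0) {
      genomic_inflation(mz$table$z_meta, ncase, nctrl)
    } else {
      list(lambda_gc = stats::median(mz$table$z_meta^2) / stats::qchisq(0.5, 1),
           lambda_1000 = NA_real_)
    }
    utils::write.table(mz$table, file.path(out_dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(overlap = ov, weights = w, meta = mz, inflation = infl)
  }, report, "meta")
  report <- sr$report
  if (!is.null(sr$value)) {
    meta <- sr$value$meta
    report$estimates$r_hat <- sr$value$overlap$r_hat
    report$estimates$lambda_gc <- sr$value$inflation$lambda_gc
    report$estimates$lambda_1000 <- sr$value$inflation$lambda_1000
  }

  if (!is.null(meta)) {
    sr <- stage_result({
      loci <- clump_loci(meta, panel, clp)
      utils::write.table(loci, file.path(out_dir, "loci.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      loci
    }, report, "loci")
    report <- sr$report
    if (!is.null(sr$value)) {
      report$estimates$n_loci <- nrow(sr$value)
      report$estimates$n_lead_snps <- sum(sr$value$n_leads)
    }
  }

  # --- Mendelian randomization
  sr <- stage_result({
    mr <- bidirectional_mr(ss1, ss2, panel, mrp)
    if (!is.null(mr$summary)) {
      utils::write.table(mr$summary, file.path(out_dir, "mr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    mr
  }, report, "mr")
  report <- sr$report
  if (!is.null(sr$value)) {
    for (d in c("forward", "reverse")) {
      r <- sr$value[[d]]
      if (inherits(r, "mr_result")) {
        report$estimates[[paste0("mr_", d)]] <-
          list(direction = r$direction, beta = r$beta_xy, se = r$se_xy,
               pval = r$pval)
      }
    }
  }

  # --- genes and gene sets
  annotation <- config$objects$annotation %||%
    (if (!is.null(config$inputs$annotation)) read_gene_annotation(config$inputs$annotation))
  gsets <- config$objects$gene_sets %||%
    (if (!is.null(config$inputs$gene_sets)) read_gmt(config$inputs$gene_sets))

  genes <- NULL
  if (!is.null(annotation) && !is.null(meta)) {
    sr <- stage_result({
      assignment <- assign_snps_to_genes(annotation, ss1,
                                         window_kb = thr$gene_window_kb %||% 20)
      zm <- stats::setNames(meta$table$z_meta, meta$table$snp_id)
      za <- stats::setNames(ss1$records$z, ss1$records$snp_id)
      zb <- stats::setNames(ss2$records$z, ss2$records$snp_id)
      g <- gene_association(assignment, panel, zm, za, zb)
      g$significant_meta <- g$pval_meta <= bonferroni_threshold(nrow(g))
      utils::write.table(g, file.path(out_dir, "genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      g
    }, report, "genes")
    report <- sr$report
    genes <- sr$value
    if (!is.null(genes)) {
      report$estimates$n_genes_tested <- nrow(genes)
      shared_genes <- pleiotropy_filter(genes, bonferroni_threshold(nrow(genes)),
                                        per_trait_p)
      report$estimates$n_shared_genes <- nrow(shared_genes)
      utils::write.table(shared_genes, file.path(out_dir, "shared_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(gsets) && !is.null(genes)) {
    sr <- stage_result({
      enr <- geneset_enrichment(genes, gsets)
      utils::write.table(enr, file.path(out_dir, "gene_sets.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      enr
    }, report, "genesets")
    report <- sr$report
    if (!is.null(sr$value)) report$estimates$n_sets_tested <- nrow(sr$value)
  }

  class(report) <- "run_report"
  report
}

default_column_map <- function() {
  c(snp = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> pleioscan", x$version, " seed =", x$seed, "\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %s%s\n", s, st$status,
                if (!is.null(st$message)) paste0(" (", st$message, ")") else ""))
  }
  est <- x$estimates
  flat <- est[vapply(est, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  for (k in names(flat)) cat(sprintf("  %-16s %.6g\n", k, flat[[k]]))
  invisible(x)
}
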