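default_pipeline_config <- function() {
  list(
    scenario = "E", n_genes = 10L, tissues = ad_tissues(),
    n_snps = 10L, maf_low = 0.05, maf_high = 0.5, ld_rho = 0.5,
    n_causal_eqtl = 2L, cis_h2 = 0.4, trait_h2_via_expression = 0.02,
    direct_snp_effect = 0.1,
    n_ref = 500L, n_gwas = 5000L,
    models = c("top1", "lasso"), n_folds = 5L, cv_floor = 0.01,
    ld_source = "gwas", ridge = 0, cis_window_bp = 5e5,
    method = "bh", alpha = 0.05, bonferroni_m = NA,
    seed = 1L, out = NULL
  )
}

#' Read a flat key-value pipeline configuration file
#'
#' Debian-control-style `key: value` text (one record); comma-separated
#' values become vectors, numeric strings become numbers.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "sumtwas_input_error")
  }
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  lapply(raw, function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
}

#' Run the full synthetic TWAS pipeline
#'
#' Simulate per-gene loci for each tissue under one causal scenario, train
#' cross-validated expression weights on the reference panels, impute the
#' expression-trait association from the GWAS cohort's summary z-scores with
#' LD adjustment, apply the per-tissue multiple-testing correction, and
#' (optionally) persist every stage output plus an audit log recording the
#' seed, alpha, correction denominator, LD ridge, cis-window and model
#' precedence. Reruns with the same config are bit-identical.
#'
#' @param config Named list overriding the defaults (see
#'   `sumtwas:::default_pipeline_config()`), or a path to a flat key-value
#'   config file ([read_pipeline_config()]). Keys include `scenario`,
#'   `n_genes`, `tissues`, cohort sizes, model list, `method`, `alpha`,
#'   `bonferroni_m`, `seed`, and `out` (output directory; `NULL` keeps
#'   results in memory).
#' @return List of class `twas_pipeline`: `assoc` (association table),
#'   `calls` (corrected calls), `genes` (gene-level report), `weights`
#'   (list of weight sets), `truth` (per gene/tissue scenario truth),
#'   `config`, `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", label,
                    conditionMessage(e)),
            class = "sumtwas_pipeline_error")
    })
  }
  arch <- stage("configure", architecture_config(
    n_causal_eqtl = cfg$n_causal_eqtl, cis_h2 = cfg$cis_h2,
    trait_h2_via_expression = cfg$trait_h2_via_expression,
    scenario = cfg$scenario, direct_snp_effect = cfg$direct_snp_effect
  ))
  grid <- tidyr::expand_grid(tissue = cfg$tissues,
                             gene = sprintf("gene%03d", seq_len(cfg$n_genes)))
  runs <- with_seed(cfg$seed, purrr::pmap(grid, function(tissue, gene) {
    study <- stage("simulate", simulate_study(
      cfg = locus_config(cfg$n_snps, maf_range = c(cfg$maf_low, cfg$maf_high),
                         ld_rho = cfg$ld_rho,
                         seed = sample.int(.Machine$integer.max, 1L)),
      arch = arch, n_ref = cfg$n_ref, n_gwas = cfg$n_gwas,
      gene = gene, tissue = tissue
    ))
    ws <- stage("train-weights", suppressWarnings(train_weights(
      study$reference$panel, study$reference$expression,
      models = cfg$models, n_folds = cfg$n_folds, floor = cfg$cv_floor,
      gene = gene, tissue = tissue,
      seed = sample.int(.Machine$integer.max, 1L)
    )))
    ld <- stage("ld", switch(cfg$ld_source,
      gwas = ld_from_panel(study$gwas$panel),
      reference = ld_from_panel(study$reference$panel),
      abort(sprintf("unknown ld_source '%s'", cfg$ld_source))
    ))
    assoc <- stage("assoc", run_locus(ws, study$sumstats, ld,
                                      ridge = cfg$ridge))
    list(ws = ws, assoc = assoc,
         truth = tibble::tibble(gene = gene, tissue = tissue,
                                scenario = cfg$scenario,
                                causal_snps = list(study$truth$causal_snps)))
  }))
  assoc <- dplyr::bind_rows(purrr::map(runs, "assoc"))
  class(assoc) <- c("twas_assoc", class(assoc))
  bonf_m <- if (is.na(cfg$bonferroni_m[1])) NULL else as.integer(cfg$bonferroni_m)
  calls <- stage("correct", apply_per_tissue(assoc, method = cfg$method,
                                             alpha = cfg$alpha, m = bonf_m))
  genes <- stage("report", gene_report(calls))
  log <- c(
    sprintf("sumtwas %s | R %s", as.character(utils::packageVersion("sumtwas")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed=%s alpha=%g method=%s bonferroni_m=%s", cfg$seed, cfg$alpha,
            cfg$method, if (is.null(bonf_m)) "per-tissue tests" else bonf_m),
    sprintf("ld_source=%s ridge=%g cis_window_bp=%g", cfg$ld_source,
            cfg$ridge, cfg$cis_window_bp),
    sprintf("scenario=%s n_genes=%d tissues=%d n_ref=%d n_gwas=%d n_snps=%d",
            cfg$scenario, as.integer(cfg$n_genes), length(cfg$tissues),
            as.integer(cfg$n_ref), as.integer(cfg$n_gwas),
            as.integer(cfg$n_snps)),
    sprintf("models=%s precedence=%s", paste(cfg$models, collapse = ","),
            paste(MODEL_PRECEDENCE, collapse = ">"))
  )
  if (!is.null(cfg$out)) {
    readr::write_tsv(assoc, file.path(cfg$out, "assoc.tsv"), progress = FALSE)
    render_report(calls, file.path(cfg$out, "calls.tsv"))
    readr::write_tsv(dplyr::select(genes, -"hits", -"significant_under"),
                     file.path(cfg$out, "genes.tsv"), progress = FALSE)
    writeLines(log, file.path(cfg$out, "run.log"))
  }
  structure(
    list(assoc = assoc, calls = calls, genes = genes,
         weights = purrr::map(runs, "ws"),
         truth = dplyr::bind_rows(purrr::map(runs, "truth")),
         config = cfg, log = log),
    class = "twas_pipeline"
  )
}

#' @export
print.twas_pipeline <- function(x, ...) {
  cat("<twas_pipeline>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  n_sig <- sum(x$calls$significant %in% TRUE)
  cat(sprintf("  %d association test(s), %d significant under %s\n",
              nrow(x$assoc), n_sig, x$config$method))
  invisible(x)
}
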