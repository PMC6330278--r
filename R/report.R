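#' Five expression-panel tissue labels
#'
#' The tissue panels of the multi-tissue Alzheimer's disease TWAS whose
#' result tables ship with the package: brain RNA-seq (total expression and
#' splicing, CMC), whole blood RNA array (YFS), peripheral blood RNA array
#' (NTR), and adipose RNA-seq (METSIM).
#'
#' @export
ad_tissues <- function() {
  c("Brain (CMC) RNA-seq", "Brain (CMC) RNA-seq splicing",
    "Whole Blood (YFS) RNA Array", "Peripheral Blood (NTR) RNA Array",
    "Adipose (METSIM) RNA-seq")
}

#' Packaged reference results from a published AD TWAS
#'
#' Gene-tissue association rows (gene, chromosome, tissue, p_value, z_score)
#' reported by a multi-tissue Alzheimer's disease TWAS of IGAP GWAS summary
#' statistics: `"bonferroni"` gives the 18 rows significant under the strict
#' 0.05/15000 threshold, `"bh"` the 34 additional rows called under the
#' per-tissue Benjamini-Hochberg procedure at FDR 0.05. Values are verbatim
#' from the published tables; read-only fixtures used for consistency
#' checks, never mutated by any pipeline run.
#'
#' @param which `"bonferroni"` or `"bh"`.
#' @return A tibble.
#' @export
#' @examples
#' t1 <- ad_twas_hits("bonferroni")
#' count_unique_significant(t1, threshold = 0.05 / 15000)$n  # 15
ad_twas_hits <- function(which = c("bonferroni", "bh")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("ad_twas_", which, ".tsv"),
                      package = "sumtwas", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    gene = "c", chromosome = "c", tissue = "c",
                    p_value = "d", z_score = "d"))
}

#' Count unique significant genes
#'
#' Distinct gene symbols among rows with `p_value < threshold` (a gene
#' hit in several tissues is counted once). Order-invariant and idempotent.
#'
#' @param rows Tibble with columns `gene` and `p_value`.
#' @param threshold P-value cutoff; `NULL` counts all rows.
#' @return List with `n` (count) and `genes` (sorted unique symbols).
#' @export
count_unique_significant <- function(rows, threshold = NULL) {
  if (nrow(rows) == 0) return(list(n = 0L, genes = character()))
  if (!is.null(threshold)) {
    rows <- dplyr::filter(rows, !is.na(.data$p_value),
                          .data$p_value < threshold)
  }
  genes <- sort(unique(rows$gene))
  list(n = length(genes), genes = genes)
}

#' Check z-score / p-value internal consistency
#'
#' Recomputes `2 * pnorm(-|z|)` from each row's z-score and flags rows whose
#' printed p-value disagrees beyond 3 significant figures and 5% relative
#' tolerance (published tables round aggressively, so both checks are
#' allowed to certify a row).
#'
#' @param rows Tibble with columns `p_value` and `z_score`.
#' @param rel_tol Relative tolerance (default 0.05).
#' @return `rows` with `p_implied`, `rel_err` and `pass` columns added.
#' @export
consistency_check <- function(rows, rel_tol = 0.05) {
  dplyr::mutate(
    rows,
    p_implied = zscore_to_pvalue(.data$z_score),
    rel_err = abs(.data$p_implied - .data$p_value) / .data$p_value,
    pass = .data$rel_err <= rel_tol |
      signif(.data$p_implied, 3) == signif(.data$p_value, 3)
  )
}

#' Aggregate association calls per gene
#'
#' One row per gene across tissues: chromosome, the per-tissue hits as a
#' list-column, the best (smallest) p-value, and which correction regimes
#' called the gene significant anywhere.
#'
#' @param calls Output of [apply_per_tissue()] (or any tibble with gene,
#'   chromosome, tissue, p_value, z_score and optionally method/significant).
#' @return A tibble, one row per gene, sorted by `best_p`.
#' @export
gene_report <- function(calls) {
  has_sig <- all(c("method", "significant") %in% names(calls))
  out <- calls |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      chromosome = dplyr::first(.data$chromosome),
      hits = {
        h <- tibble::new_tibble(list(tissue = .data$tissue,
                                     p_value = .data$p_value,
                                     z_score = .data$z_score))
        list(h)
      },
      best_p = min(.data$p_value),
      significant_under = if (has_sig) {
        list(sort(unique(.data$method[.data$significant %in% TRUE])))
      } else {
        list(character())
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$best_p)
  out
}

#' Write an association/calls table to disk
#'
#' Emits the table sorted deterministically — significant rows first (when a
#' `significant` column is present), then ascending p — as TSV or a simple
#' Markdown table.
#'
#' @param calls Association or calls tibble.
#' @param path Output file.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(calls, path, format = c("tsv", "markdown")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       sprintf("unknown format '%s'.", format[1]),
                       class = "sumtwas_input_error"))
  ord <- if ("significant" %in% names(calls)) {
    order(!(calls$significant %in% TRUE), calls$p_value, calls$gene)
  } else {
    order(calls$p_value, calls$gene)
  }
  out <- calls[ord, , drop = FALSE]
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    cols <- names(out)
    fmt_cell <- function(x) {
      if (is.numeric(x)) formatC(x, format = "g", digits = 6) else as.character(x)
    }
    body <- apply(as.data.frame(lapply(out, fmt_cell)), 1L,
                  function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    lines <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
               if (nrow(out) > 0) body)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @method autoplot twas_assoc
#' @export
autoplot.twas_assoc <- function(object, alpha = 0.05, m = 15000, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_value))
  df$gene <- factor(df$gene, levels = unique(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene,
                                   y = -log10(.data$p_value),
                                   colour = .data$tissue)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha / m), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Imputed expression-trait associations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @method autoplot twas_correction
#' @export
autoplot.twas_correction <- function(object, ...) {
  if (!"rank" %in% names(object)) {
    abort("ladder plot is defined for Benjamini-Hochberg corrections.",
          class = "sumtwas_input_error")
  }
  alpha <- attr(object, "alpha"); m <- attr(object, "m")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$p_value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_abline(slope = alpha / m, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(x = "rank k", y = expression(P[(k)]),
                  title = sprintf("Benjamini-Hochberg step-up (alpha = %g)",
                                  alpha)) +
    ggplot2::theme_minimal()
}
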