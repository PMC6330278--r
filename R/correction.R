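new_correction <- function(tbl, method, alpha, m, threshold, k_star = NA_integer_,
                           tissue = NA_character_) {
  structure(
    tbl,
    method = method, alpha = alpha, m = m, threshold = threshold,
    k_star = k_star, tissue = tissue,
    class = c("twas_correction", class(tbl))
  )
}

check_pvalues <- function(p) {
  p_ok <- p[!is.na(p)]
  if (any(p_ok < 0 | p_ok > 1)) {
    abort("p-values must lie in [0, 1].", class = "sumtwas_input_error")
  }
  invisible(p)
}

#' Bonferroni family-wise error control
#'
#' Rejects exactly the tests with `p < alpha / m`. By default `m` is the
#' number of tests supplied; fixing `m = 15000` reproduces the conventional
#' transcriptome-wide threshold 0.05/15000 used in published TWAS.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Correction denominator (default: `length(pvalues)`).
#' @return A `twas_correction` tibble (index, p_value, significant) with
#'   attributes method/alpha/m/threshold.
#' @export
#' @examples
#' bonferroni(c(1e-7, 0.01), alpha = 0.05, m = 15000)
bonferroni <- function(pvalues, alpha = 0.05, m = NULL) {
  check_pvalues(pvalues)
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "sumtwas_config_error")
  }
  keep <- !is.na(pvalues)
  m <- as.integer(m %||% sum(keep))
  if (m < 1) abort("`m` must be >= 1.", class = "sumtwas_config_error")
  threshold <- alpha / m
  tbl <- tibble::tibble(
    index = which(keep), p_value = as.numeric(pvalues[keep]),
    significant = pvalues[keep] < threshold
  )
  new_correction(tbl, "bonferroni", alpha, m, threshold)
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Sorts the p-values in ascending order (stable in the original order on
#' ties), computes the critical value `(k / m) * alpha` for each rank k,
#' finds the largest k with `P_(k) <= (k / m) * alpha`, and rejects the
#' hypotheses of ranks 1..k — including any intermediate rank whose own
#' p-value exceeds its critical value, per the step-up rule.
#'
#' @inheritParams bonferroni
#' @return A `twas_correction` tibble (index, p_value, rank, critical,
#'   significant), attributes include `k_star` and `threshold` (the largest
#'   rejected p-value, or 0 if none).
#' @export
#' @examples
#' benjamini_hochberg(c(0.001, 0.049, 0.9), alpha = 0.05)
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  check_pvalues(pvalues)
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "sumtwas_config_error")
  }
  keep <- !is.na(pvalues)
  p <- as.numeric(pvalues[keep])
  m <- length(p)
  if (m == 0) {
    tbl <- tibble::tibble(index = integer(), p_value = numeric(),
                          rank = integer(), critical = numeric(),
                          significant = logical())
    return(new_correction(tbl, "bh", alpha, 0L, 0, k_star = 0L))
  }
  ord <- order(p)                      # stable for ties (radix)
  critical <- seq_len(m) / m * alpha
  ok <- p[ord] <= critical
  k_star <- if (any(ok)) max(which(ok)) else 0L
  sig_sorted <- seq_len(m) <= k_star
  threshold <- if (k_star > 0) p[ord][k_star] else 0
  rank <- integer(m); rank[ord] <- seq_len(m)
  sig <- logical(m); sig[ord] <- sig_sorted
  tbl <- tibble::tibble(
    index = which(keep), p_value = p, rank = rank,
    critical = critical[rank], significant = sig
  )
  new_correction(tbl, "bh", alpha, m, threshold, k_star = as.integer(k_star))
}

#' @method glance twas_correction
#' @export
glance.twas_correction <- function(x, ...) {
  tibble::tibble(
    tissue = attr(x, "tissue"), method = attr(x, "method"),
    alpha = attr(x, "alpha"), m = attr(x, "m"),
    threshold = attr(x, "threshold"), k_star = attr(x, "k_star"),
    n_rejected = sum(x$significant, na.rm = TRUE)
  )
}

#' @export
print.twas_correction <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<twas_correction> %s at alpha = %g (m = %d): %d rejection(s)\n",
              g$method, g$alpha, g$m, g$n_rejected))
  invisible(x)
}

#' Apply a multiple-testing correction within each tissue
#'
#' Correction families are formed per tissue stratum (each tissue's tests
#' are corrected independently), matching per-tissue FDR practice. Rows with
#' `NA` p-values (untestable genes) are excluded from the family size and
#' flagged `NA`. Ties in p are broken by a stable sort on (p, gene, tissue).
#'
#' @param assoc Association tibble with columns `gene`, `tissue`, `p_value`
#'   (e.g. from [twas_assoc()]).
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha Error rate in (0, 1).
#' @param m Fixed Bonferroni denominator (e.g. 15000); default: the number
#'   of tests actually performed in the tissue. Ignored for BH.
#' @param tissues Optional subset of tissue labels; unknown labels error.
#' @return The association tibble with columns `method`, `threshold` and
#'   `significant` added, sorted by tissue then p; attribute `summary` holds
#'   the per-tissue [glance()] table.
#' @export
apply_per_tissue <- function(assoc, method = c("bh", "bonferroni"),
                             alpha = 0.05, m = NULL, tissues = NULL) {
  method <- match.arg(method)
  if (!all(c("gene", "tissue", "p_value") %in% names(assoc))) {
    abort("`assoc` needs columns gene, tissue, p_value.",
          class = "sumtwas_input_error")
  }
  if (!is.null(tissues)) {
    unknown <- setdiff(tissues, unique(assoc$tissue))
    if (length(unknown) > 0) {
      abort(sprintf("unknown tissue label(s): %s",
                    paste(unknown, collapse = ", ")),
            class = "sumtwas_input_error")
    }
    assoc <- dplyr::filter(assoc, .data$tissue %in% tissues)
  }
  assoc <- dplyr::arrange(assoc, .data$tissue, .data$p_value, .data$gene)
  pieces <- split(assoc, factor(assoc$tissue, levels = unique(assoc$tissue)))
  summaries <- list()
  out <- purrr::map_dfr(pieces, function(df) {
    corr <- if (method == "bonferroni") {
      bonferroni(df$p_value, alpha = alpha, m = m)
    } else {
      benjamini_hochberg(df$p_value, alpha = alpha)
    }
    attr(corr, "tissue") <- df$tissue[1]
    summaries[[df$tissue[1]]] <<- glance(corr)
    df$method <- method
    df$threshold <- attr(corr, "threshold")
    df$significant <- NA
    df$significant[corr$index] <- corr$significant
    df
  })
  out <- tibble::as_tibble(out)
  attr(out, "summary") <- dplyr::bind_rows(summaries)
  class(out) <- c("twas_calls", class(out))
  out
}
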