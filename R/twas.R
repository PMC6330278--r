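#' Estimate or validate an LD (SNP correlation) matrix
#'
#' `ld_from_panel()` estimates the LD correlation matrix from dosages;
#' `validate_ld()` checks symmetry, unit diagonal and positive
#' semi-definiteness (to tolerance) of a supplied matrix.
#'
#' @param panel A `genotype_panel` or dosage matrix.
#' @return SNP correlation matrix with SNP-id dimnames.
#' @export
ld_from_panel <- function(panel) {
  x <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  s <- suppressWarnings(cor(x))
  s[!is.finite(s)] <- 0       # monomorphic columns carry no LD information
  diag(s) <- 1
  validate_ld(s)
}

#' @rdname ld_from_panel
#' @param ld Square numeric matrix to validate.
#' @param tol Numerical tolerance.
#' @export
validate_ld <- function(ld, tol = 1e-6) {
  ld <- as.matrix(ld)
  if (nrow(ld) != ncol(ld)) {
    abort("LD matrix must be square.", class = "sumtwas_input_error")
  }
  if (max(abs(ld - t(ld))) > tol) {
    abort("LD matrix must be symmetric.", class = "sumtwas_input_error")
  }
  if (max(abs(diag(ld) - 1)) > tol) {
    abort("LD matrix must have unit diagonal.", class = "sumtwas_input_error")
  }
  ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev))) {
    abort("LD matrix is not positive semi-definite.",
          class = "sumtwas_input_error")
  }
  ld
}

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")
ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align expression weights with GWAS summary statistics
#'
#' Intersects SNPs by id, orders both sources identically, flips the sign of
#' the GWAS z-score where the effect/other alleles are swapped between the
#' two sources (including strand-complement matches), and by default drops
#' strand-ambiguous (A/T, C/G) SNPs, whose orientation cannot be resolved
#' from summary data. SNPs with irreconcilable alleles are dropped with a
#' warning; SNPs present in the weights but absent from the summary are
#' dropped and the remaining weights used as-is (counts reported).
#'
#' @param ws A `weight_set` whose `snps` carry a1/a2 allele columns.
#' @param sumstats A `gwas_summary` tibble.
#' @param drop_palindromic Drop strand-ambiguous SNPs (default `TRUE`).
#' @return List with `w` (weights), `z` (aligned z-scores), `snps` (aligned
#'   SNP tibble) and counts `n_flipped`, `n_palindromic`, `n_mismatch`,
#'   `n_missing`.
#' @export
harmonize <- function(ws, sumstats, drop_palindromic = TRUE) {
  stopifnot(inherits(ws, "weight_set"))
  wsnp <- ws$snps
  if (!all(c("a1", "a2") %in% names(wsnp))) {
    abort("weight set lacks allele columns a1/a2.",
          class = "sumtwas_input_error")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(wsnp, w_a1 = "a1", w_a2 = "a2"),
    dplyr::select(sumstats, "snp_id", g_a1 = "a1", g_a2 = "a2", "z"),
    by = "snp_id"
  )
  n_missing <- nrow(wsnp) - nrow(joined)
  if (nrow(joined) == 0) {
    abort("no overlapping SNPs between weights and summary statistics.",
          class = "sumtwas_input_error")
  }
  pal <- paste(joined$w_a1, joined$w_a2, sep = "/") %in% PALINDROMIC
  n_palindromic <- 0L
  if (drop_palindromic && any(pal)) {
    n_palindromic <- sum(pal)
    warn(sprintf("dropping %d strand-ambiguous SNP(s)", n_palindromic))
    joined <- joined[!pal, , drop = FALSE]
  }
  if (nrow(joined) == 0) {
    abort("no overlapping SNPs after removing strand-ambiguous sites.",
          class = "sumtwas_input_error")
  }
  comp <- function(a) unname(ALLELE_COMPLEMENT[a])
  same <- (joined$g_a1 == joined$w_a1 & joined$g_a2 == joined$w_a2) |
    (joined$g_a1 == comp(joined$w_a1) & joined$g_a2 == comp(joined$w_a2))
  swapped <- (joined$g_a1 == joined$w_a2 & joined$g_a2 == joined$w_a1) |
    (joined$g_a1 == comp(joined$w_a2) & joined$g_a2 == comp(joined$w_a1))
  mismatch <- !same & !swapped
  n_mismatch <- sum(mismatch)
  if (n_mismatch > 0) {
    warn(sprintf("dropping %d SNP(s) with irreconcilable alleles", n_mismatch))
    joined <- joined[!mismatch, , drop = FALSE]
    same <- same[!mismatch]
    swapped <- swapped[!mismatch]
  }
  if (nrow(joined) == 0) {
    abort("no overlapping SNPs after allele reconciliation.",
          class = "sumtwas_input_error")
  }
  z <- ifelse(swapped, -joined$z, joined$z)
  list(
    w = setNames(joined$weight, joined$snp_id),
    z = setNames(z, joined$snp_id),
    snps = dplyr::select(joined, "snp_id", dplyr::any_of(c("chr", "pos")),
                         a1 = "w_a1", a2 = "w_a2"),
    n_flipped = sum(swapped), n_palindromic = n_palindromic,
    n_mismatch = n_mismatch, n_missing = n_missing
  )
}

#' Impute the expression-trait association z-score
#'
#' The summary TWAS statistic: `z_twas = (W Z) / sqrt(W S W^T)`, where W are
#' the expression weights, Z the GWAS summary z-scores and S the SNP LD
#' matrix. Optionally shrinks S toward the identity,
#' `S <- (1 - ridge) S + ridge I`, before the quadratic form — recommended
#' (default in the table-level drivers: 0.1) when S is estimated from a
#' small external panel; use `ridge = 0` when S comes from the GWAS cohort
#' itself.
#'
#' @param w Numeric weight vector.
#' @param z Numeric z-score vector, aligned with `w`.
#' @param ld LD correlation matrix aligned with `w`.
#' @param ridge Shrinkage weight toward the identity in `[0, 1]`.
#' @param tol Degenerate-variance tolerance: if `W S W^T < tol` the gene is
#'   untestable and a `sumtwas_degenerate_error` is thrown.
#' @return The scalar imputed z-score.
#' @export
#' @examples
#' impute_association(c(1, 1), c(3, 3),
#'                    matrix(c(1, 0.5, 0.5, 1), 2), ridge = 0)  # 6/sqrt(3)
impute_association <- function(w, z, ld, ridge = 0, tol = 1e-10) {
  if (length(w) != length(z) || length(w) != nrow(ld)) {
    abort("`w`, `z` and `ld` dimensions disagree.",
          class = "sumtwas_input_error")
  }
  if (any(!is.finite(w)) || any(!is.finite(z))) {
    abort("non-finite weights or z-scores.", class = "sumtwas_input_error")
  }
  assert_prob(ridge, "ridge")
  s <- as.matrix(ld)
  if (ridge > 0) {
    s <- (1 - ridge) * s + diag(ridge, nrow(s))
  }
  denom <- drop(crossprod(w, s %*% w))
  if (denom < tol) {
    abort(sprintf("degenerate variance W S W^T = %.3g < %.3g; gene untestable",
                  denom, tol),
          class = "sumtwas_degenerate_error")
  }
  sum(w * z) / sqrt(denom)
}

#' Two-sided normal p-value of a z-score
#'
#' `p = 2 * pnorm(-|z|)`, evaluated on the lower tail directly (an
#' erfc-based path, numerically stable far beyond |z| = 8; e.g. |z| = 12.16
#' gives p = 4.9e-34 without underflow).
#'
#' @param z Finite numeric vector of z-scores.
#' @return p-values in (0, 1].
#' @export
zscore_to_pvalue <- function(z) {
  if (any(!is.finite(z))) {
    abort("non-finite z-score.", class = "sumtwas_input_error")
  }
  2 * pnorm(-abs(z))
}

#' Run the summary TWAS test for one gene
#'
#' Composes [harmonize()], [impute_association()] and [zscore_to_pvalue()]
#' for one trained weight set. Untestable genes (no usable weights, no SNP
#' overlap, or degenerate variance) are reported as rows with `NA`
#' statistics and a `status` label, never silently dropped.
#'
#' @param ws A `weight_set`.
#' @param sumstats A `gwas_summary` tibble.
#' @param ld LD correlation matrix covering the weight SNPs, or a
#'   `genotype_panel` to estimate it from.
#' @param ridge LD shrinkage toward the identity (see
#'   [impute_association()]; default 0.1, appropriate for external-panel LD).
#' @param drop_palindromic Passed to [harmonize()].
#' @return One-row tibble: gene, chromosome, tissue, p_value, z_score,
#'   n_snps, model, cv_r2, status.
#' @export
run_locus <- function(ws, sumstats, ld, ridge = 0.1, drop_palindromic = TRUE) {
  stopifnot(inherits(ws, "weight_set"))
  chrom <- if ("chr" %in% names(ws$snps)) as.character(ws$snps$chr[1]) else NA_character_
  row <- function(p, z, n, status) {
    tibble::tibble(gene = ws$gene, chromosome = chrom, tissue = ws$tissue,
                   p_value = p, z_score = z, n_snps = as.integer(n),
                   model = ws$model, cv_r2 = ws$cv_r2, status = status)
  }
  if (isTRUE(ws$untestable)) {
    return(row(NA_real_, NA_real_, NA_integer_, "untestable_weights"))
  }
  if (inherits(ld, "genotype_panel")) ld <- ld_from_panel(ld)
  h <- tryCatch(harmonize(ws, sumstats, drop_palindromic = drop_palindromic),
                sumtwas_input_error = function(e) e)
  if (inherits(h, "error")) {
    return(row(NA_real_, NA_real_, NA_integer_, "no_overlap"))
  }
  if (!is.null(colnames(ld))) {
    keep <- intersect(names(h$w), colnames(ld))
    if (length(keep) == 0) {
      return(row(NA_real_, NA_real_, NA_integer_, "no_overlap"))
    }
    idx <- match(keep, names(h$w))
    h$w <- h$w[idx]; h$z <- h$z[idx]
    s <- ld[keep, keep, drop = FALSE]
  } else {
    s <- as.matrix(ld)
  }
  zt <- tryCatch(
    impute_association(h$w, h$z, s, ridge = ridge),
    sumtwas_degenerate_error = function(e) e
  )
  if (inherits(zt, "error")) {
    return(row(NA_real_, NA_real_, length(h$w), "degenerate_variance"))
  }
  row(zscore_to_pvalue(zt), zt, length(h$w), "ok")
}

#' Run the summary TWAS test for many genes
#'
#' Applies [run_locus()] over a list of weight sets and returns the stacked
#' association table, column order mirroring the published layout
#' (gene / chromosome / tissue / p_value / z_score / ...).
#'
#' @param weight_sets List of `weight_set` objects.
#' @param sumstats A `gwas_summary` tibble (shared) or list parallel to
#'   `weight_sets`.
#' @param ld LD matrix or `genotype_panel` (shared), or a list parallel to
#'   `weight_sets`.
#' @inheritParams run_locus
#' @return A `twas_assoc` tibble.
#' @export
twas_assoc <- function(weight_sets, sumstats, ld, ridge = 0.1,
                       drop_palindromic = TRUE) {
  if (inherits(weight_sets, "weight_set")) weight_sets <- list(weight_sets)
  n <- length(weight_sets)
  get_i <- function(obj, i) {
    if (is.list(obj) && !inherits(obj, c("gwas_summary", "genotype_panel")) &&
        !is.data.frame(obj)) obj[[i]] else obj
  }
  out <- purrr::map_dfr(seq_len(n), function(i) {
    run_locus(weight_sets[[i]], get_i(sumstats, i), get_i(ld, i),
              ridge = ridge, drop_palindromic = drop_palindromic)
  })
  class(out) <- c("twas_assoc", class(out))
  out
}

#' @method glance twas_assoc
#' @export
glance.twas_assoc <- function(x, ...) {
  tibble::tibble(
    n_tests = sum(x$status == "ok"),
    n_untestable = sum(x$status != "ok"),
    n_genes = dplyr::n_distinct(x$gene),
    n_tissues = dplyr::n_distinct(x$tissue),
    min_p = suppressWarnings(min(x$p_value, na.rm = TRUE))
  )
}
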