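MODEL_MENU <- c("top1", "lasso", "enet", "blup_ridge")
# tie-break precedence among equal cross-validation R^2
MODEL_PRECEDENCE <- c("lasso", "enet", "blup_ridge", "top1")

new_weight_set <- function(gene, tissue, model, cv_r2, snps, n_folds = NA_integer_,
                           untestable = FALSE) {
  structure(
    list(gene = gene, tissue = tissue, model = model, cv_r2 = cv_r2,
         snps = snps, n_folds = n_folds, untestable = untestable),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> %s / %s: model %s, cv R2 = %.3f, %d SNPs (%d nonzero)%s\n",
              x$gene, x$tissue, x$model, x$cv_r2, nrow(x$snps),
              sum(x$snps$weight != 0),
              if (isTRUE(x$untestable)) " [untestable]" else ""))
  invisible(x)
}

#' @method tidy weight_set
#' @export
tidy.weight_set <- function(x, ...) {
  dplyr::mutate(x$snps, gene = x$gene, tissue = x$tissue, model = x$model,
                .before = 1L)
}

#' @method glance weight_set
#' @export
glance.weight_set <- function(x, ...) {
  tibble::tibble(gene = x$gene, tissue = x$tissue, model = x$model,
                 cv_r2 = x$cv_r2, n_folds = x$n_folds,
                 n_snps = nrow(x$snps), n_nonzero = sum(x$snps$weight != 0),
                 untestable = isTRUE(x$untestable))
}

seeded_foldid <- function(n, n_folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Fit one cis expression-prediction model
#'
#' Fits SNP weights for predicting expression from cis dosages, on internally
#' standardized scales (weight training is therefore invariant to affine
#' rescaling of raw expression). Models: `top1` (the single best marginal
#' eQTL's univariate coefficient, zeros elsewhere), `lasso` and `enet`
#' (glmnet, penalty chosen by seeded inner cross-validation; elastic-net
#' mixing fixed at 0.5), and `blup_ridge` (ridge regression on all cis SNPs,
#' the best-linear-unbiased-predictor surrogate).
#'
#' @param panel A `genotype_panel` (or bare dosage matrix with SNP columns).
#' @param expression Numeric expression vector.
#' @param model One of `"top1"`, `"lasso"`, `"enet"`, `"blup_ridge"`.
#' @param hyper Optional list: `s` (penalty choice for glmnet models,
#'   default `"lambda.1se"`), `lambda` (fixed ridge penalty for
#'   `blup_ridge`, bypassing CV), `n_folds` (inner CV folds, default 5).
#' @param seed Seed for the inner cross-validation folds.
#' @return Named numeric weight vector (one per SNP, standardized scales).
#' @export
fit_model <- function(panel, expression, model = "lasso", hyper = list(),
                      seed = NULL) {
  model <- match.arg(model, MODEL_MENU)
  x <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  xs <- standardize_cols(x, zero_as = "zero")
  ys <- standardize_vec(expression)
  m <- ncol(xs)
  n <- nrow(xs)
  s <- hyper$s %||% "lambda.1se"
  n_folds <- hyper$n_folds %||% 5L

  w <- if (model == "top1") {
    r <- drop(crossprod(xs, ys)) / (n - 1)
    w <- numeric(m)
    j <- which.max(abs(r))
    w[j] <- r[j]
    w
  } else if (model == "blup_ridge" && !is.null(hyper$lambda)) {
    lam <- hyper$lambda
    xtx <- crossprod(xs) / (n - 1)
    if (lam <= 0 && rcond_safe(xtx) < 1e-12) {
      warn("singular design with zero ridge penalty; applying regularization floor 1e-6")
      lam <- 1e-6
    }
    drop(solve(xtx + diag(lam, m), crossprod(xs, ys) / (n - 1)))
  } else {
    alpha <- switch(model, lasso = 1, enet = 0.5, blup_ridge = 0)
    foldid <- seeded_foldid(n, n_folds, seed)
    fit <- glmnet::cv.glmnet(xs, ys, alpha = alpha, foldid = foldid,
                             standardize = FALSE, intercept = TRUE)
    drop(as.matrix(coef(fit, s = s)))[-1L]
  }
  setNames(as.numeric(w), colnames(xs))
}

rcond_safe <- function(a) {
  tryCatch(1 / kappa(a, exact = FALSE), error = function(e) 0)
}

#' Cross-validated prediction accuracy of one model
#'
#' K-fold cross-validation with seeded fold assignment; the returned `cv_r2`
#' is the squared correlation between the concatenated held-out predictions
#' and observed expression. Near-zero predictive models may give values at or
#' near 0 (reported as is; a usability floor is applied only at model
#' selection).
#'
#' @inheritParams fit_model
#' @param n_folds Number of outer folds (>= 2).
#' @return A single numeric `cv_r2`.
#' @export
cross_validate <- function(panel, expression, model = "lasso", n_folds = 5L,
                           hyper = list(), seed = NULL) {
  x <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  n <- nrow(x)
  if (n_folds < 2L) {
    abort("`n_folds` must be >= 2.", class = "sumtwas_config_error")
  }
  if (n < n_folds) {
    abort("fewer individuals than folds.", class = "sumtwas_config_error")
  }
  foldid <- seeded_foldid(n, n_folds, seed)
  pred <- numeric(n)
  for (k in seq_len(n_folds)) {
    test <- foldid == k
    w <- fit_model(x[!test, , drop = FALSE], expression[!test], model = model,
                   hyper = hyper, seed = seed)
    xt <- x[test, , drop = FALSE]
    # apply training-fold standardization to the held-out dosages
    tr <- x[!test, , drop = FALSE]
    mu <- colMeans(tr)
    sds <- apply(tr, 2L, sd)
    sds[sds == 0] <- 1
    pred[test] <- drop(scale(xt, center = mu, scale = sds) %*% w)
  }
  if (sd(pred) == 0 || sd(expression) == 0) return(0)
  as.numeric(cor(pred, expression)^2)
}

#' Select the best expression model by cross-validation
#'
#' Returns the candidate with maximal `cv_r2`; exact ties are broken by the
#' fixed precedence lasso > enet > blup_ridge > top1. If every candidate is
#' below the usability floor the gene is marked untestable (it is reported,
#' and excluded from association testing downstream).
#'
#' @param candidates Tibble with columns `model`, `cv_r2`, and `weights`
#'   (list-column of named weight vectors).
#' @param floor Usability floor on `cv_r2` (default 0.01).
#' @param gene,tissue,n_folds Metadata carried into the result.
#' @return A `weight_set`.
#' @export
select_model <- function(candidates, floor = 0.01, gene = "gene",
                         tissue = "tissue", n_folds = NA_integer_) {
  if (nrow(candidates) == 0) {
    abort("no candidate models supplied.", class = "sumtwas_config_error")
  }
  cand <- dplyr::mutate(
    candidates,
    .rank = match(.data$model, MODEL_PRECEDENCE),
    cv_r2_sel = pmax(.data$cv_r2, 0)
  )
  cand <- dplyr::arrange(cand, dplyr::desc(.data$cv_r2_sel), .data$.rank)
  best <- cand[1L, ]
  w <- best$weights[[1L]]
  snps <- tibble::tibble(snp_id = names(w), weight = as.numeric(w))
  untestable <- best$cv_r2_sel <= floor || all(snps$weight == 0)
  if (untestable) {
    warn(sprintf("gene %s (%s): no model above cv R2 floor %.3g; marked untestable",
                 gene, tissue, floor))
  }
  new_weight_set(gene = gene, tissue = tissue, model = best$model,
                 cv_r2 = best$cv_r2, snps = snps, n_folds = n_folds,
                 untestable = untestable)
}

#' Train cis expression weights by cross-validated model competition
#'
#' Cross-validates each requested model on the reference panel, refits the
#' winner on the full data, and returns a `weight_set` carrying the per-SNP
#' weights, the winning model label and its cross-validation R^2 — the
#' weight vector W of the summary TWAS statistic.
#'
#' @inheritParams fit_model
#' @param models Subset of `c("top1", "lasso", "enet", "blup_ridge")`.
#' @param n_folds Outer cross-validation folds (default 5).
#' @param floor Usability floor on `cv_r2` (default 0.01).
#' @param gene,tissue Labels carried through to results.
#' @return A `weight_set`; SNP metadata columns (chr, pos, a1, a2) are
#'   attached when `panel` is a `genotype_panel`.
#' @export
#' @examples
#' study <- simulate_study(locus_config(8, seed = 1),
#'                         architecture_config(2, cis_h2 = 0.5),
#'                         n_ref = 200, n_gwas = 200, seed = 2)
#' ws <- train_weights(study$reference$panel, study$reference$expression,
#'                     models = c("top1", "lasso"), seed = 3)
#' glance(ws)
train_weights <- function(panel, expression,
                          models = c("top1", "lasso", "enet", "blup_ridge"),
                          n_folds = 5L, floor = 0.01, gene = "gene",
                          tissue = "tissue", hyper = list(), seed = NULL) {
  models <- match.arg(models, MODEL_MENU, several.ok = TRUE)
  candidates <- purrr::map_dfr(models, function(mod) {
    tibble::tibble(
      model = mod,
      cv_r2 = cross_validate(panel, expression, model = mod,
                             n_folds = n_folds, hyper = hyper, seed = seed),
      weights = list(fit_model(panel, expression, model = mod, hyper = hyper,
                               seed = seed))
    )
  })
  ws <- select_model(candidates, floor = floor, gene = gene, tissue = tissue,
                     n_folds = as.integer(n_folds))
  if (inherits(panel, "genotype_panel")) {
    ws$snps <- dplyr::left_join(ws$snps, panel$snps, by = "snp_id")
    ws$snps <- dplyr::select(ws$snps, "snp_id", "chr", "pos", "a1", "a2",
                             "weight")
  }
  ws$candidates <- dplyr::select(candidates, "model", "cv_r2")
  ws
}

#' Marginal ImpG-style weights
#'
#' The summary-imputation weight vector `Sigma_es %*% solve(Sigma_ss + lambda I)`
#' on standardized scales: `Sigma_es` is the sample covariance between each
#' SNP and expression, `Sigma_ss` the SNP correlation (LD) matrix, and
#' `lambda` a ridge term guarding rank-deficient panels. If the regularized
#' system is still numerically singular the penalty is escalated with a
#' warning.
#'
#' @inheritParams fit_model
#' @param lambda Ridge penalty on the LD correlation scale (default 0.1).
#' @return Named numeric weight vector.
#' @export
marginal_impg_weights <- function(panel, expression, lambda = 0.1) {
  x <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  xs <- standardize_cols(x, zero_as = "zero")
  ys <- standardize_vec(expression)
  n <- nrow(xs)
  ses <- drop(crossprod(xs, ys)) / (n - 1)
  sss <- crossprod(xs) / (n - 1)
  m <- ncol(xs)
  lam <- lambda
  repeat {
    w <- tryCatch(drop(solve(sss + diag(lam, m), ses)), error = function(e) NULL)
    if (!is.null(w)) break
    lam <- max(lam * 10, 1e-4)
    warn(sprintf("LD matrix singular; escalating ridge penalty to %g", lam))
  }
  setNames(as.numeric(w), colnames(xs))
}

#' Restrict a SNP table to the cis window of a gene
#'
#' SNPs within `window` base pairs of the gene start (1-based, inclusive).
#'
#' @param snps Tibble with columns `chr` and `pos`.
#' @param gene_chr,gene_start Gene anchor coordinates.
#' @param window Half-width in base pairs (default 500 kb).
#' @return The filtered tibble.
#' @export
cis_window <- function(snps, gene_chr, gene_start, window = 5e5) {
  dplyr::filter(snps, .data$chr == as.character(gene_chr),
                abs(.data$pos - gene_start) <= window)
}

#' Build a weight set from marginal ImpG weights
#'
#' Convenience wrapper pairing [marginal_impg_weights()] with the panel's
#' SNP metadata so the result can flow straight into [run_locus()].
#'
#' @inheritParams marginal_impg_weights
#' @param gene,tissue Labels carried through to results.
#' @return A `weight_set` with model label `"marginal_impg"`.
#' @export
impg_weight_set <- function(panel, expression, gene = "gene",
                            tissue = "tissue", lambda = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"))
  w <- marginal_impg_weights(panel, expression, lambda = lambda)
  snps <- dplyr::left_join(
    tibble::tibble(snp_id = names(w), weight = as.numeric(w)),
    panel$snps, by = "snp_id"
  )
  snps <- dplyr::select(snps, "snp_id", "chr", "pos", "a1", "a2", "weight")
  new_weight_set(gene = gene, tissue = tissue, model = "marginal_impg",
                 cv_r2 = NA_real_, snps = snps)
}
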