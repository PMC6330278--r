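# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "sumtwas_config_error")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else
      suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Column-standardize a dosage/covariate matrix (mean 0, sd 1, n-1 denominator).
# Zero-variance columns: "error" aborts; "drop" removes them with a warning
# (the summary-statistics contract: flagged and excluded); "zero" keeps them
# as all-zero columns carrying no signal (simulation/training contexts).
standardize_cols <- function(x, zero_as = c("error", "drop", "zero")) {
  zero_as <- match.arg(zero_as)
  x <- as.matrix(x)
  sds <- apply(x, 2L, sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    labels <- paste(head(colnames(x)[bad], 5L), collapse = ", ")
    if (zero_as == "error") {
      abort(sprintf("%d zero-variance column(s): %s", sum(bad), labels),
            class = "sumtwas_degenerate_error")
    }
    if (zero_as == "drop") {
      warn(sprintf("excluding %d zero-variance SNP(s): %s", sum(bad), labels))
      x <- x[, !bad, drop = FALSE]
      sds <- sds[!bad]
    } else {
      sds[bad] <- 1          # centered column becomes all-zero: no signal
    }
  }
  scale(x, center = TRUE, scale = sds)
}

standardize_vec <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) {
    abort("vector has zero variance; cannot standardize.",
          class = "sumtwas_degenerate_error")
  }
  as.numeric((y - mean(y)) / s)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name),
          class = "sumtwas_config_error")
  }
  invisible(x)
}
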