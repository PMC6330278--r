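test_that("lasso puts unit mass on a noiseless single eQTL", {
  cfg <- locus_config(6, maf_range = c(0.3, 0.5), ld_rho = 0.2, seed = 1001)
  panel <- simulate_genotypes(cfg, 400, seed = 1002)
  expr <- as.numeric(scale(panel$dosage[, 3]))
  w <- fit_model(panel, expr, "lasso", seed = 1003)
  expect_gt(w[3], 0.9)
  expect_true(all(abs(w[-3]) < 0.05))
})

test_that("lasso returns all zeros on non-heritable expression", {
  cfg <- locus_config(8, seed = 1011)
  panel <- simulate_genotypes(cfg, 400, seed = 1012)
  ex <- simulate_expression(panel, architecture_config(2, cis_h2 = 0),
                            seed = 1013)
  w <- fit_model(panel, ex$expression, "lasso", seed = 1014)
  expect_true(all(w == 0))
})

test_that("fitted weights recover the simulated eQTL architecture", {
  rec <- vapply(1:5, function(i) {
    st <- suppressWarnings(simulate_study(
      locus_config(20, maf_range = c(0.1, 0.5), ld_rho = 0.2,
                   seed = 1020 + i),
      architecture_config(3, cis_h2 = 0.5),
      n_ref = 500, n_gwas = 10, seed = 1040 + i
    ))
    w <- fit_model(st$reference$panel, st$reference$expression, "lasso",
                   seed = 1060 + i)
    cor(w, st$truth$weights$weight)
  }, numeric(1))
  expect_gt(mean(rec), 0.8)
})

test_that("weight training is invariant to affine rescaling of expression", {
  cfg <- locus_config(8, seed = 1071)
  panel <- simulate_genotypes(cfg, 300, seed = 1072)
  ex <- simulate_expression(panel, architecture_config(2, cis_h2 = 0.5),
                            seed = 1073)
  for (mod in c("top1", "lasso", "enet", "blup_ridge")) {
    w1 <- fit_model(panel, ex$expression, mod, seed = 1074)
    w2 <- fit_model(panel, 3.7 * ex$expression - 11, mod, seed = 1074)
    expect_equal(w1, w2, tolerance = 1e-12)
  }
})

test_that("blup_ridge with zero penalty on a singular design applies a floor", {
  cfg <- locus_config(5, maf_range = c(0.3, 0.5), seed = 1081)
  panel <- simulate_genotypes(cfg, 200, seed = 1082)
  panel$dosage[, 5] <- panel$dosage[, 4]         # exact collinearity
  ex <- simulate_expression(panel, architecture_config(1, cis_h2 = 0.5),
                            seed = 1083)
  expect_warning(
    w <- fit_model(panel, ex$expression, "blup_ridge",
                   hyper = list(lambda = 0)),
    "regularization floor"
  )
  expect_true(all(is.finite(w)))
})

test_that("cross-validation approaches 1 for noiseless prediction, 0 under the null", {
  cfg <- locus_config(6, maf_range = c(0.3, 0.5), seed = 1091)
  panel <- simulate_genotypes(cfg, 300, seed = 1092)
  expr <- as.numeric(scale(panel$dosage[, 2]))
  expect_gt(cross_validate(panel, expr, "lasso", seed = 1093), 0.98)

  ex0 <- simulate_expression(panel, architecture_config(2, cis_h2 = 0),
                             seed = 1094)
  expect_lt(cross_validate(panel, ex0$expression, "lasso", seed = 1095), 0.05)
})

test_that("cross-validation errors with more folds than individuals", {
  cfg <- locus_config(3, seed = 1101)
  panel <- simulate_genotypes(cfg, 4, seed = 1102)
  expect_error(cross_validate(panel, rnorm(4), "top1", n_folds = 5),
               class = "sumtwas_config_error")
  expect_error(cross_validate(panel, rnorm(4), "top1", n_folds = 1),
               class = "sumtwas_config_error")
})

test_that("mean cv R2 sits below cis_h2 by the expected shrinkage margin", {
  cv <- vapply(1:20, function(i) {
    st <- suppressWarnings(simulate_study(
      locus_config(10, seed = 1110 + i), architecture_config(3, cis_h2 = 0.5),
      n_ref = 500, n_gwas = 10, seed = 1140 + i
    ))
    cross_validate(st$reference$panel, st$reference$expression, "lasso",
                   seed = 1170 + i)
  }, numeric(1))
  expect_gte(mean(cv), 0.40)
  expect_lte(mean(cv), 0.50)
})

test_that("model selection takes the argmax and breaks ties by precedence", {
  w <- setNames(c(0.2, 0, 0), c("a", "b", "c"))
  cand <- tibble::tibble(model = c("top1", "lasso"), cv_r2 = c(0.30, 0.45),
                         weights = list(w, w))
  expect_identical(select_model(cand)$model, "lasso")

  cand_tie <- tibble::tibble(model = c("top1", "lasso"), cv_r2 = c(0.40, 0.40),
                             weights = list(w, w))
  expect_identical(select_model(cand_tie)$model, "lasso")

  cand_low <- tibble::tibble(model = c("top1", "lasso"),
                             cv_r2 = c(0.005, 0.002), weights = list(w, w))
  expect_warning(ws <- select_model(cand_low), "untestable")
  expect_true(ws$untestable)
})

test_that("the selected model is at least as predictive as top1", {
  st <- suppressWarnings(simulate_study(
    locus_config(10, seed = 1201), architecture_config(3, cis_h2 = 0.5),
    n_ref = 300, n_gwas = 10, seed = 1202
  ))
  ws <- train_weights(st$reference$panel, st$reference$expression,
                      models = c("top1", "lasso", "enet"), seed = 1203)
  cands <- ws$candidates
  expect_gte(max(cands$cv_r2), cands$cv_r2[cands$model == "top1"])
  expect_identical(ws$cv_r2, max(cands$cv_r2))
})

test_that("ImpG weights equal marginal covariances under exactly identity LD", {
  set.seed(1301)
  n <- 100
  raw <- matrix(rnorm(n * 4), n, 4)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))                       # orthonormal, mean ~0 columns
  x <- scale(q)                            # unit sd, sample correlation = I
  colnames(x) <- sprintf("s%d", 1:4)
  y <- rnorm(n)
  w <- marginal_impg_weights(x, y, lambda = 0)
  ses <- drop(crossprod(scale(x), scale(y))) / (n - 1)
  expect_equal(unname(w), unname(ses), tolerance = 1e-10)
})

test_that("ImpG weight of a single SNP is its expression correlation", {
  set.seed(1311)
  x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "s1"))
  y <- 0.5 * x[, 1] + rnorm(200)
  w <- marginal_impg_weights(x, y, lambda = 0)
  expect_equal(unname(w), cor(x[, 1], y), tolerance = 1e-10)
})

test_that("ImpG weights at zero penalty equal the multi-SNP least-squares fit", {
  cfg <- locus_config(3, maf_range = c(0.2, 0.5), ld_rho = 0.5, seed = 1321)
  panel <- simulate_genotypes(cfg, 250, seed = 1322)
  ex <- simulate_expression(panel, architecture_config(2, cis_h2 = 0.4),
                            seed = 1323)
  w <- marginal_impg_weights(panel, ex$expression, lambda = 0)
  xs <- scale(panel$dosage)
  ys <- scale(ex$expression)
  wols <- drop(solve(crossprod(xs), crossprod(xs, ys)))
  expect_equal(unname(w), unname(wols), tolerance = 1e-10)
})

test_that("weight files round-trip through the TSV format", {
  st <- suppressWarnings(simulate_study(locus_config(5, seed = 1401),
                       architecture_config(1, cis_h2 = 0.6),
                       n_ref = 200, n_gwas = 10, seed = 1402))
  ws <- train_weights(st$reference$panel, st$reference$expression,
                      models = c("top1", "lasso"), gene = "ABC1",
                      tissue = "Brain (CMC) RNA-seq", seed = 1403)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(ws, path)
  back <- read_weights(path)
  expect_identical(back$gene, "ABC1")
  expect_identical(back$model, ws$model)
  expect_equal(back$cv_r2, ws$cv_r2, tolerance = 1e-9)
  expect_equal(back$snps$weight, ws$snps$weight, tolerance = 1e-12)
})

test_that("tidy and glance summarise a weight set", {
  ws <- make_weight_set(c(0.5, 0, -0.2))
  td <- tidy(ws)
  expect_identical(nrow(td), 3L)
  expect_true(all(c("gene", "tissue", "model", "snp_id", "weight") %in%
                    names(td)))
  gl <- glance(ws)
  expect_identical(gl$n_nonzero, 2L)
  expect_false(gl$untestable)
})

test_that("cis_window keeps only SNPs near the gene anchor", {
  snps <- tibble::tibble(chr = c("1", "1", "2"), pos = c(1e6, 2e6, 1e6))
  out <- cis_window(snps, gene_chr = "1", gene_start = 1.2e6, window = 5e5)
  expect_identical(nrow(out), 1L)
  expect_identical(out$pos, 1e6)
})
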