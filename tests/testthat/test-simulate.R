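test_that("locus_config validates its inputs", {
  expect_error(locus_config(0), class = "sumtwas_config_error")
  expect_error(locus_config(3, maf_range = c(0.5, 0.1)),
               class = "sumtwas_config_error")
  expect_error(locus_config(3, maf_range = c(0, 0.5)),
               class = "sumtwas_config_error")
  expect_error(locus_config(3, ld_rho = 1), class = "sumtwas_config_error")
  expect_error(locus_config(3, ld_rho = -0.1), class = "sumtwas_config_error")
  expect_error(locus_config(3, positions = c(5, 4, 6)),
               class = "sumtwas_config_error")
})

test_that("genotype dosages are diploid counts with frequencies in range", {
  cfg <- locus_config(6, maf_range = c(0.1, 0.4), ld_rho = 0.3, seed = 11)
  panel <- simulate_genotypes(cfg, 4000, seed = 12)
  expect_true(all(panel$dosage %in% 0:2))
  freq <- colMeans(panel$dosage) / 2
  expect_true(all(abs(freq - cfg$maf) < 0.03))
  expect_true(all(freq >= 0.1 - 0.03 & freq <= 0.4 + 0.03))
})

test_that("independent loci show near-zero off-diagonal correlation", {
  cfg <- locus_config(6, ld_rho = 0, seed = 21)
  panel <- simulate_genotypes(cfg, 5000, seed = 22)
  cc <- cor(panel$dosage)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("adjacent-SNP dosage correlation hits the calibrated LD target", {
  # 10-replicate average against the generator's own target
  cfg <- locus_config(6, maf_range = c(0.45, 0.5), ld_rho = 0.8, seed = 31)
  adj <- vapply(1:10, function(i) {
    panel <- simulate_genotypes(cfg, 5000, seed = 31 + i)
    cc <- cor(panel$dosage)
    mean(diag(cc[-1, -ncol(cc), drop = FALSE]))
  }, numeric(1))
  expect_true(abs(mean(adj) - 0.8) < 0.03)
})

test_that("boundary MAF 0.5 yields frequency one-half at every SNP", {
  cfg <- locus_config(5, maf_range = c(0.5, 0.5), ld_rho = 0.2, seed = 41)
  panel <- simulate_genotypes(cfg, 5000, seed = 42)
  expect_true(all(abs(colMeans(panel$dosage) / 2 - 0.5) < 0.02))
})

test_that("identical seed gives identical genotypes, different seed differs", {
  cfg <- locus_config(5, seed = 51)
  a <- simulate_genotypes(cfg, 100, seed = 52)
  b <- simulate_genotypes(cfg, 100, seed = 52)
  c <- simulate_genotypes(cfg, 100, seed = 53)
  expect_identical(a$dosage, b$dosage)
  expect_false(identical(a$dosage, c$dosage))
})

test_that("architecture_config enforces the scenario contract", {
  expect_error(architecture_config(cis_h2 = 1.2), class = "sumtwas_config_error")
  expect_error(architecture_config(scenario = "Z"),
               class = "sumtwas_config_error")
  # null scenarios imply no expression-mediated trait effect
  expect_error(architecture_config(scenario = "A",
                                   trait_h2_via_expression = 0.1),
               class = "sumtwas_config_error")
  expect_s3_class(architecture_config(scenario = "G",
                                      trait_h2_via_expression = 0.1),
                  "architecture_config")
})

test_that("expression: null heritability gives no SNP correlation", {
  cfg <- locus_config(6, seed = 61)
  panel <- simulate_genotypes(cfg, 800, seed = 62)
  ex <- simulate_expression(panel, architecture_config(2, cis_h2 = 0),
                            seed = 63)
  rs <- abs(cor(panel$dosage, ex$expression))
  expect_true(all(rs < 0.12))
  expect_true(all(ex$truth$weight == 0))
})

test_that("expression: cis_h2 = 1 with one eQTL is collinear with its dosage", {
  cfg <- locus_config(6, maf_range = c(0.3, 0.5), seed = 71)
  panel <- simulate_genotypes(cfg, 300, seed = 72)
  ex <- simulate_expression(panel, architecture_config(1, cis_h2 = 1),
                            seed = 73)
  causal <- ex$truth$snp_id[ex$truth$weight != 0]
  expect_length(causal, 1)
  expect_equal(abs(cor(panel$dosage[, causal], ex$expression)), 1,
               tolerance = 1e-10)
})

test_that("expression: realized variance split equals cis_h2 exactly", {
  cfg <- locus_config(10, seed = 81)
  panel <- simulate_genotypes(cfg, 2000, seed = 82)
  for (h2 in c(0.1, 0.3, 0.7)) {
    ex <- simulate_expression(panel, architecture_config(3, cis_h2 = h2),
                              seed = 83)
    r2 <- summary(lm(ex$expression ~ ex$genetic_value))$r.squared
    expect_equal(r2, h2, tolerance = 1e-8)
    expect_equal(var(ex$expression), 1, tolerance = 1e-8)
  }
})

test_that("null scenarios produce traits independent of the genetic value", {
  for (scen in c("A", "B", "C", "D")) {
    st <- simulate_study(
      locus_config(6, seed = 91), architecture_config(2, cis_h2 = 0.4,
                                                      scenario = scen),
      n_ref = 200, n_gwas = 3000, seed = 92
    )
    xs <- scale(st$gwas$panel$dosage)
    g <- drop(xs %*% st$truth$weights$weight[
      match(colnames(xs), st$truth$weights$snp_id)])
    r <- if (sd(g) == 0) 0 else cor(g, st$gwas$trait)
    expect_lt(abs(r), 3.5 / sqrt(3000))
  }
})

test_that("scenario E mediation is detectable and vanishes at zero share", {
  hits <- vapply(1:20, function(i) {
    st <- simulate_study(
      locus_config(6, seed = 100 + i),
      architecture_config(2, cis_h2 = 0.4, trait_h2_via_expression = 0.05,
                          scenario = "E"),
      n_ref = 200, n_gwas = 5000, seed = 200 + i
    )
    xs <- scale(st$gwas$panel$dosage)
    g <- drop(xs %*% st$truth$weights$weight[
      match(colnames(xs), st$truth$weights$snp_id)])
    cor.test(g, st$gwas$trait)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  st0 <- simulate_study(
    locus_config(6, seed = 301),
    architecture_config(2, cis_h2 = 0.4, trait_h2_via_expression = 0,
                        scenario = "E"),
    n_ref = 200, n_gwas = 3000, seed = 302
  )
  xs <- scale(st0$gwas$panel$dosage)
  g <- drop(xs %*% st0$truth$weights$weight[
    match(colnames(xs), st0$truth$weights$snp_id)])
  expect_lt(abs(cor(g, st0$gwas$trait)), 3.5 / sqrt(3000))
})

test_that("pleiotropy and linkage scenarios couple the trait to the locus", {
  for (scen in c("G", "H")) {
    st <- simulate_study(
      locus_config(6, maf_range = c(0.2, 0.5), ld_rho = 0.6, seed = 401),
      architecture_config(2, cis_h2 = 0.4, trait_h2_via_expression = 0.05,
                          scenario = scen),
      n_ref = 200, n_gwas = 5000, seed = 402
    )
    expect_gt(max(abs(st$sumstats$z)), 4)
  }
})

test_that("summary z-scores are calibrated under the null", {
  # pooled independent SNPs across replicate cohorts
  zs <- unlist(lapply(1:20, function(i) {
    cfg <- locus_config(50, maf_range = c(0.2, 0.5), ld_rho = 0,
                        seed = 500 + i)
    panel <- simulate_genotypes(cfg, 500, seed = 600 + i)
    trait <- with(list(), {set.seed(700 + i); rnorm(500)})
    compute_gwas_summary(panel, trait)$z
  }))
  expect_length(zs, 1000)
  expect_true(abs(mean(abs(zs) > 1.96) - 0.05) < 0.02)
})

test_that("summary z-scores match sqrt(n) * correlation for modest effects", {
  cfg <- locus_config(5, maf_range = c(0.3, 0.5), seed = 801)
  panel <- simulate_genotypes(cfg, 10000, seed = 802)
  set.seed(803)
  trait <- drop(0.1 * scale(panel$dosage[, 3]) + rnorm(10000))
  ss <- compute_gwas_summary(panel, trait)
  r <- cor(panel$dosage[, 3], trait)
  expect_equal(ss$z[3], sqrt(10000) * r, tolerance = 0.02)
})

test_that("a perfectly associated SNP has z growing as sqrt(n)", {
  cfg <- locus_config(3, maf_range = c(0.4, 0.5), seed = 811)
  p1 <- simulate_genotypes(cfg, 1000, seed = 812)
  p2 <- simulate_genotypes(cfg, 4000, seed = 813)
  z1 <- compute_gwas_summary(p1, p1$dosage[, 2])$z[2]
  z2 <- compute_gwas_summary(p2, p2$dosage[, 2])$z[2]
  expect_equal(z2 / z1, 2, tolerance = 0.01)
})

test_that("zero-variance SNPs are excluded from summaries with a warning", {
  cfg <- locus_config(4, seed = 821)
  panel <- simulate_genotypes(cfg, 200, seed = 822)
  panel$dosage[, 2] <- 1L
  set.seed(823)
  trait <- rnorm(200)
  expect_warning(ss <- compute_gwas_summary(panel, trait), "zero-variance")
  expect_equal(nrow(ss), 3)
  expect_false(cfg$snp_id[2] %in% ss$snp_id)
})

test_that("simulate_study is reproducible from a single seed", {
  a <- simulate_study(seed = 901, n_ref = 50, n_gwas = 60)
  b <- simulate_study(seed = 901, n_ref = 50, n_gwas = 60)
  expect_identical(a$reference$panel$dosage, b$reference$panel$dosage)
  expect_identical(a$sumstats$z, b$sumstats$z)
  expect_identical(a$gwas$trait, b$gwas$trait)
})
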