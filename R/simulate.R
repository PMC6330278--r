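#' Configure a cis locus for simulation
#'
#' Fixes the population parameters of a simulated cis locus: per-SNP minor
#' allele frequencies (drawn uniformly within `maf_range`), base-pair
#' positions, allele labels, and the latent adjacent-SNP correlations that
#' deliver an AR(1)-type dosage LD profile with adjacent correlation
#' `ld_rho`. Genotypes are later drawn per cohort from this shared
#' configuration, so a reference panel and a GWAS cohort simulated from the
#' same `locus_config` share SNP identity, allele coding and LD structure.
#'
#' Haplotypes are generated by thresholding a latent AR(1) Gaussian at the
#' MAF quantile and an individual's dosage is the sum of two independent
#' haplotypes. Thresholding attenuates correlation, so the latent adjacent
#' correlation is calibrated numerically (per adjacent pair, given both MAFs)
#' such that the allele-indicator — and hence dosage — correlation equals
#' `ld_rho`. Correlation between SNPs of unequal allele frequency is bounded
#' above (the usual allele-frequency bound on r); pairs whose bound falls
#' below `ld_rho` receive the maximum attainable correlation instead.
#'
#' @param n_snps Number of SNPs at the locus (>= 1).
#' @param maf_range Length-2 numeric, lower/upper minor allele frequency in
#'   (0, 0.5].
#' @param ld_rho Target adjacent-SNP dosage correlation in `[0, 1)`.
#' @param chr Chromosome label.
#' @param positions Optional strictly increasing base-pair positions
#'   (default: evenly spaced, 5 kb apart, starting at 1e6).
#' @param seed Seed fixing the locus parameters (MAF draw, allele labels).
#' @return An object of class `locus_config`.
#' @export
#' @examples
#' cfg <- locus_config(n_snps = 5, ld_rho = 0.6, seed = 1)
#' panel <- simulate_genotypes(cfg, n_individuals = 100, seed = 2)
locus_config <- function(n_snps, maf_range = c(0.05, 0.5), ld_rho = 0.5,
                         chr = "1", positions = NULL, seed = NULL) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1) {
    abort("`n_snps` must be a count >= 1.", class = "sumtwas_config_error")
  }
  n_snps <- as.integer(n_snps)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must be ordered and within (0, 0.5].",
          class = "sumtwas_config_error")
  }
  if (!is.numeric(ld_rho) || length(ld_rho) != 1L || ld_rho < 0 || ld_rho >= 1) {
    abort("`ld_rho` must be in [0, 1).", class = "sumtwas_config_error")
  }
  if (is.null(positions)) {
    positions <- 1e6 + 5000 * (seq_len(n_snps) - 1L)
  }
  if (length(positions) != n_snps || is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing, one per SNP.",
          class = "sumtwas_config_error")
  }
  pars <- with_seed(seed, {
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    # non-strand-ambiguous allele pairs only
    pair <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"), ncol = 2,
                   byrow = TRUE)[sample.int(4L, n_snps, replace = TRUE), ,
                                 drop = FALSE]
    list(maf = maf, a1 = pair[, 1], a2 = pair[, 2])
  })
  latent <- if (n_snps > 1L) {
    vapply(seq_len(n_snps - 1L), function(j) {
      calibrate_latent_rho(ld_rho, pars$maf[j], pars$maf[j + 1L])
    }, numeric(1))
  } else {
    numeric(0)
  }
  structure(
    list(
      n_snps = n_snps, maf = pars$maf, ld_rho = ld_rho,
      latent_rho = latent, chr = as.character(chr), positions = positions,
      snp_id = sprintf("snp%03d_%s", seq_len(n_snps), as.character(chr)),
      a1 = pars$a1, a2 = pars$a2, maf_range = maf_range, seed = seed
    ),
    class = "locus_config"
  )
}

# Correlation of two threshold indicators 1{Z1 < qnorm(p1)}, 1{Z2 < qnorm(p2)}
# for bivariate standard normal (Z1, Z2) with correlation r.
indicator_corr <- function(r, p1, p2) {
  if (r == 0) return(0)
  t1 <- qnorm(p1); t2 <- qnorm(p2)
  joint <- integrate(function(z) pnorm((t2 - r * z) / sqrt(1 - r^2)) * dnorm(z),
                     lower = -Inf, upper = t1, rel.tol = 1e-9)$value
  (joint - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent Gaussian correlation that yields indicator correlation `target`.
# Dosage correlation between SNPs of unequal allele frequency is bounded
# above (the classic allele-frequency bound on r); unattainable targets get
# the frequency-bounded maximum (latent correlation -> 1).
calibrate_latent_rho <- function(target, p1, p2) {
  if (target == 0) return(0)
  upper <- 0.99995
  if (indicator_corr(upper, p1, p2) <= target) {
    return(upper)
  }
  uniroot(function(r) indicator_corr(r, p1, p2) - target,
          lower = target, upper = upper, tol = 1e-7)$root
}

# One haplotype block: latent AR chain thresholded at the MAF quantile.
simulate_haplotypes <- function(n, maf, latent_rho) {
  m <- length(maf)
  z <- matrix(rnorm(n * m), n, m)
  if (m > 1L) {
    for (j in 2:m) {
      r <- latent_rho[j - 1L]
      z[, j] <- r * z[, j - 1L] + sqrt(1 - r^2) * z[, j]
    }
  }
  sweep(z, 2L, qnorm(maf), `<`) * 1L
}

#' Simulate a genotype dosage panel at a configured locus
#'
#' Draws `n_individuals` diploid dosages (0/1/2) at the locus, as the sum of
#' two thresholded latent-Gaussian haplotypes, so that per-SNP allele
#' frequencies match the configured MAFs and adjacent-SNP dosage correlation
#' matches the configured `ld_rho` in expectation.
#'
#' @param cfg A [locus_config()].
#' @param n_individuals Cohort size (>= 2).
#' @param seed Optional seed for this draw.
#' @return A `genotype_panel`: list with `dosage` (individuals x SNPs integer
#'   matrix, columns named by SNP id) and `snps` (tibble with snp_id, chr,
#'   pos, a1, a2, maf).
#' @export
simulate_genotypes <- function(cfg, n_individuals, seed = NULL) {
  stopifnot(inherits(cfg, "locus_config"))
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    abort("`n_individuals` must be >= 2.", class = "sumtwas_config_error")
  }
  n <- as.integer(n_individuals)
  dosage <- with_seed(seed, {
    simulate_haplotypes(n, cfg$maf, cfg$latent_rho) +
      simulate_haplotypes(n, cfg$maf, cfg$latent_rho)
  })
  colnames(dosage) <- cfg$snp_id
  structure(
    list(
      dosage = dosage,
      snps = tibble::tibble(
        snp_id = cfg$snp_id, chr = cfg$chr, pos = cfg$positions,
        a1 = cfg$a1, a2 = cfg$a2, maf = cfg$maf
      ),
      cfg = cfg
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs (chr %s)\n",
              nrow(x$dosage), ncol(x$dosage), x$cfg$chr))
  invisible(x)
}

#' Configure a cis-eQTL architecture and causal scenario
#'
#' @param n_causal_eqtl Number of causal cis-eQTLs.
#' @param cis_h2 Proportion of expression variance explained by the causal
#'   cis SNPs, in `[0, 1]`.
#' @param trait_h2_via_expression Trait-variance share of the genetic
#'   expression component (scenarios E-H), in `[0, 1]`.
#' @param scenario One of `"A"`..`"H"`. A-D are null modes (trait independent
#'   of the gene's genetic expression component); E-H are alternatives. See
#'   the methods vignette for the exact generative definitions.
#' @param direct_snp_effect Trait-variance share of non-mediated genetics in
#'   scenarios B/G/H (unlinked background, pleiotropy, linkage).
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(n_causal_eqtl = 1L, cis_h2 = 0.3,
                                trait_h2_via_expression = 0,
                                scenario = "E", direct_snp_effect = 0.1) {
  assert_prob(cis_h2, "cis_h2")
  assert_prob(trait_h2_via_expression, "trait_h2_via_expression")
  assert_prob(direct_snp_effect, "direct_snp_effect")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% LETTERS[1:8]) {
    abort("`scenario` must be one of \"A\"..\"H\".",
          class = "sumtwas_config_error")
  }
  if (scenario %in% c("A", "B", "C", "D") && trait_h2_via_expression != 0) {
    abort("null scenarios A-D imply trait_h2_via_expression = 0.",
          class = "sumtwas_config_error")
  }
  structure(
    list(n_causal_eqtl = as.integer(n_causal_eqtl), cis_h2 = cis_h2,
         trait_h2_via_expression = trait_h2_via_expression,
         scenario = scenario, direct_snp_effect = direct_snp_effect),
    class = "architecture_config"
  )
}

#' Simulate gene expression with a sparse cis-eQTL architecture
#'
#' Picks `n_causal_eqtl` causal SNPs, draws their effects i.i.d. normal on
#' the standardized dosage scale, and rescales the genetic value and an
#' orthogonalized noise component so that the realized in-sample variance
#' split is exactly `cis_h2` / `1 - cis_h2` (removing replicate-to-replicate
#' heritability jitter). The returned truth weights are the rescaled effects.
#'
#' @param panel A `genotype_panel`.
#' @param arch An [architecture_config()].
#' @param seed Optional seed.
#' @return List with `expression` (unit-variance numeric vector),
#'   `truth` (tibble snp_id/weight over all locus SNPs; zero off the causal
#'   set), and `genetic_value` (the causal genetic component).
#' @export
simulate_expression <- function(panel, arch, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(arch, "architecture_config"))
  m <- ncol(panel$dosage)
  n <- nrow(panel$dosage)
  if (arch$n_causal_eqtl > m) {
    abort("n_causal_eqtl exceeds the number of SNPs at the locus.",
          class = "sumtwas_config_error")
  }
  h2 <- if (arch$scenario == "C") 0 else arch$cis_h2
  with_seed(seed, {
    xs <- standardize_cols(panel$dosage, zero_as = "zero")
    w <- numeric(m)
    g <- numeric(n)
    if (h2 > 0 && arch$n_causal_eqtl > 0) {
      causal <- sort(sample.int(m, arch$n_causal_eqtl))
      beta <- rnorm(arch$n_causal_eqtl)
      g_raw <- drop(xs[, causal, drop = FALSE] %*% beta)
      sc <- sqrt(h2) / sd(g_raw)
      g <- (g_raw - mean(g_raw)) * sc
      w[causal] <- beta * sc
    }
    e <- numeric(n)
    if (h2 < 1) {
      e_raw <- rnorm(n)
      if (h2 > 0) {                 # orthogonalize noise against the signal
        e_raw <- e_raw - g * sum(e_raw * g) / sum(g * g)
      }
      e <- (e_raw - mean(e_raw)) * sqrt(1 - h2) / sd(e_raw - mean(e_raw))
    }
    list(
      expression = g + e,
      truth = tibble::tibble(snp_id = panel$snps$snp_id, weight = w),
      genetic_value = g
    )
  })
}

#' Simulate a trait under one of the eight causal scenarios
#'
#' Scenarios A-D construct a trait independent of the gene's genetic
#' expression component (the TWAS null); E-H tie the trait to the locus with
#' trait-variance share `trait_h2_via_expression` (E: via total latent
#' expression; F: via the genetic component only; G: pleiotropy — direct
#' effects at the causal eQTLs; H: linkage — a direct effect at a correlated
#' non-causal SNP). Genetic components are rescaled so realized variance
#' shares are exact in-sample.
#'
#' @param gwas_panel `genotype_panel` of the GWAS cohort.
#' @param truth Truth-weight tibble from [simulate_expression()] (snp_id,
#'   weight), defining the gene's genetic expression component.
#' @param arch An [architecture_config()].
#' @param seed Optional seed.
#' @return Numeric trait vector (unit variance).
#' @export
simulate_trait <- function(gwas_panel, truth, arch, seed = NULL) {
  stopifnot(inherits(gwas_panel, "genotype_panel"),
            inherits(arch, "architecture_config"))
  n <- nrow(gwas_panel$dosage)
  with_seed(seed, {
    xs <- standardize_cols(gwas_panel$dosage, zero_as = "zero")
    w <- truth$weight[match(colnames(xs), truth$snp_id)]
    g <- drop(xs %*% w)                       # genetic expression component
    h2g <- if (arch$cis_h2 > 0) arch$cis_h2 else 1
    scen <- arch$scenario
    h2v <- arch$trait_h2_via_expression
    add_noise <- function(signal, share) {
      if (share <= 0) return(standardize_vec(rnorm(n)))
      s <- (signal - mean(signal)) * sqrt(share) / sd(signal)
      s + standardize_vec(rnorm(n)) * sqrt(1 - share)
    }
    switch(scen,
      A = standardize_vec(rnorm(n)),
      B = add_noise(rnorm(n), arch$direct_snp_effect),  # unlinked background
      C = standardize_vec(rnorm(n)),
      D = {  # environmental expression-trait confounding, no genetics
        env <- rnorm(n)                       # cohort's env. expression part
        add_noise(env, arch$direct_snp_effect)
      },
      E = {
        if (h2v == 0 || all(w == 0)) standardize_vec(rnorm(n)) else {
          e_lat <- rnorm(n) * sqrt(1 - h2g)   # latent expression noise part
          expr_lat <- g + e_lat
          # scale so the *genetic* part contributes share h2v
          b <- sqrt(h2v) / sd(g)
          tot <- b^2 * var(expr_lat)
          if (tot >= 1) {
            abort("trait_h2_via_expression too large for this cis_h2.",
                  class = "sumtwas_config_error")
          }
          b * (expr_lat - mean(expr_lat)) + standardize_vec(rnorm(n)) * sqrt(1 - tot)
        }
      },
      F = if (h2v == 0 || all(w == 0)) standardize_vec(rnorm(n)) else
            add_noise(g, h2v),
      G = {
        causal <- which(w != 0)
        if (length(causal) == 0 || h2v == 0) standardize_vec(rnorm(n)) else {
          gamma <- rnorm(length(causal))
          add_noise(drop(xs[, causal, drop = FALSE] %*% gamma), h2v)
        }
      },
      H = {
        causal <- which(w != 0)
        if (length(causal) == 0 || h2v == 0) standardize_vec(rnorm(n)) else {
          ld <- cor(xs)
          cand <- setdiff(seq_len(ncol(xs)), causal)
          if (length(cand) == 0) {
            abort("scenario H needs at least one non-causal SNP.",
                  class = "sumtwas_config_error")
          }
          # the non-causal SNP in strongest LD with any causal eQTL
          j <- cand[which.max(apply(abs(ld[cand, causal, drop = FALSE]), 1, max))]
          add_noise(xs[, j], h2v)
        }
      },
      abort(sprintf("unknown scenario '%s'.", scen),
            class = "sumtwas_config_error")
    )
  })
}

#' Compute per-SNP GWAS summary z-scores
#'
#' Marginal association of the (internally standardized) trait with each
#' (internally standardized) SNP dosage: z is the regression coefficient over
#' its standard error, i.e. `r * sqrt((n - 2) / (1 - r^2))` for the sample
#' correlation r. Under a null trait z is standard normal (asymptotically).
#' Zero-variance SNPs are excluded with a warning.
#'
#' @param gwas_panel `genotype_panel` of the GWAS cohort.
#' @param trait Numeric trait vector, one value per individual.
#' @return A `gwas_summary` tibble: snp_id, chr, pos, a1, a2, z.
#' @export
compute_gwas_summary <- function(gwas_panel, trait) {
  stopifnot(inherits(gwas_panel, "genotype_panel"))
  if (length(trait) != nrow(gwas_panel$dosage)) {
    abort("trait length must match the cohort size.",
          class = "sumtwas_config_error")
  }
  xs <- standardize_cols(gwas_panel$dosage, zero_as = "drop")
  ys <- standardize_vec(trait)
  n <- length(ys)
  r <- drop(crossprod(xs, ys)) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  # perfect association makes the t-statistic unbounded; floor the residual
  # variance so z stays finite and still scales as sqrt(n)
  z <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  out <- dplyr::inner_join(
    gwas_panel$snps,
    tibble::tibble(snp_id = colnames(xs), z = unname(z)),
    by = "snp_id"
  )
  out <- dplyr::select(out, "snp_id", "chr", "pos", "a1", "a2", "z")
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Simulate a complete two-cohort TWAS study at one locus
#'
#' Draws a reference panel (genotypes + expression) and an independent GWAS
#' cohort (genotypes + trait + summary z-scores) from a shared locus
#' configuration, under one causal scenario. The truth record (causal SNPs,
#' true weights, scenario) suffices to score recovery downstream.
#'
#' @param cfg A [locus_config()]; created with defaults if `NULL`.
#' @param arch An [architecture_config()].
#' @param n_ref Reference-panel size (default 500).
#' @param n_gwas GWAS cohort size (default 5000).
#' @param gene,tissue Labels carried through to results.
#' @param seed Single seed from which all draws flow.
#' @return A `simulated_study` list: `reference` (panel, expression),
#'   `gwas` (panel, trait), `sumstats`, `truth`, `arch`, `cfg`.
#' @export
simulate_study <- function(cfg = NULL, arch = architecture_config(),
                           n_ref = 500, n_gwas = 5000,
                           gene = "GENE1", tissue = "Tissue1", seed = NULL) {
  with_seed(seed, {
    if (is.null(cfg)) cfg <- locus_config(n_snps = 10L)
    ref_panel <- simulate_genotypes(cfg, n_ref)
    expr <- simulate_expression(ref_panel, arch)
    gwas_panel <- simulate_genotypes(cfg, n_gwas)
    trait <- simulate_trait(gwas_panel, expr$truth, arch)
    sumstats <- compute_gwas_summary(gwas_panel, trait)
    structure(
      list(
        reference = list(panel = ref_panel, expression = expr$expression),
        gwas = list(panel = gwas_panel, trait = trait),
        sumstats = sumstats,
        truth = list(weights = expr$truth,
                     causal_snps = expr$truth$snp_id[expr$truth$weight != 0],
                     scenario = arch$scenario),
        arch = arch, cfg = cfg, gene = gene, tissue = tissue
      ),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> gene %s, tissue %s, scenario %s: ref n=%d, GWAS n=%d, %d SNPs\n",
    x$gene, x$tissue, x$arch$scenario, nrow(x$reference$panel$dosage),
    nrow(x$gwas$panel$dosage), x$cfg$n_snps))
  invisible(x)
}
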