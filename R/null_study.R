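#' Simulate a global-null multi-tissue TWAS study, batched
#'
#' Generates a full scenario-A (global null: every trait draw is pure
#' environmental noise, independent of all genotypes) multi-tissue study and
#' pushes it through the summary TWAS machinery: per tissue, a reference
#' panel with heritable expression per gene trains marginal ImpG weights,
#' and each replicate redraws the GWAS trait on a fixed genotype cohort
#' (conditional-on-genotypes design) to produce per-gene summary z-scores
#' and imputed association p-values.
#'
#' All loci share one MAF and one adjacent-LD value so genotypes for
#' thousands of genes can be simulated as a single block-AR matrix; this is
#' a calibration instrument for error-rate studies, not a realistic
#' genome.
#'
#' @param n_genes Genes per tissue.
#' @param n_replicates Trait redraws.
#' @param tissues Character vector of tissue labels (default the five
#'   packaged panels, [ad_tissues()]).
#' @param n_ref,n_gwas Cohort sizes.
#' @param n_snps SNPs per gene locus.
#' @param maf Shared minor allele frequency.
#' @param ld_rho Shared adjacent-SNP dosage LD.
#' @param cis_h2 Expression cis-heritability used when training weights.
#' @param impg_lambda Ridge for the ImpG weight solve.
#' @param seed Seed for the whole study.
#' @return Tibble: replicate, tissue, gene, z_score, p_value.
#' @export
simulate_null_study <- function(n_genes = 2000, n_replicates = 100,
                                tissues = ad_tissues(), n_ref = 200,
                                n_gwas = 1000, n_snps = 4, maf = 0.3,
                                ld_rho = 0.5, cis_h2 = 0.3,
                                impg_lambda = 0.1, seed = NULL) {
  with_seed(seed, {
    latent <- if (n_snps > 1) {
      rep(calibrate_latent_rho(ld_rho, maf, maf), n_snps - 1L)
    } else {
      numeric(0)
    }
    m_total <- n_genes * n_snps
    gene_of <- rep(seq_len(n_genes), each = n_snps)
    mafs <- rep(maf, n_snps)

    # block-AR haplotypes for all genes at once: run the AR chain within
    # each block position across genes simultaneously
    sim_block_geno <- function(n) {
      z1 <- matrix(rnorm(n * m_total), n, m_total)
      z2 <- matrix(rnorm(n * m_total), n, m_total)
      if (n_snps > 1) {
        for (j in 2:n_snps) {
          idx <- which(((seq_len(m_total) - 1L) %% n_snps) + 1L == j)
          r <- latent[j - 1L]
          z1[, idx] <- r * z1[, idx - 1L] + sqrt(1 - r^2) * z1[, idx]
          z2[, idx] <- r * z2[, idx - 1L] + sqrt(1 - r^2) * z2[, idx]
        }
      }
      thr <- qnorm(maf)
      (z1 < thr) + (z2 < thr)
    }

    res <- purrr::map_dfr(tissues, function(tis) {
      # reference panel: expression and ImpG weights per gene
      xref <- standardize_cols(sim_block_geno(n_ref))
      wvec <- numeric(m_total)
      denom <- numeric(n_genes)
      xg <- standardize_cols(sim_block_geno(n_gwas))
      for (g in seq_len(n_genes)) {
        cols <- which(gene_of == g)
        xr <- xref[, cols, drop = FALSE]
        causal <- sample(seq_len(n_snps), 1L)
        expr <- sqrt(cis_h2) * xr[, causal] + sqrt(1 - cis_h2) * rnorm(n_ref)
        ses <- drop(crossprod(xr, expr)) / (n_ref - 1) / sd(expr)
        sss <- crossprod(xr) / (n_ref - 1)
        w <- drop(solve(sss + diag(impg_lambda, n_snps), ses))
        wvec[cols] <- w
        sg <- crossprod(xg[, cols, drop = FALSE]) / (n_gwas - 1)
        denom[g] <- drop(crossprod(w, sg %*% w))
      }
      purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
        y <- standardize_vec(rnorm(n_gwas))
        r <- drop(crossprod(xg, y)) / (n_gwas - 1)
        z <- r * sqrt((n_gwas - 2) / pmax(1 - r^2, .Machine$double.eps))
        num <- as.numeric(rowsum(wvec * z, gene_of))
        zt <- num / sqrt(denom)
        tibble::tibble(replicate = rep_i, tissue = tis,
                       gene = sprintf("gene%05d", seq_len(n_genes)),
                       z_score = zt, p_value = zscore_to_pvalue(zt))
      })
    })
    res
  })
}

#' Empirical false-discovery proportion of per-tissue BH on a null study
#'
#' Applies [benjamini_hochberg()] within each tissue of each replicate of a
#' [simulate_null_study()] table and returns the per-(replicate, tissue)
#' false-discovery proportion; under the global null every rejection is
#' false, so FDP is 1 if the tissue family rejects anything, else 0.
#'
#' @param null_tbl Output of [simulate_null_study()].
#' @param alpha FDR level.
#' @return Tibble: replicate, tissue, n_rejected, fdp.
#' @export
null_study_fdp <- function(null_tbl, alpha = 0.05) {
  null_tbl |>
    dplyr::group_by(.data$replicate, .data$tissue) |>
    dplyr::summarise(
      n_rejected = sum(benjamini_hochberg(.data$p_value,
                                          alpha = alpha)$significant),
      .groups = "drop"
    ) |>
    dplyr::mutate(fdp = as.numeric(.data$n_rejected > 0))
}
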