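# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# A weight set with explicit SNP metadata, for harmonization tests.
make_weight_set <- function(weights, a1 = rep("A", length(weights)),
                            a2 = rep("G", length(weights)),
                            snp_id = sprintf("rs%d", seq_along(weights)),
                            gene = "GENE1", tissue = "TissueX",
                            model = "lasso", cv_r2 = 0.5,
                            chr = "1", untestable = FALSE) {
  sumtwas:::new_weight_set(
    gene = gene, tissue = tissue, model = model, cv_r2 = cv_r2,
    snps = tibble::tibble(snp_id = snp_id, chr = chr,
                          pos = seq_along(weights) * 1000, a1 = a1, a2 = a2,
                          weight = weights),
    untestable = untestable
  )
}

make_sumstats <- function(z, a1 = rep("A", length(z)),
                          a2 = rep("G", length(z)),
                          snp_id = sprintf("rs%d", seq_along(z)), chr = "1") {
  out <- tibble::tibble(snp_id = snp_id, chr = chr,
                        pos = seq_along(z) * 1000, a1 = a1, a2 = a2, z = z)
  class(out) <- c("gwas_summary", class(out))
  out
}

# A small study with signal, shared by several tests.
make_signal_study <- function(seed = 101, n_ref = 300, n_gwas = 2000,
                              scenario = "E", h2v = 0.05) {
  simulate_study(
    locus_config(8, maf_range = c(0.2, 0.5), ld_rho = 0.4, seed = seed),
    architecture_config(2, cis_h2 = 0.5, trait_h2_via_expression = h2v,
                        scenario = scenario),
    n_ref = n_ref, n_gwas = n_gwas, seed = seed + 1
  )
}

# Brute-force O(m^2) step-up rule, straight from its definition: for every
# k check P_(k) <= (k/m) alpha, take the largest such k, reject ranks 1..k.
bh_bruteforce_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0L
  for (k in seq_len(m)) {
    if (p[ord][k] <= k / m * alpha) k_star <- k
  }
  rejected <- logical(m)
  if (k_star > 0) rejected[ord[seq_len(k_star)]] <- TRUE
  rejected
}
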