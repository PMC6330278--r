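#' Read and write GWAS summary statistics
#'
#' Tab-separated with header `SNP CHR BP A1 A2 Z` (case-insensitive); A1 is
#' the effect allele of Z.
#'
#' @param path File path.
#' @return A `gwas_summary` tibble (snp_id, chr, pos, a1, a2, z).
#' @export
read_gwas_summary <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  want <- c(snp = "snp_id", chr = "chr", bp = "pos", a1 = "a1", a2 = "a2",
            z = "z")
  missing <- setdiff(names(want), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("summary file lacks column(s): %s",
                  paste(toupper(missing), collapse = ", ")),
          class = "sumtwas_input_error")
  }
  out <- tibble::tibble(
    snp_id = as.character(raw$snp), chr = as.character(raw$chr),
    pos = as.numeric(raw$bp), a1 = toupper(raw$a1), a2 = toupper(raw$a2),
    z = as.numeric(raw$z)
  )
  if (anyDuplicated(out$snp_id)) {
    abort("duplicate SNP ids in summary file.", class = "sumtwas_input_error")
  }
  if (any(!is.finite(out$z))) {
    abort("non-finite z-scores in summary file.", class = "sumtwas_input_error")
  }
  class(out) <- c("gwas_summary", class(out))
  out
}

#' @rdname read_gwas_summary
#' @param sumstats A `gwas_summary` tibble.
#' @export
write_gwas_summary <- function(sumstats, path) {
  out <- tibble::tibble(SNP = sumstats$snp_id, CHR = sumstats$chr,
                        BP = sumstats$pos, A1 = sumstats$a1,
                        A2 = sumstats$a2, Z = sumstats$z)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated study to plain-text files
#'
#' Writes, per cohort, a dosage matrix (individuals x SNPs, tab-separated
#' with SNP-id header) and a shared SNP map (snp_id, chr, pos, a1, a2); the
#' reference expression as a long table (gene, tissue, individual, value);
#' and the GWAS summaries as `SNP/CHR/BP/A1/A2/Z`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage <- function(panel, path) {
    readr::write_tsv(tibble::as_tibble(as.data.frame(panel$dosage)), path,
                     progress = FALSE)
  }
  write_dosage(study$reference$panel, file.path(dir, "reference_dosage.tsv"))
  write_dosage(study$gwas$panel, file.path(dir, "gwas_dosage.tsv"))
  readr::write_tsv(study$reference$panel$snps, file.path(dir, "snp_map.tsv"),
                   progress = FALSE)
  expr <- tibble::tibble(
    gene = study$gene, tissue = study$tissue,
    individual = seq_along(study$reference$expression),
    value = study$reference$expression
  )
  readr::write_tsv(expr, file.path(dir, "expression.tsv"), progress = FALSE)
  write_gwas_summary(study$sumstats, file.path(dir, "gwas_sumstats.tsv"))
  readr::write_tsv(study$truth$weights, file.path(dir, "truth_weights.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read and write expression-prediction weight files
#'
#' TSV with comment header lines `#gene=`, `#tissue=`, `#model=`, `#cv_r2=`
#' and columns snp_id, chr, pos, a1, a2, weight.
#'
#' @param ws A `weight_set` (see [train_weights()]).
#' @param path File path.
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "weight_set"))
  hdr <- sprintf("#%s=%s", c("gene", "tissue", "model", "cv_r2"),
                 c(ws$gene, ws$tissue, ws$model, format(ws$cv_r2, digits = 10)))
  writeLines(hdr, path)
  readr::write_tsv(ws$snps, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  snps <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  new_weight_set(
    gene = meta[["gene"]], tissue = meta[["tissue"]], model = meta[["model"]],
    cv_r2 = as.numeric(meta[["cv_r2"]]), snps = tibble::as_tibble(snps)
  )
}

#' Read an LD matrix from a square text file
#'
#' Tab-separated square matrix with a SNP-id header row; validated to be
#' symmetric with unit diagonal.
#'
#' @param path File path.
#' @return Correlation matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE))
  rownames(raw) <- colnames(raw)
  validate_ld(raw)
}

#' @rdname read_ld_matrix
#' @param ld LD matrix to write.
#' @export
write_ld_matrix <- function(ld, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(ld)), path,
                   progress = FALSE)
  invisible(path)
}
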