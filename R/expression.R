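#' Configuration for expression simulation
#'
#' @param cohort_size Reference cohort size (default 274 samples).
#' @param log_mean_sd Standard deviation of per-gene log TPM means.
#' @param log_sd Within-gene log-normal sd.
#' @param cn_effect Apply a (CN / 2) multiplier to tumor TPM of genes on
#'   non-diploid segments.
#' @param fusion_multiplier Overexpression multiplier applied to fusion
#'   partner genes in the tumor sample.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(cohort_size = 274, log_mean_sd = 1.5, log_sd = 0.4,
                          cn_effect = TRUE, fusion_multiplier = 4) {
  if (cohort_size < 2) stop_config("cohort_size must be >= 2")
  structure(list(cohort_size = as.integer(cohort_size),
                 log_mean_sd = log_mean_sd, log_sd = log_sd,
                 cn_effect = cn_effect, fusion_multiplier = fusion_multiplier),
            class = "cohort_config")
}

#' Simulate tumor expression and a reference cohort
#'
#' Per-gene baseline expression is log-normal; the reference cohort is drawn
#' from the same distribution.  The tumor sample's TPM for genes on
#' copy-number-altered segments is multiplied by CN/2, and fusion partner
#' genes receive an overexpression multiplier, so copy-number- and SV-linked
#' expression biomarkers are recoverable downstream.
#'
#' @param genome A `synthetic_genome`.
#' @param truth A `tumor_truth`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return list with `tumor_tpm` (named numeric vector), `reference` (genes x
#'   cohort matrix) and `gene_cn` (data.frame of per-gene tumor total CN).
#' @export
simulate_expression <- function(genome, truth, config = cohort_config(),
                                seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  genes <- genome$genes
  if (nrow(genes) == 0) stop_config("genome has no genes")
  with_seed(seed, {
    mu <- stats::rnorm(nrow(genes), mean = 3, sd = config$log_mean_sd)
    names(mu) <- genes$gene
    ref <- matrix(exp(stats::rnorm(nrow(genes) * config$cohort_size,
                                   mean = rep(mu, config$cohort_size),
                                   sd = config$log_sd)),
                  nrow = nrow(genes),
                  dimnames = list(genes$gene,
                                  sprintf("REF%03d", seq_len(config$cohort_size))))
    tumor <- exp(stats::rnorm(nrow(genes), mean = mu, sd = config$log_sd))
    names(tumor) <- genes$gene

    mid <- floor((genes$start + genes$end) / 2)
    cn <- cn_at(truth$cn_segments, genes$contig, mid + 1)
    if (config$cn_effect) tumor <- tumor * cn$total_cn / 2

    fus <- truth$variants[truth$variants$class == "fusion", , drop = FALSE]
    partners <- unique(c(fus$gene5, fus$gene3))
    partners <- partners[!is.na(partners)]
    tumor[names(tumor) %in% partners] <-
      tumor[names(tumor) %in% partners] * config$fusion_multiplier

    list(tumor_tpm = tumor, reference = ref,
         gene_cn = data.frame(gene = genes$gene, total_cn = cn$total_cn))
  })
}

#' Write a TPM table as TSV
#' @param mat Matrix or named vector of TPM values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm_tsv <- function(mat, path) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1,
                                       dimnames = list(names(mat), "TPM"))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
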