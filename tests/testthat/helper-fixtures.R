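# Shared fixtures, built once per test run.  A small two-contig genome keeps
# context-index construction fast while leaving every trinucleotide context
# with thousands of placeable loci.

.fixtures <- new.env(parent = emptyenv())

fixture_genome <- function() {
  if (is.null(.fixtures$genome))
    .fixtures$genome <- simulate_genome(
      genome_config(contigs = c(chr1 = 2e5, chr2 = 2e5), n_genes = 20),
      seed = 42)
  .fixtures$genome
}

# biclonal tumor used by several modules (CCF 1.0 / 0.4)
fixture_tumor <- function() {
  if (is.null(.fixtures$tumor))
    .fixtures$tumor <- simulate_tumor(
      fixture_genome(),
      tumor_config(purity = 0.8,
                   clones = data.frame(clone_id = c("C1", "C2"),
                                       parent_id = c(NA, "C1"),
                                       ccf = c(1, 0.4)),
                   n_snv = c(200, 200), n_indel = c(20, 10),
                   n_sv = 6, n_fusion = 2, n_cn_events = 2),
      seed = 7)
  .fixtures$tumor
}

# flat clonal diploid tumor at purity 1 (null scenarios, power checks,
# cfDNA VAF-density estimation, which in real data sees thousands of SNVs)
fixture_clonal_tumor <- function() {
  if (is.null(.fixtures$clonal))
    .fixtures$clonal <- simulate_tumor(
      fixture_genome(),
      tumor_config(purity = 1,
                   clones = data.frame(clone_id = "C1", parent_id = NA,
                                       ccf = 1),
                   n_snv = 2000, n_indel = 0, n_sv = 0, n_fusion = 0,
                   signature_mix = c(SBS_A = 1), n_cn_events = 0),
      seed = 9)
  .fixtures$clonal
}

# quick constructor for small-variant call tables
make_calls <- function(keys, caller = "A", class = "SNV") {
  parts <- strsplit(keys, ":", fixed = TRUE)
  n <- length(keys)
  data.frame(contig = vapply(parts, `[`, "", 1),
             pos = as.numeric(vapply(parts, `[`, "", 2)),
             ref = vapply(parts, `[`, "", 3),
             alt = vapply(parts, `[`, "", 4),
             class = rep_len(class, n), filter = rep_len("PASS", n),
             caller = rep_len(caller, n), stringsAsFactors = FALSE)
}

# synthetic observation table (no genome needed)
make_observations <- function(n, depth_mean, vaf, seed, class = "SNV",
                              purity = 1, local_cn = 2) {
  withr::with_seed(seed, {
    depth <- stats::rnbinom(n, size = 10, mu = depth_mean)
    vaf <- rep_len(vaf, n)
    data.frame(variant_id = sprintf("V%05d", seq_len(n)), assay = "wgs",
               class = class, contig = "chr1", pos = seq_len(n),
               ref = "A", alt = "T", depth = depth,
               alt_reads = stats::rbinom(n, depth, vaf), purity = purity,
               local_cn = local_cn, multiplicity = 1L,
               ccf = vaf / expected_vaf(1, purity, local_cn, 1),
               vaf_true = vaf, stringsAsFactors = FALSE)
  })
}
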