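test_that("genome simulation is deterministic and honours the coding fraction", {
  g1 <- simulate_genome(genome_config(contigs = c(chr1 = 5e4)), seed = 1)
  g2 <- simulate_genome(genome_config(contigs = c(chr1 = 5e4)), seed = 1)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(nchar(g1$sequence[["chr1"]]), 50000L)

  g <- fixture_genome()
  widths <- g$coding_regions$end - g$coding_regions$start
  expect_equal(sum(widths), 0.01 * 4e5, tolerance = 1e-6)
  # intervals within bounds and non-overlapping per contig
  for (ct in g$contigs$name) {
    cr <- g$coding_regions[g$coding_regions$contig == ct, ]
    cr <- cr[order(cr$start), ]
    expect_true(all(cr$start >= 0 & cr$end <= g$contigs$length[
      g$contigs$name == ct]))
    if (nrow(cr) > 1) expect_true(all(cr$start[-1] >= cr$end[-nrow(cr)]))
  }
  expect_true(all(g$genes$end <= g$contigs$length[
    match(g$genes$contig, g$contigs$name)]))
})

test_that("genome config is validated and zero genes is a valid genome", {
  expect_error(genome_config(coding_fraction = 1.5), "coding_fraction")
  expect_error(genome_config(coding_fraction = 0), "coding_fraction")
  g <- simulate_genome(genome_config(contigs = c(chr1 = 5e4), n_genes = 0),
                       seed = 3)
  expect_identical(nrow(g$genes), 0L)
})

test_that("expected_vaf follows the purity/CN-adjusted formula and its domain", {
  expect_equal(expected_vaf(1.0, 0.5, 2, 1), 0.25)
  expect_equal(expected_vaf(1.0, 1.0, 2, 1), 0.5)
  expect_equal(expected_vaf(0.35, 0.8, 3, 1), 0.1)  # 0.8*0.35/(0.8*3+0.4)
  expect_error(expected_vaf(1, 1, 2, 3), "multiplicity")
  expect_error(expected_vaf(0, 1, 2, 1), "ccf")
  set.seed(11)
  ccf <- runif(200, 0.01, 1); pur <- runif(200, 0.05, 1)
  cnt <- sample(1:6, 200, TRUE); m <- pmax(1, pmin(cnt, sample(1:3, 200, TRUE)))
  v <- expected_vaf(ccf, pur, cnt, m)
  expect_true(all(v > 0 & v <= 1))
})

test_that("tumor simulation respects clone bookkeeping and CCF constraints", {
  g <- fixture_genome()
  tr <- simulate_tumor(g, tumor_config(
    purity = 0.7,
    clones = data.frame(clone_id = "C1", parent_id = NA, ccf = 1),
    n_snv = 100, n_indel = 0, n_sv = 0, n_fusion = 0), seed = 2)
  expect_true(all(tr$variants$ccf == 1))

  tr2 <- simulate_tumor(g, tumor_config(
    clones = data.frame(clone_id = c("C1", "C2"), parent_id = c(NA, "C1"),
                        ccf = c(1.0, 0.4)),
    n_snv = c(60, 40), n_indel = 0, n_sv = 0, n_fusion = 0), seed = 2)
  counts <- table(tr2$variants$clone_id[tr2$variants$class == "SNV"])
  expect_identical(as.integer(counts[c("C1", "C2")]), c(60L, 40L))
  # unique loci
  expect_false(any(duplicated(paste0(tr2$variants$contig, ":",
                                     tr2$variants$pos))))
  expect_error(tumor_config(clones = data.frame(
    clone_id = c("C1", "C2"), parent_id = c(NA, "C1"), ccf = c(1, 1.2))),
    "exceeds")
  expect_error(tumor_config(clones = data.frame(
    clone_id = "C1", parent_id = NA, ccf = 0.8)), "truncal")
})

test_that("simulated SNV contexts follow the configured signature mixture", {
  g <- fixture_genome()
  tr <- simulate_tumor(g, tumor_config(
    clones = data.frame(clone_id = "C1", parent_id = NA, ccf = 1),
    n_snv = 2000, n_indel = 0, n_sv = 0, n_fusion = 0,
    signature_mix = c(SBS_A = 1)), seed = 5)
  counts <- table(factor(tr$variants$context, levels = sbs_contexts()))
  expected <- synthetic_signature_catalog()$matrix[, "SBS_A"]
  set.seed(99)
  gof <- chisq.test(as.numeric(counts), p = expected,
                    simulate.p.value = TRUE, B = 2000)
  expect_gt(gof$p.value, 0.001)
  # and the written genome really carries those contexts
  v96 <- context_matrix(tr$variants, g)
  expect_equal(as.numeric(v96), as.numeric(counts))
})

test_that("assay read sampling matches the binomial expectation", {
  g <- fixture_genome()
  tr <- fixture_clonal_tumor()
  obs <- simulate_assay(tr, assay_config(mean_depth = 100, purity = 1),
                        seed = 4)
  vafs <- obs$alt_reads[obs$depth > 0] / obs$depth[obs$depth > 0]
  se <- sd(vafs) / sqrt(length(vafs))
  expect_lt(abs(mean(vafs) - 0.5), 3 * se + 1e-3)
  # determinism
  obs2 <- simulate_assay(tr, assay_config(mean_depth = 100, purity = 1),
                         seed = 4)
  expect_identical(obs, obs2)
  # absent clone -> zero alt reads always
  tr2 <- fixture_tumor()
  obs3 <- simulate_assay(tr2, assay_config(name = "panel", mean_depth = 400,
                                           clones = "C1"), seed = 6)
  expect_true(all(obs3$alt_reads[obs3$ccf == 0] == 0))
  expect_error(assay_config(mean_depth = 0), "mean_depth")
})

test_that("empirical VAF converges to expected_vaf at extreme depth", {
  tr <- fixture_tumor()
  obs <- simulate_assay(tr, assay_config(mean_depth = 10000), seed = 8)
  ok <- obs$depth > 0 & obs$vaf_true > 0
  dev <- (obs$alt_reads[ok] / obs$depth[ok]) - obs$vaf_true[ok]
  se <- sqrt(obs$vaf_true[ok] * (1 - obs$vaf_true[ok]) / obs$depth[ok])
  expect_gt(mean(abs(dev) <= 3 * se), 0.99 - 0.02)
})

test_that("caller simulation is exact when deterministic and Poisson for FPs", {
  g <- fixture_genome()
  tr <- fixture_tumor()
  obs <- simulate_assay(tr, assay_config(mean_depth = 100), seed = 10)
  det <- lapply(c("A", "B", "C"), caller_model, min_alt_reads = 2,
                miss_prob = 0, fp_rate_per_mb = 0)
  calls <- simulate_caller_outputs(obs, g, det, seed = 11)
  expected_ids <- sort(obs$variant_id[obs$alt_reads >= 2])
  for (cs in calls) expect_identical(sort(cs$truth_id), expected_ids)
  # identical deterministic callers -> support 3 everywhere downstream
  cons <- merge_small_variants(calls, genome = g)
  expect_true(all(cons$n_callers == 3))
  expect_true(all(cons$high_confidence))

  # FP count ~ Poisson(rate * Mb): mean over seeds near 0.4 * rate
  fp_model <- list(caller_model("A", miss_prob = 0, fp_rate_per_mb = 10))
  n_fp <- vapply(1:40, function(s) {
    cc <- simulate_caller_outputs(obs[0, ], g, fp_model, seed = s)
    nrow(cc$A)
  }, numeric(1))
  lambda <- 10 * 0.4
  expect_lt(abs(mean(n_fp) - lambda), 3 * sqrt(lambda / 40))
  expect_error(caller_model("X", miss_prob = 1.5), "miss_prob")
})

test_that("expression simulation links CN to TPM and uses the full cohort", {
  g <- fixture_genome()
  tr <- fixture_tumor()
  ex <- simulate_expression(g, tr, cohort_config(cohort_size = 274,
                                                 log_sd = 0.1), seed = 12)
  expect_identical(ncol(ex$reference), 274L)
  amp <- ex$gene_cn$gene[ex$gene_cn$total_cn >= 8]
  if (length(amp) > 0) {
    ratios <- vapply(1:20, function(s) {
      e <- simulate_expression(g, tr, cohort_config(cohort_size = 50,
                                                    log_sd = 0.1), seed = s)
      e$tumor_tpm[amp[1]] / median(e$reference[amp[1], ])
    }, numeric(1))
    expect_equal(median(ratios), 4, tolerance = 0.15)
  }
  neutral <- ex$gene_cn$gene[ex$gene_cn$total_cn == 2]
  fus <- tr$variants[tr$variants$class == "fusion", ]
  neutral <- setdiff(neutral, c(fus$gene5, fus$gene3))
  g0 <- neutral[1]
  pct <- mean(ex$reference[g0, ] <= ex$tumor_tpm[g0])
  expect_gt(pct, 0); expect_lt(pct, 1)  # drawn from the reference distribution
})

test_that("YAML run configs parse into validated config objects", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "genome: {coding_fraction: 0.02, n_genes: 10}",
    "tumor:",
    "  purity: 0.7",
    "  clones: [{clone_id: C1, ccf: 1.0}, {clone_id: C2, parent_id: C1, ccf: 0.3}]",
    "  n_snv: [100, 50]",
    "assays:",
    "  - {name: wgs, mean_depth: 100}",
    "  - {name: panel, mean_depth: 500, clones: [C1]}"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$genome$coding_fraction, 0.02)
  expect_equal(cfg$tumor$purity, 0.7)
  expect_identical(cfg$tumor$clones$clone_id, c("C1", "C2"))
  expect_identical(cfg$tumor$n_snv, c(100L, 50L))
  expect_length(cfg$assays, 2)
  expect_identical(cfg$assays[[2]]$clones, "C1")
  writeLines("tumour: {purity: 0.5}", path)  # typo'd key fails fast
  expect_error(read_run_config(path), "unknown run config key")
})

test_that("cfDNA simulation honours tumor fraction and private clones", {
  tr <- fixture_clonal_tumor()
  expect_error(simulate_cfdna(tr, 1.0), "tumor_fraction")
  expect_equal(expected_vaf(1, 0.5, 2, 1), 0.25)  # cfDNA at TF 0.5, diploid het
  cf <- simulate_cfdna(tr, 0.83, mean_depth = 100, seed = 13)
  ok <- cf$observations$local_cn == 2
  detected <- mean(cf$observations$alt_reads[ok] >= 2)
  power <- mean(detection_power(cf$observations$depth[ok],
                                cf$observations$vaf_true[ok]))
  expect_gt(detected, 0.98)
  expect_lt(abs(detected - power), 0.02)
  cfp <- simulate_cfdna(tr, 0.5, private_clone = list(ccf = 0.3, n_snv = 40),
                        seed = 14)
  expect_length(cfp$private_variant_ids, 40)
  expect_false(any(cfp$private_variant_ids %in% tr$variants$id))
})
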