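fixture_gene_table <- function() {
  data.frame(gene = c("TP53", "KRAS", "MYC", "NFIB"),
             contig = c("chr1", "chr1", "chr2", "chr2"),
             start = c(1000, 10000, 1000, 20000),
             end = c(5000, 15000, 6000, 26000),
             strand = "+", is_cancer_gene = TRUE)
}

fixture_driver_table <- function() {
  data.frame(gene = c("TP53", "KRAS", "TP53", "EWSR1"),
             class = c("any", "SNV", "SV", "fusion"),
             alteration = NA_character_)
}

test_that("oncogenic annotation combines table lookup and SV gene targeting", {
  gt <- fixture_gene_table(); dt <- fixture_driver_table()
  small <- data.frame(class = c("SNV", "SNV", "indel"),
                      gene = c("TP53", "MYC", "TP53"))
  expect_identical(annotate_oncogenic(small, dt), c(TRUE, FALSE, TRUE))
  svs <- data.frame(class = "SV", contig = c("chr1", "chr2"),
                    pos = c(2000, 50000), contig2 = c("chr1", "chr2"),
                    pos2 = c(80000, 60000), svtype = "DEL")
  expect_identical(annotate_oncogenic(svs, dt, gt), c(TRUE, FALSE))
  fus <- data.frame(class = "fusion", contig = "chr1", pos = 90000,
                    contig2 = "chr2", pos2 = 90000, svtype = "TRA",
                    gene5 = "EWSR1", gene3 = "FLI1")
  expect_true(annotate_oncogenic(fus, dt, gt))
})

test_that("SV gene targeting reports breakpoint hits and contained deletions", {
  gt <- fixture_gene_table()
  svs <- data.frame(
    contig = c("chr1", "chr1", "chr1"),
    pos = c(2000, 500, 60000),
    contig2 = c("chr1", "chr1", "chr1"),
    pos2 = c(90000, 20000, 70000),
    svtype = c("TRA", "DEL", "TRA"))
  tg <- sv_gene_targeting(svs, gt)
  expect_identical(tg[[1]], "TP53")                    # breakpoint inside
  expect_setequal(tg[[2]], c("TP53", "KRAS"))          # contained by deletion
  expect_length(tg[[3]], 0)                            # intergenic
})

test_that("expression biomarker calls follow the cohort percentile bands", {
  set.seed(81)
  ref <- matrix(rlnorm(3 * 100, 2, 0.5), nrow = 3,
                dimnames = list(c("TP53", "KRAS", "MYC"), NULL))
  tpm <- c(TP53 = max(ref["TP53", ]) * 2,           # above the maximum
           KRAS = unname(quantile(ref["KRAS", ], 0.92)),
           MYC = unname(median(ref["MYC", ])))
  calls <- expression_biomarkers(tpm, ref)
  expect_identical(calls$call[calls$gene == "TP53"], "severe_over")
  expect_identical(calls$call[calls$gene == "KRAS"], "over")
  expect_identical(calls$call[calls$gene == "MYC"], "none")
  # absent gene or thin cohort -> NA call
  calls2 <- expression_biomarkers(c(ABSENT = 5), ref)
  expect_true(is.na(calls2$call))
  # monotonicity: raising TPM never demotes the call severity
  severity <- c(severe_under = -2, under = -1, none = 0, over = 1,
                severe_over = 2)
  grid <- sort(c(ref["KRAS", ], max(ref["KRAS", ]) * 1.5))
  lv <- severity[vapply(grid, function(x)
    expression_biomarkers(c(KRAS = x), ref)$call, "")]
  expect_true(all(diff(lv) >= 0))
})

test_that("SV support for biomarkers is direction-consistent", {
  gt <- fixture_gene_table()
  calls <- data.frame(gene = c("KRAS", "MYC", "TP53"),
                      tpm = c(100, 100, 1),
                      percentile = c(0.97, 0.96, 0.03),
                      call = c("severe_over", "severe_over", "severe_under"))
  cn <- data.frame(contig = "chr1", start = 9000, end = 16000,
                   total_cn = 8, major_cn = 7)
  svs <- data.frame(contig = "chr1", pos = 2000, contig2 = "chr1",
                    pos2 = 3000, svtype = "DEL")
  out <- sv_supported_biomarkers(calls, svs = svs, cn_segments = cn,
                                 gene_table = gt)
  # KRAS amplified+overexpressed, TP53 disrupted by intragenic SV; MYC diploid
  expect_setequal(out$supported$gene, c("KRAS", "TP53"))
  expect_equal(out$fraction, 2 / 3)
  none <- sv_supported_biomarkers(calls[2, , drop = FALSE], gene_table = gt)
  expect_equal(none$fraction, 0)
})

test_that("germline prioritization lets assertions override frequency filters", {
  cons <- merge_small_variants(list(
    A = make_calls(c("chr1:10:A:G", "chr1:20:C:T", "chr1:30:G:A")),
    B = make_calls(c("chr1:10:A:G", "chr1:20:C:T", "chr1:30:G:A"))))
  af <- c("chr1:10:A:G" = 0.2, "chr1:20:C:T" = 1e-4, "chr1:30:G:A" = 0.02)
  assertions <- c("chr1:20:C:T" = "pathogenic", "chr1:30:G:A" = "pathogenic")
  out <- prioritize_germline(cons, population_af = af,
                             assertions = assertions)
  expect_setequal(out$key, c("chr1:20:C:T", "chr1:30:G:A"))
  expect_identical(out$retained_by[out$key == "chr1:30:G:A"], "assertion")
  # missing AF table: filter skipped with a warning
  expect_warning(all3 <- prioritize_germline(cons), "AF")
  expect_identical(nrow(all3), 3L)
  # recurrence cap
  rec <- c("chr1:20:C:T" = 50)
  out2 <- prioritize_germline(cons, population_af = af,
                              cohort_recurrence = rec, recurrence_cap = 5)
  expect_false("chr1:20:C:T" %in% out2$key)
})

test_that("incremental findings are a keyed set difference with categories", {
  cw <- data.frame(patient_id = "P1", key = c("A", "B", "C"),
                   type = c("SNV", "fusion", "signature"),
                   oncogenic = c(TRUE, TRUE, FALSE),
                   prognostic_evidence = c(FALSE, FALSE, TRUE))
  pan <- data.frame(patient_id = "P1", key = "A", type = "SNV",
                    oncogenic = TRUE)
  inc <- incremental_findings(cw, pan)
  expect_setequal(inc$key, c("B", "C"))
  expect_identical(inc$clinical_category[inc$key == "B"], "driver_fusion")
  expect_identical(inc$clinical_category[inc$key == "C"], "prognostic")
  # self-difference is empty; empty panel returns everything
  expect_identical(nrow(incremental_findings(cw, cw)), 0L)
  expect_identical(nrow(incremental_findings(cw, pan[0, ])), 3L)
  # precedence: diagnostic beats prognostic
  multi <- data.frame(patient_id = "P1", key = "D", type = "SNV",
                      oncogenic = TRUE, prognostic_evidence = TRUE,
                      diagnostic_evidence = TRUE)
  expect_identical(incremental_findings(multi, pan)$clinical_category,
                   "diagnostic")
  # no evidence -> none
  bare <- data.frame(patient_id = "P1", key = "E", type = "SNV",
                     oncogenic = TRUE)
  expect_identical(incremental_findings(bare, pan)$clinical_category, "none")
})

test_that("WES/RNA maskability follows event-type and coding-overlap rules", {
  bed <- data.frame(contig = "chr1", start = 1000, end = 2000)
  f <- data.frame(
    type = c("SNV", "SNV", "SV", "SV", "fusion", "biomarker", "signature",
             "TMB", "MSI"),
    contig = c("chr1", "chr1", "chr1", "chr1", "chr1", NA, NA, NA, NA),
    pos = c(1500, 5000, 1500, 8000, 9000, NA, NA, NA, NA),
    contig2 = c(NA, NA, "chr1", "chr1", "chr1", NA, NA, NA, NA),
    pos2 = c(NA, NA, 9000, 9500, 9990, NA, NA, NA, NA))
  out <- wes_rna_maskability(f, bed)
  expect_identical(out$wes_capturable,
                   c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(out$rna_capturable,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                     FALSE))
})

test_that("the cohort report aggregates per-patient counts and percentages", {
  f <- data.frame(patient_id = c("P1", "P1", "P2", "P3"),
                  key = c("A", "B", "C", "D"),
                  type = c("SNV", "fusion", "SNV", "SNV"),
                  oncogenic = c(TRUE, TRUE, TRUE, FALSE),
                  diagnostic_evidence = c(TRUE, FALSE, FALSE, FALSE),
                  wes_capturable = c(TRUE, FALSE, FALSE, FALSE),
                  rna_capturable = c(FALSE, TRUE, FALSE, FALSE))
  f$clinical_category <- wgtsbench:::assign_clinical_category(f)
  rep <- cohort_report(f, n_patients = 10)
  expect_identical(rep$patients_with_incremental, 2L)  # P1, P2 (oncogenic)
  expect_equal(rep$incremental_percent, 20)
  expect_identical(rep$clinically_relevant_patients, 1L)
  expect_identical(rep$category_counts$diagnostic, 1L)
  expect_identical(rep$capturability$combined_patients, 1L)
  # single patient with no findings
  empty <- f[0, ]
  rep0 <- cohort_report(empty, n_patients = 1)
  expect_equal(rep0$incremental_percent, 0)
  # JSON report is written and parseable
  path <- tempfile(fileext = ".json")
  cohort_report(f, 10, json_path = path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_patients, 10)
  expect_identical(parsed$schema_version, "1.0")
})
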