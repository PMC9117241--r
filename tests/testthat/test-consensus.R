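test_that("small-variant merge applies the two-caller high-confidence rule", {
  cs <- list(A = make_calls(c("chr1:100:A:T", "chr1:200:G:C")),
             B = make_calls("chr1:100:A:T"))
  out <- merge_small_variants(cs)
  expect_identical(nrow(out), 2L)
  m1 <- out[out$pos == 100, ]; m2 <- out[out$pos == 200, ]
  expect_true(m1$high_confidence); expect_identical(m1$n_callers, 2L)
  expect_false(m2$high_confidence)
  expect_identical(nrow(merge_small_variants(list(A = make_calls(character(0))))),
                   0L)
})

test_that("merging is idempotent and invariant to caller order", {
  set.seed(21)
  pool <- sprintf("chr1:%d:%s:%s", sample(1000, 30),
                  sample(c("A", "C"), 30, TRUE), sample(c("G", "T"), 30, TRUE))
  cs <- list(A = make_calls(sample(pool, 20)), B = make_calls(sample(pool, 20)),
             C = make_calls(sample(pool, 20)))
  out <- merge_small_variants(cs)
  perm <- merge_small_variants(cs[c(3, 1, 2)])
  expect_identical(out, perm)
  again <- merge_small_variants(list(X = out[, c("contig", "pos", "ref", "alt",
                                                 "class")]))
  expect_identical(again$key, out$key)  # variant set is stable under re-merge
  # support sets partition the input records
  expect_identical(sum(out$n_callers), sum(vapply(cs, nrow, integer(1))))
})

test_that("consensus support matches an exhaustive oracle on random instances", {
  for (rep in 1:10) {
    set.seed(100 + rep)
    pool <- sprintf("chr1:%d:A:T", sample(5000, 50))
    cs <- lapply(setNames(1:3, c("A", "B", "C")), function(i)
      make_calls(sample(pool, sample(10:50, 1))))
    out <- merge_small_variants(cs)
    # oracle: count caller sets by exhaustive intersection over keys
    keyset <- lapply(cs, function(x)
      paste(x$contig, x$pos, x$ref, x$alt, sep = ":"))
    for (i in seq_len(nrow(out))) {
      support <- sum(vapply(keyset, function(k) out$key[i] %in% k, logical(1)))
      expect_identical(out$n_callers[i], support)
      expect_identical(out$high_confidence[i], support >= 2)
    }
  }
})

test_that("padded indel representations merge onto one left-aligned key", {
  g <- fixture_genome()
  # a real deletion taken from the genome, re-padded two ways
  pos <- 5000
  seqch <- substring(g$sequence[["chr1"]], pos, pos + 6)
  a <- data.frame(contig = "chr1", pos = pos,
                  ref = substr(seqch, 1, 4), alt = substr(seqch, 1, 1),
                  class = "indel", filter = "PASS")
  b <- data.frame(contig = "chr1", pos = pos,
                  ref = substr(seqch, 1, 5), alt = substr(seqch, 1, 2),
                  class = "indel", filter = "PASS")  # same event, extra pad
  skipme <- substr(seqch, 2, 2) != substr(seqch, 5, 5)
  out <- merge_small_variants(list(A = a, B = b), genome = g)
  if (skipme) {
    # representations genuinely differ at this locus; both survive
    expect_gte(nrow(out), 1L)
  } else {
    expect_identical(nrow(out), 1L)
    expect_identical(out$n_callers, 2L)
  }
  # multi-allelic records are split before merging
  m <- data.frame(contig = "chr1", pos = 10, ref = "A", alt = "T,G",
                  class = "SNV", filter = "PASS")
  out2 <- merge_small_variants(list(A = m))
  expect_identical(nrow(out2), 2L)
  expect_setequal(out2$alt, c("T", "G"))
})

test_that("non-PASS records are excluded and contig namespaces checked", {
  a <- make_calls(c("chr1:100:A:T", "chr1:200:G:C"))
  a$filter[2] <- "LowQual"
  out <- merge_small_variants(list(A = a))
  expect_identical(nrow(out), 1L)
  b <- make_calls("1:100:A:T")
  expect_error(merge_small_variants(list(A = make_calls("chr1:100:A:T"),
                                         B = b)), "namespace")
})

test_that("panel-of-normals filtering uses >=3 alt reads in >=1% of normals", {
  cons <- merge_small_variants(list(A = make_calls(c("chr1:100:A:T",
                                                     "chr1:200:G:C",
                                                     "chr1:300:C:G")),
                                    B = make_calls(c("chr1:100:A:T",
                                                     "chr1:200:G:C",
                                                     "chr1:300:C:G"))))
  pon <- matrix(0L, nrow = 3, ncol = 100,
                dimnames = list(cons$key, sprintf("N%03d", 1:100)))
  pon["chr1:100:A:T", 1:2] <- 5L   # 2% of normals
  pon["chr1:200:G:C", 1] <- 3L     # exactly 1% (inclusive boundary)
  out <- pon_filter(cons, pon)
  expect_true(out$pon_filtered[out$key == "chr1:100:A:T"])
  expect_true(out$pon_filtered[out$key == "chr1:200:G:C"])
  expect_false(out$pon_filtered[out$key == "chr1:300:C:G"])
  expect_false(out$high_confidence[out$key == "chr1:100:A:T"])
  # missing variant treated as absent from all normals
  out2 <- pon_filter(cons, pon[1:2, , drop = FALSE])
  expect_false(out2$pon_filtered[out2$key == "chr1:300:C:G"])
  # a variant below the alt-read threshold in every normal is kept
  pon2 <- pon; pon2[] <- 2L
  expect_false(any(pon_filter(cons, pon2)$pon_filtered))
})

test_that("SV merging clusters by window and orientation (single linkage)", {
  sv <- function(p1, p2, s1 = "+", s2 = "-", caller = "A", type = "DEL")
    data.frame(contig = "chr1", pos = p1, strand1 = s1, contig2 = "chr1",
               pos2 = p2, strand2 = s2, svtype = type, caller = caller,
               stringsAsFactors = FALSE)
  out <- merge_svs(list(A = sv(1000, 5000), B = sv(1050, 5040)))
  expect_identical(nrow(out), 1L)
  expect_identical(out$n_callers, 2L)
  expect_true(out$high_confidence)
  expect_equal(out$pos, median(c(1000, 1050)))
  # same loci, opposite orientation: kept apart
  out2 <- merge_svs(list(A = sv(1000, 5000, "+", "-"),
                         B = sv(1000, 5000, "-", "+", type = "DUP")))
  expect_identical(nrow(out2), 2L)
  # three callers, one cluster
  out3 <- merge_svs(list(A = sv(1000, 5000), B = sv(1100, 5100),
                         C = sv(1150, 5150)))
  expect_identical(out3$n_callers, 3L)  # A-B and B-C within 200, chain merges
  # missing mate information: warned and excluded
  bad <- sv(1000, 5000); bad$pos2 <- NA
  expect_warning(out4 <- merge_svs(list(A = bad, B = sv(1000, 5000))),
                 "mate")
  expect_identical(out4$n_callers, 1L)
})

test_that("fusion merging keys on the ordered 5'/3' gene pair", {
  fu <- function(g5, g3, caller) data.frame(gene5 = g5, gene3 = g3,
                                            caller = caller)
  out <- merge_fusions(list(A = fu("EWSR1", "FLI1", "A"),
                            B = fu("EWSR1", "FLI1", "B"),
                            C = fu("PAX3", "FOXO1", "C")))
  ew <- out[out$gene5 == "EWSR1", ]
  expect_true(ew$high_confidence); expect_identical(ew$n_callers, 2L)
  expect_false(out$high_confidence[out$gene5 == "PAX3"])
  # reversed orientation is a distinct record
  out2 <- merge_fusions(list(A = fu("X", "Y", "A"), B = fu("Y", "X", "B")))
  expect_identical(nrow(out2), 2L)
  expect_false(any(out2$high_confidence))
})

test_that("germline merging requires exactly two callers, both for confidence", {
  a <- make_calls(c("chr1:10:A:G", "chr1:20:C:T"))
  b <- make_calls(c("chr1:10:A:G", "chr1:30:G:A"))
  out <- merge_germline(list(strelka = a, freebayes = b))
  expect_identical(nrow(out), 3L)
  expect_true(out$high_confidence[out$pos == 10])
  expect_false(any(out$high_confidence[out$pos %in% c(20, 30)]))
  disjoint <- merge_germline(list(A = make_calls("chr1:10:A:G"),
                                  B = make_calls("chr1:20:C:T")))
  expect_identical(sum(disjoint$high_confidence), 0L)
  expect_error(merge_germline(list(a, b, a)), "exactly 2")
})

test_that("VCF round-trip preserves calls", {
  g <- fixture_genome()
  tr <- fixture_tumor()
  obs <- simulate_assay(tr, assay_config(mean_depth = 100), seed = 31)
  calls <- simulate_caller_outputs(obs, g, list(caller_model("A")), seed = 32)
  path <- tempfile(fileext = ".vcf")
  write_caller_vcf(calls$A, g, path)
  back <- read_caller_vcf(path)
  expect_identical(nrow(back), nrow(calls$A))
  expect_identical(as.integer(back$pos), as.integer(calls$A$pos))
  expect_identical(back$truth_id, calls$A$truth_id)
  # independent parser agrees on the record table
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_identical(nrow(v@fix), nrow(calls$A))
  expect_identical(as.integer(v@fix[, "POS"]), as.integer(calls$A$pos))
})
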