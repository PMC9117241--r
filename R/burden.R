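#' Count coding SNVs and indels against a coding mask
#'
#' Variant positions are 1-based; BED intervals are 0-based half-open, so a
#' variant at 1-based position `pos` falls in `[start, end)` iff
#' `start <= pos - 1 < end`.
#'
#' @param variants data.frame with columns contig, pos (1-based), class.
#' @param coding_bed data.frame (contig, start, end) as from [read_bed()].
#' @return list: coding_snv_count, coding_indel_count, in_coding (logical
#'   per variant).
#' @export
coding_mask <- function(variants, coding_bed) {
  if (nrow(coding_bed) == 0 || nrow(variants) == 0) {
    return(list(coding_snv_count = 0L, coding_indel_count = 0L,
                in_coding = rep(FALSE, nrow(variants))))
  }
  vr <- GenomicRanges::GRanges(variants$contig,
                               IRanges::IRanges(variants$pos, variants$pos))
  cr <- GenomicRanges::GRanges(coding_bed$contig,
                               IRanges::IRanges(coding_bed$start + 1,
                                                coding_bed$end))
  hit <- IRanges::overlapsAny(vr, cr)
  list(coding_snv_count = sum(hit & variants$class == "SNV"),
       coding_indel_count = sum(hit & variants$class == "indel"),
       in_coding = hit)
}

#' Coding tumor mutational burden
#'
#' TMB = (coding SNVs + coding indels) / 30, the divisor approximating the
#' human exome length in Mb.  Classification uses strict thresholds: above 2
#' mutations/Mb is pediatric-high, above 10 is hypermutator.
#'
#' @param snv_count,indel_count Coding mutation counts.
#' @return list of class `tmb_result`: coding_snv_count, coding_indel_count,
#'   tmb, class.
#' @export
coding_tmb <- function(snv_count, indel_count) {
  stopifnot(snv_count >= 0, indel_count >= 0)
  tmb <- (snv_count + indel_count) / 30
  cls <- if (tmb > 10) "hypermutator" else if (tmb > 2) "pediatric_high" else
    "normal"
  structure(list(coding_snv_count = snv_count,
                 coding_indel_count = indel_count,
                 tmb = tmb, class = cls), class = "tmb_result")
}

#' 96-context mutation spectrum of a set of SNVs
#'
#' Each SNV is mapped to its trinucleotide context (5' base, substitution,
#' 3' base) with the mutated base expressed as its pyrimidine partner: when
#' the reference base is a purine the whole context is reverse-complemented.
#' Positions at contig boundaries are skipped with a warning.  The vector
#' sums to the number of (usable) SNVs.
#'
#' @param snvs data.frame with contig, pos (1-based), ref, alt.
#' @param genome A `synthetic_genome` (or any list with a `sequence` element
#'   of per-contig strings).
#' @return Named numeric vector over [sbs_contexts()].
#' @export
context_matrix <- function(snvs, genome) {
  vec <- stats::setNames(numeric(96), sbs_contexts())
  if (nrow(snvs) == 0) return(vec)
  lens <- vapply(genome$sequence, nchar, numeric(1))
  for (i in seq_len(nrow(snvs))) {
    ct <- snvs$contig[i]; pos <- snvs$pos[i]
    if (!ct %in% names(genome$sequence))
      stop_config("contig '%s' absent from genome", ct)
    if (pos <= 1 || pos >= lens[[ct]]) {
      warning(sprintf("SNV at %s:%d lies at a contig boundary; skipped",
                      ct, pos))
      next
    }
    tri <- substring(genome$sequence[[ct]], pos - 1, pos + 1)
    ref <- snvs$ref[i]; alt <- snvs$alt[i]
    if (substr(tri, 2, 2) != ref)
      stop_config("reference mismatch at %s:%d (genome %s, variant %s)",
                  ct, pos, substr(tri, 2, 2), ref)
    if (ref %in% c("A", "G")) {
      tri <- revcomp(tri)
      ref <- chartr("AG", "TC", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    label <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                    substr(tri, 3, 3))
    vec[label] <- vec[label] + 1
  }
  vec
}

#' Refit a 96-context spectrum against a signature catalog
#'
#' Non-negative least squares of the observed spectrum on the catalog
#' columns, followed by iterative pruning: signatures contributing less than
#' `prune_share` of the fitted mass are dropped and the remainder refitted,
#' until the active set is stable.  The reconstruction cosine similarity is
#' reported; values below 0.8 indicate a spectrum the catalog cannot
#' represent.
#'
#' @param vector96 Named numeric 96-context vector (counts).
#' @param catalog A `signature_catalog`.
#' @param prune_share Minimum exposure share to retain a signature
#'   (default 0.01).
#' @return list of class `exposure_vector`: `exposures` (named mutation
#'   counts, 0 for pruned signatures), `shares`, `cosine`, `low_confidence`
#'   (cosine < 0.8).
#' @export
refit_signatures <- function(vector96, catalog, prune_share = 0.01) {
  stopifnot(inherits(catalog, "signature_catalog"))
  if (length(vector96) != 96) stop_config("spectrum must have 96 entries")
  if (any(vector96 < 0)) stop_config("spectrum entries must be non-negative")
  if (sum(vector96) == 0) stop_config("all-zero spectrum: nothing to fit")
  if (!is.null(names(vector96))) vector96 <- vector96[sbs_contexts()]
  A <- catalog$matrix
  active <- colnames(A)
  repeat {
    fit <- pracma::lsqnonneg(A[, active, drop = FALSE], as.numeric(vector96))
    x <- stats::setNames(fit$x, active)
    share <- if (sum(x) > 0) x / sum(x) else x
    drop <- names(share)[share < prune_share]
    keep <- setdiff(active, drop)
    if (length(keep) == length(active) || length(keep) == 0) break
    active <- keep
  }
  exposures <- stats::setNames(numeric(ncol(A)), colnames(A))
  exposures[names(x)] <- x
  recon <- as.vector(A %*% exposures)
  cs <- cosine_sim(as.numeric(vector96), recon)
  structure(list(exposures = exposures,
                 shares = if (sum(exposures) > 0)
                   exposures / sum(exposures) else exposures,
                 cosine = cs, low_confidence = is.na(cs) || cs < 0.8),
            class = "exposure_vector")
}

#' Flag treatment-associated mutational signatures
#'
#' A treatment signature (platinum, temozolomide) is flagged when its
#' exposure share reaches `min_share` and its mutation count reaches
#' `min_mutations`.
#'
#' @param exposures An `exposure_vector` from [refit_signatures()].
#' @param signatures Signature names to assess.
#' @param min_share Minimum exposure share (default 0.05).
#' @param min_mutations Minimum attributed mutations (default 50).
#' @return Named logical vector; NA for signatures absent from the catalog.
#' @export
treatment_signature_flag <- function(exposures,
                                     signatures = c("SBS_platinum",
                                                    "SBS_temozolomide"),
                                     min_share = 0.05, min_mutations = 50) {
  stopifnot(inherits(exposures, "exposure_vector"))
  out <- stats::setNames(rep(NA, length(signatures)), signatures)
  present <- signatures %in% names(exposures$exposures)
  out[present] <- exposures$shares[signatures[present]] >= min_share &
    exposures$exposures[signatures[present]] >= min_mutations
  out
}

#' Microsatellite instability score from site-level repeat-length histograms
#'
#' Each microsatellite site contributes a tumor and a normal repeat-length
#' histogram; sites with at least `min_reads` supporting reads in both
#' samples are assessed by a chi-square homogeneity test (0.5 pseudo-counts
#' added to every cell) and called unstable at p < `alpha`.  The score is
#' 100 x unstable / assessed; status bands: < 3 stable, 3-10 indeterminate,
#' >= 10 high.
#'
#' @param site_histograms data.frame with columns site, repeat_length,
#'   tumor, normal (read counts per length).
#' @param min_reads Minimum reads per sample per site (default 20).
#' @param alpha Site-level significance threshold (default 0.05).
#' @return list of class `msi_result`: sites_assessed, sites_unstable,
#'   score, status.
#' @export
msi_score <- function(site_histograms, min_reads = 20, alpha = 0.05) {
  stopifnot(all(c("site", "repeat_length", "tumor", "normal") %in%
                  names(site_histograms)))
  assessed <- 0L; unstable <- 0L
  for (s in unique(site_histograms$site)) {
    h <- site_histograms[site_histograms$site == s, , drop = FALSE]
    if (sum(h$tumor) < min_reads || sum(h$normal) < min_reads) next
    assessed <- assessed + 1L
    if (nrow(h) < 2) next  # a single observed length: distributions identical
    m <- rbind(h$tumor, h$normal) + 0.5
    p <- suppressWarnings(stats::chisq.test(m)$p.value)
    if (!is.na(p) && p < alpha) unstable <- unstable + 1L
  }
  if (assessed == 0)
    return(structure(list(sites_assessed = 0L, sites_unstable = 0L,
                          score = NA_real_, status = NA_character_),
                     class = "msi_result"))
  score <- 100 * unstable / assessed
  status <- if (score >= 10) "high" else if (score >= 3) "indeterminate" else
    "stable"
  structure(list(sites_assessed = assessed, sites_unstable = unstable,
                 score = score, status = status), class = "msi_result")
}
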