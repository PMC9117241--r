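#' Pileup VAF of an observation
#'
#' @param alt_reads,depth Read counts (vectors).
#' @return `alt_reads / depth`; `NA` where depth is 0.
#' @export
pileup_vaf <- function(alt_reads, depth) {
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Purity-adjusted two-sample proportion test for intratumor heterogeneity
#'
#' Compares the clonal representation of a mutation in two assays.  Alt reads
#' are purity-normalized (`a' = min(alt / purity, depth)`) so that a mutation
#' clonal in both biopsies yields comparable adjusted proportions regardless
#' of biopsy purity, then a two-sided two-sample proportion z-test with
#' pooled variance is applied to the adjusted (alt, depth) pairs.  A p-value
#' below 0.05 suggests a genuine difference in clonal representation (ITH).
#'
#' @param alt1,depth1,purity1 Panel-assay observation (depth > 0,
#'   purity in (0, 1]).
#' @param alt2,depth2,purity2 WGS-assay observation.
#' @return Two-sided p-value in [0, 1]; 1 when both adjusted proportions are
#'   0.
#' @export
ith_proportion_test <- function(alt1, depth1, purity1, alt2, depth2, purity2) {
  n <- max(length(alt1), length(alt2))
  alt1 <- rep_len(alt1, n); depth1 <- rep_len(depth1, n)
  purity1 <- rep_len(purity1, n); alt2 <- rep_len(alt2, n)
  depth2 <- rep_len(depth2, n); purity2 <- rep_len(purity2, n)
  if (any(depth1 <= 0 | depth2 <= 0)) stop_config("depths must be positive")
  if (any(purity1 <= 0 | purity1 > 1 | purity2 <= 0 | purity2 > 1))
    stop_config("purities must lie in (0, 1]")
  a1 <- pmin(alt1 / purity1, depth1)
  a2 <- pmin(alt2 / purity2, depth2)
  p1 <- a1 / depth1; p2 <- a2 / depth2
  pool <- (a1 + a2) / (depth1 + depth2)
  se <- sqrt(pool * (1 - pool) * (1 / depth1 + 1 / depth2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[a1 + a2 == 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' Classify the cross-assay call status of a panel-reported mutation
#'
#' `Both` when the mutation was called in the WGS consensus; `ITH` when it is
#' absent from WGS and either targeted resequencing also failed to call it or
#' the proportion test signals a clonal-representation difference (p < 0.05);
#' otherwise `indeterminate` (a possible sensitivity failure rather than
#' heterogeneity).
#'
#' @param called_in_wgs Logical: present in the WGS consensus.
#' @param p_value Proportion-test p-value (NA when unavailable).
#' @param resequencing_called Logical: called in higher-depth resequencing
#'   (NA when resequencing was not performed).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector in {"Both", "ITH", "indeterminate"}.
#' @export
classify_call_status <- function(called_in_wgs, p_value = NA,
                                 resequencing_called = NA, alpha = 0.05) {
  n <- length(called_in_wgs)
  p_value <- rep_len(p_value, n)
  resequencing_called <- rep_len(resequencing_called, n)
  ith <- (!is.na(resequencing_called) & !resequencing_called) |
    (!is.na(p_value) & p_value < alpha)
  ifelse(called_in_wgs, "Both", ifelse(ith, "ITH", "indeterminate"))
}

#' VAF concordance between two assays
#'
#' @param vaf_panel,vaf_wgs Paired VAF vectors.
#' @return list(r, r_squared): Pearson correlation and its square; both NA
#'   when fewer than 3 complete pairs or zero variance in either axis.
#' @export
vaf_concordance <- function(vaf_panel, vaf_wgs) {
  ok <- !is.na(vaf_panel) & !is.na(vaf_wgs)
  x <- vaf_panel[ok]; y <- vaf_wgs[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_))
  r <- stats::cor(x, y)
  list(r = r, r_squared = r * r)
}

#' Cross-assay concordance summary
#'
#' Counts panel-reported mutations recovered in WGS, overall and among
#' oncogenic mutations, with percentages rounded half away from zero to
#' match clinical reporting, plus the Pearson r-squared of paired VAFs.
#'
#' @param pairs data.frame with columns `call_status` (from
#'   [classify_call_status()]), `oncogenic` (logical) and optionally
#'   `vaf_panel`, `vaf_wgs`.
#' @return list of class `concordance_summary`: n_panel_reported,
#'   n_called_in_wgs, recall_percent, n_oncogenic_panel, n_oncogenic_called,
#'   oncogenic_recall_percent, pearson_r2.
#' @export
concordance_summary <- function(pairs) {
  if (nrow(pairs) == 0)
    return(structure(list(n_panel_reported = 0L, n_called_in_wgs = 0L,
                          recall_percent = 0, n_oncogenic_panel = 0L,
                          n_oncogenic_called = 0L,
                          oncogenic_recall_percent = 0,
                          pearson_r2 = NA_real_),
                     class = "concordance_summary"))
  called <- pairs$call_status == "Both"
  onc <- if ("oncogenic" %in% names(pairs)) pairs$oncogenic else
    rep(FALSE, nrow(pairs))
  r2 <- if (all(c("vaf_panel", "vaf_wgs") %in% names(pairs)))
    vaf_concordance(pairs$vaf_panel, pairs$vaf_wgs)$r_squared else NA_real_
  pct <- function(k, n) if (n == 0) 0 else round_half_up(100 * k / n)
  structure(list(
    n_panel_reported = nrow(pairs),
    n_called_in_wgs = sum(called),
    recall_percent = pct(sum(called), nrow(pairs)),
    n_oncogenic_panel = sum(onc),
    n_oncogenic_called = sum(called & onc),
    oncogenic_recall_percent = pct(sum(called & onc), sum(onc)),
    pearson_r2 = r2), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Cross-assay concordance: %d/%d mutations called in WGS (%g%%)\n",
              x$n_called_in_wgs, x$n_panel_reported, x$recall_percent))
  cat(sprintf("  oncogenic: %d/%d (%g%%)\n", x$n_oncogenic_called,
              x$n_oncogenic_panel, x$oncogenic_recall_percent))
  if (!is.na(x$pearson_r2))
    cat(sprintf("  VAF concordance r^2 = %.2f\n", x$pearson_r2))
  invisible(x)
}

#' Per-class overlap of cfDNA de novo calls with tissue calls
#'
#' For SNVs and indels the intersection is exact on the variant key; for SVs
#' two calls match when both breakpoints lie within the merge window with
#' matching orientations; for CNA profiles the value is the fraction of the
#' genome on which total copy number agrees within +/-1.
#'
#' @param cfdna_small,tissue_small `consensus_calls` data.frames (cfDNA and
#'   tissue small variants).
#' @param cfdna_svs,tissue_svs Optional `consensus_svs` data.frames.
#' @param cfdna_cn,tissue_cn Optional CN segment data.frames (contig, start,
#'   end, total_cn).
#' @param window_bp SV matching window (default 200).
#' @param high_confidence_only Restrict both sides to high-confidence calls.
#' @return Named list of overlap fractions (`snv`, `indel`, `sv`, `cna`);
#'   a class with no cfDNA calls reports `NA`.
#' @export
cfdna_overlap <- function(cfdna_small, tissue_small,
                          cfdna_svs = NULL, tissue_svs = NULL,
                          cfdna_cn = NULL, tissue_cn = NULL,
                          window_bp = 200, high_confidence_only = TRUE) {
  pick <- function(x) {
    if (is.null(x)) return(x)
    if (high_confidence_only && "high_confidence" %in% names(x))
      x[x$high_confidence, , drop = FALSE] else x
  }
  cfdna_small <- pick(cfdna_small); tissue_small <- pick(tissue_small)
  cfdna_svs <- pick(cfdna_svs); tissue_svs <- pick(tissue_svs)
  out <- list()
  for (cls in c("SNV", "indel")) {
    cf <- cfdna_small[cfdna_small$class == cls, , drop = FALSE]
    ti <- tissue_small[tissue_small$class == cls, , drop = FALSE]
    out[[tolower(cls)]] <- if (nrow(cf) == 0) NA_real_ else
      mean(cf$key %in% ti$key)
  }
  out$sv <- if (is.null(cfdna_svs) || nrow(cfdna_svs) == 0) NA_real_ else {
    if (is.null(tissue_svs) || nrow(tissue_svs) == 0) 0 else {
      hit <- vapply(seq_len(nrow(cfdna_svs)), function(i) {
        any(cfdna_svs$contig[i] == tissue_svs$contig &
              cfdna_svs$contig2[i] == tissue_svs$contig2 &
              cfdna_svs$strand1[i] == tissue_svs$strand1 &
              cfdna_svs$strand2[i] == tissue_svs$strand2 &
              abs(cfdna_svs$pos[i] - tissue_svs$pos) <= window_bp &
              abs(cfdna_svs$pos2[i] - tissue_svs$pos2) <= window_bp)
      }, logical(1))
      mean(hit)
    }
  }
  out$cna <- if (is.null(cfdna_cn) || is.null(tissue_cn)) NA_real_ else
    cna_agreement(cfdna_cn, tissue_cn)
  out
}

#' Fraction of the genome where two CN profiles agree within a tolerance
#'
#' @param cn_a,cn_b CN segment data.frames (contig, start, end, total_cn;
#'   0-based half-open).
#' @param tol Allowed absolute total-CN difference (default 1).
#' @return Length-weighted agreement fraction over the union of covered
#'   territory.
#' @export
cna_agreement <- function(cn_a, cn_b, tol = 1) {
  contigs <- union(cn_a$contig, cn_b$contig)
  agree <- 0; total <- 0
  for (ct in contigs) {
    a <- cn_a[cn_a$contig == ct, , drop = FALSE]
    b <- cn_b[cn_b$contig == ct, , drop = FALSE]
    cuts <- sort(unique(c(a$start, a$end, b$start, b$end)))
    if (length(cuts) < 2) next
    for (i in seq_len(length(cuts) - 1)) {
      s <- cuts[i]; e <- cuts[i + 1]
      ca <- a$total_cn[a$start <= s & a$end >= e]
      cb <- b$total_cn[b$start <= s & b$end >= e]
      if (length(ca) == 0 || length(cb) == 0) next
      total <- total + (e - s)
      if (abs(ca[1] - cb[1]) <= tol) agree <- agree + (e - s)
    }
  }
  if (total == 0) return(NA_real_)
  agree / total
}

#' Estimate circulating tumor fraction from cfDNA SNV VAFs
#'
#' On copy-number-neutral (CNt = 2) segments a clonal heterozygous mutation
#' has expected VAF = tumor_fraction / 2, so the kernel-density mode of the
#' diploid-segment VAF distribution, doubled and clamped at 1, estimates the
#' tumor fraction.
#'
#' @param observations cfDNA observation data.frame (needs alt_reads, depth,
#'   local_cn).
#' @param min_snvs Minimum diploid-segment SNVs required (default 50).
#' @return Estimated tumor fraction in (0, 1], or NA when too few informative
#'   SNVs.
#' @export
estimate_tumor_fraction <- function(observations, min_snvs = 50) {
  ok <- observations$local_cn == 2 & observations$depth > 0
  if ("class" %in% names(observations)) ok <- ok & observations$class == "SNV"
  vafs <- observations$alt_reads[ok] / observations$depth[ok]
  vafs <- vafs[vafs > 0]
  if (length(vafs) < min_snvs) return(NA_real_)
  # Sheather-Jones plug-in bandwidth: less mode bias than the rule-of-thumb
  d <- tryCatch(stats::density(vafs, bw = "SJ", from = 0, to = 1, n = 512),
                error = function(e)
                  stats::density(vafs, from = 0, to = 1, n = 512))
  mode <- d$x[which.max(d$y)]
  min(2 * mode, 1)
}
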