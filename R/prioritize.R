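#' Annotate variants with the gene whose body contains them
#'
#' @param variants data.frame with contig, pos (1-based).
#' @param gene_table data.frame (gene, contig, start, end; 0-based
#'   half-open).
#' @return The variants with a `gene` column (NA when intergenic).
#' @export
annotate_genes <- function(variants, gene_table) {
  variants$gene <- NA_character_
  if (nrow(variants) == 0 || nrow(gene_table) == 0) return(variants)
  vr <- GenomicRanges::GRanges(variants$contig,
                               IRanges::IRanges(variants$pos, variants$pos))
  gr <- GenomicRanges::GRanges(gene_table$contig,
                               IRanges::IRanges(gene_table$start + 1,
                                                gene_table$end))
  hits <- GenomicRanges::findOverlaps(vr, gr, select = "first")
  variants$gene <- gene_table$gene[hits]
  variants
}

#' Flag established oncogenic ("driver") variants
#'
#' SNVs and indels are flagged by lookup in a local driver table (gene plus
#' optional variant class and specific alteration).  SVs are flagged when
#' either breakpoint falls inside a listed gene body (events targeting known
#' oncogenes and tumor suppressors).
#'
#' @param variants data.frame with class, gene (for small variants) or
#'   contig/pos/contig2/pos2 (for SVs); fusions may carry gene5/gene3.
#' @param driver_table data.frame (gene, class, alteration); `class` may be
#'   "any", `alteration` NA for gene-level entries.
#' @param gene_table Gene coordinate table for SV breakpoint intersection.
#' @return Logical vector of oncogenic flags.
#' @export
annotate_oncogenic <- function(variants, driver_table, gene_table = NULL) {
  n <- nrow(variants)
  flags <- rep(FALSE, n)
  if (n == 0) return(flags)
  driver_genes <- function(cls) {
    driver_table$gene[driver_table$class %in% c(cls, "any")]
  }
  small <- variants$class %in% c("SNV", "indel")
  if (any(small)) {
    if (!"gene" %in% names(variants))
      stop_config("small variants need a gene column (see annotate_genes)")
    for (i in which(small)) {
      d <- driver_table[driver_table$gene %in% variants$gene[i] &
                          driver_table$class %in% c(variants$class[i], "any"), ,
                        drop = FALSE]
      if (nrow(d) == 0) next
      alt_spec <- d$alteration[!is.na(d$alteration)]
      flags[i] <- any(is.na(d$alteration)) ||
        (("alteration" %in% names(variants)) &&
           variants$alteration[i] %in% alt_spec)
    }
  }
  svlike <- variants$class %in% c("SV", "fusion")
  if (any(svlike)) {
    if (is.null(gene_table))
      stop_config("SV oncogenicity needs a gene_table")
    targets <- sv_gene_targeting(variants[svlike, , drop = FALSE], gene_table)
    dg <- driver_genes("SV")
    hit <- vapply(targets, function(g) any(g %in% dg), logical(1))
    fus <- variants$class[svlike] == "fusion"
    if (any(fus)) {
      fd <- driver_genes("fusion")
      hit[fus] <- hit[fus] |
        variants$gene5[svlike][fus] %in% fd |
        variants$gene3[svlike][fus] %in% fd
    }
    flags[svlike] <- hit
  }
  flags
}

#' Genes targeted by structural variants
#'
#' A gene is targeted when its body contains either breakpoint; deletions
#' additionally target genes fully contained between the breakpoints.
#'
#' @param svs data.frame with contig, pos, contig2, pos2, svtype.
#' @param gene_table Gene coordinate table (0-based half-open).
#' @return List (one element per SV) of targeted gene names.
#' @export
sv_gene_targeting <- function(svs, gene_table) {
  if (nrow(svs) == 0) return(list())
  gr <- GenomicRanges::GRanges(gene_table$contig,
                               IRanges::IRanges(gene_table$start + 1,
                                                gene_table$end))
  lapply(seq_len(nrow(svs)), function(i) {
    bp <- GenomicRanges::GRanges(
      c(svs$contig[i], svs$contig2[i]),
      IRanges::IRanges(c(svs$pos[i], svs$pos2[i]),
                       c(svs$pos[i], svs$pos2[i])))
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, bp)))
    genes <- gene_table$gene[hit]
    if (identical(svs$svtype[i], "DEL") && svs$contig[i] == svs$contig2[i]) {
      span <- GenomicRanges::GRanges(
        svs$contig[i], IRanges::IRanges(min(svs$pos[i], svs$pos2[i]),
                                        max(svs$pos[i], svs$pos2[i])))
      contained <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr, span, type = "within")))
      genes <- union(genes, gene_table$gene[contained])
    }
    genes
  })
}

#' Call expression biomarkers against a reference cohort
#'
#' A gene is overexpressed when its tumor TPM exceeds the 90th empirical
#' percentile of the reference cohort (severe: 95th) and underexpressed below
#' the 10th (severe: 5th).  Percentiles use linear interpolation between
#' cohort order statistics.
#'
#' @param tumor_tpm Named numeric vector of tumor TPM values.
#' @param reference Genes x samples reference TPM matrix.
#' @param actionable_genes Optional gene subset to assess.
#' @param min_cohort Minimum cohort values per gene (default 20).
#' @return data.frame: gene, tpm, percentile, call in {severe_over, over,
#'   under, severe_under, none}; genes absent from the reference (or with a
#'   thin cohort) get an NA call.
#' @export
expression_biomarkers <- function(tumor_tpm, reference,
                                  actionable_genes = NULL, min_cohort = 20) {
  genes <- names(tumor_tpm)
  if (!is.null(actionable_genes)) genes <- intersect(genes, actionable_genes)
  out <- data.frame(gene = genes, tpm = tumor_tpm[genes],
                    percentile = NA_real_, call = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (!g %in% rownames(reference)) next
    vals <- reference[g, ]
    vals <- vals[!is.na(vals)]
    if (length(vals) < min_cohort) next
    sv <- sort(vals)
    pct <- stats::approx(sv, seq(0, 1, length.out = length(sv)),
                         xout = out$tpm[i], rule = 2, ties = "ordered")$y
    out$percentile[i] <- pct
    out$call[i] <- if (pct > 0.95) "severe_over" else if (pct > 0.90) "over"
      else if (pct < 0.05) "severe_under" else if (pct < 0.10) "under"
      else "none"
  }
  rownames(out) <- NULL
  out
}

#' Expression biomarkers supported by an acquired SV, fusion or CN event
#'
#' A biomarker is SV-supported when its gene is targeted by an SV or is a
#' fusion partner, or when it lies on an amplified segment (total CN >= 2 x
#' ploidy, with overexpression) or a homozygously deleted segment (total CN
#' 0, with underexpression) — direction-consistent support only.
#'
#' @param biomarker_calls Output of [expression_biomarkers()].
#' @param svs SV data.frame (contig, pos, contig2, pos2, svtype), or NULL.
#' @param fusions Fusion data.frame with gene5/gene3, or NULL.
#' @param cn_segments CN segment data.frame, or NULL.
#' @param gene_table Gene coordinate table.
#' @param ploidy Tumor ploidy (default 2).
#' @return list: `supported` (subset of calls), `fraction` (supported over
#'   all non-`none` biomarker calls).
#' @export
sv_supported_biomarkers <- function(biomarker_calls, svs = NULL,
                                    fusions = NULL, cn_segments = NULL,
                                    gene_table, ploidy = 2) {
  calls <- biomarker_calls[!is.na(biomarker_calls$call) &
                             biomarker_calls$call != "none", , drop = FALSE]
  if (nrow(calls) == 0) return(list(supported = calls, fraction = NA_real_))
  sv_genes <- if (!is.null(svs) && nrow(svs) > 0)
    unique(unlist(sv_gene_targeting(svs, gene_table))) else character(0)
  fus_genes <- if (!is.null(fusions) && nrow(fusions) > 0)
    unique(c(fusions$gene5, fusions$gene3)) else character(0)
  gt <- gene_table[match(calls$gene, gene_table$gene), , drop = FALSE]
  mid <- floor((gt$start + gt$end) / 2)
  cn <- cn_at(cn_segments, gt$contig, mid + 1)
  over <- calls$call %in% c("over", "severe_over")
  under <- calls$call %in% c("under", "severe_under")
  supported <- calls$gene %in% c(sv_genes, fus_genes) |
    (over & cn$total_cn >= 2 * ploidy) |
    (under & cn$total_cn == 0)
  list(supported = calls[supported, , drop = FALSE],
       fraction = mean(supported))
}

#' Prioritize germline variants for review
#'
#' Retains variants that are rare (maximum population allele frequency below
#' `max_af`) and not over-recurrent in the cohort, or that carry a
#' pathogenic / likely-pathogenic clinical assertion (assertions override
#' the frequency filters).
#'
#' @param germline_consensus A `consensus_calls` data.frame (germline).
#' @param population_af Named numeric vector of max population AFs keyed by
#'   variant key; NULL skips the AF filter with a warning.
#' @param cohort_recurrence Named integer vector of cohort carrier counts by
#'   key (missing keys count 0).
#' @param assertions Named character vector of clinical assertions by key
#'   (e.g. "pathogenic", "likely_pathogenic", "benign").
#' @param max_af AF threshold (default 0.01).
#' @param recurrence_cap Maximum cohort recurrence (default Inf).
#' @return The retained subset with columns `population_af`, `recurrence`,
#'   `assertion`, `retained_by`.
#' @export
prioritize_germline <- function(germline_consensus, population_af = NULL,
                                cohort_recurrence = NULL, assertions = NULL,
                                max_af = 0.01, recurrence_cap = Inf) {
  g <- germline_consensus
  key <- g$key
  af <- if (is.null(population_af)) {
    warning("population AF table missing; AF filter skipped")
    rep(0, nrow(g))
  } else {
    a <- population_af[key]
    a[is.na(a)] <- 0
    a
  }
  rec <- if (is.null(cohort_recurrence)) rep(0, nrow(g)) else {
    r <- cohort_recurrence[key]; r[is.na(r)] <- 0; r
  }
  assert <- if (is.null(assertions)) rep(NA_character_, nrow(g)) else
    unname(assertions[key])
  pathogenic <- !is.na(assert) &
    assert %in% c("pathogenic", "likely_pathogenic")
  rare <- af < max_af & rec <= recurrence_cap
  keep <- pathogenic | rare
  out <- g[keep, , drop = FALSE]
  out$population_af <- af[keep]
  out$recurrence <- rec[keep]
  out$assertion <- assert[keep]
  out$retained_by <- ifelse(pathogenic[keep], "assertion", "rarity")
  out
}

# fixed precedence for multi-category findings
category_precedence <- c("diagnostic", "germline", "therapy_informing",
                         "driver_fusion", "prognostic")

assign_clinical_category <- function(findings) {
  getcol <- function(nm) {
    if (nm %in% names(findings)) findings[[nm]] else rep(FALSE, nrow(findings))
  }
  diag <- getcol("diagnostic_evidence")
  germ <- getcol("germline_pathogenic")
  ther <- getcol("therapy_evidence")
  prog <- getcol("prognostic_evidence")
  fus <- findings$type == "fusion" & getcol("oncogenic")
  cat <- rep("none", nrow(findings))
  cat[prog] <- "prognostic"
  cat[fus] <- "driver_fusion"
  cat[ther] <- "therapy_informing"
  cat[germ] <- "germline"
  cat[diag] <- "diagnostic"
  cat
}

#' Incremental findings of cWGTS over the matched panel assays
#'
#' Set difference of findings keyed per patient (variants by locus key,
#' fusions by gene pair, signatures by name); each incremental finding is
#' assigned one clinical-relevance category (diagnostic, germline,
#' therapy-informing, driver fusion, prognostic) by fixed precedence, or
#' `none` when no category evidence is recorded.
#'
#' @param cwgts_findings,panel_findings data.frames with columns patient_id,
#'   key, type, oncogenic, and optional evidence columns
#'   (diagnostic_evidence, prognostic_evidence, therapy_evidence,
#'   germline_pathogenic).
#' @return The incremental subset of `cwgts_findings` with a
#'   `clinical_category` column.
#' @export
incremental_findings <- function(cwgts_findings, panel_findings) {
  pk <- paste(panel_findings$patient_id, panel_findings$key)
  ck <- paste(cwgts_findings$patient_id, cwgts_findings$key)
  inc <- cwgts_findings[!(ck %in% pk), , drop = FALSE]
  inc$clinical_category <- assign_clinical_category(inc)
  rownames(inc) <- NULL
  inc
}

#' WES / RNA capturability of findings
#'
#' Infers which findings an exome (WES) or transcriptome (RNA-seq) assay
#' could in principle capture: coding SNVs/indels and SVs with a coding
#' breakpoint are WES-capturable, CN findings over coding genes likewise;
#' genome-wide signature/TMB/MSI findings are exome-derivable; fusion
#' transcripts and expression biomarkers are RNA-capturable; noncoding SVs
#' (e.g. enhancer hijacking without an expression biomarker record) are
#' capturable by neither.
#'
#' @param findings Findings data.frame with `type` and loci columns (contig,
#'   pos, contig2, pos2, gene as applicable).
#' @param coding_bed Coding mask data.frame (contig, start, end).
#' @param gene_table Gene coordinate table (for CN findings).
#' @return The findings with logical columns `wes_capturable`,
#'   `rna_capturable`.
#' @export
wes_rna_maskability <- function(findings, coding_bed, gene_table = NULL) {
  n <- nrow(findings)
  wes <- rep(FALSE, n); rna <- rep(FALSE, n)
  in_coding <- function(contig, pos) {
    ok <- !is.na(contig) & !is.na(pos)
    out <- rep(FALSE, length(pos))
    if (any(ok) && nrow(coding_bed) > 0) {
      out[ok] <- coding_mask(data.frame(contig = contig[ok], pos = pos[ok],
                                        class = "SNV"), coding_bed)$in_coding
    }
    out
  }
  small <- findings$type %in% c("SNV", "indel")
  wes[small] <- in_coding(findings$contig[small], findings$pos[small])
  svf <- findings$type %in% c("SV", "fusion")
  if (any(svf)) {
    wes[svf] <- in_coding(findings$contig[svf], findings$pos[svf]) |
      in_coding(findings$contig2[svf], findings$pos2[svf])
  }
  rna[findings$type == "fusion"] <- TRUE
  rna[findings$type == "biomarker"] <- TRUE
  wes[findings$type %in% c("signature", "TMB", "MSI")] <- TRUE
  if ("gene" %in% names(findings) && !is.null(gene_table)) {
    cnv <- findings$type == "CNA" & !is.na(findings$gene)
    if (any(cnv)) {
      gt <- gene_table[match(findings$gene[cnv], gene_table$gene), ,
                       drop = FALSE]
      mid <- floor((gt$start + gt$end) / 2) + 1
      wes[cnv] <- in_coding(gt$contig, mid) |
        vapply(seq_len(nrow(gt)), function(i) {
          any(coding_bed$contig == gt$contig[i] &
                coding_bed$start < gt$end[i] & coding_bed$end > gt$start[i])
        }, logical(1))
    }
  }
  findings$wes_capturable <- wes
  findings$rna_capturable <- rna
  findings
}

#' Cohort-level summary of incremental findings
#'
#' Per-cohort counts and rounded percentages: patients with at least one
#' incremental oncogenic finding; the clinically relevant subset and its
#' category breakdown; and how many of the incremental-finding patients
#' would be covered by WES alone, RNA-seq alone, or the two combined.
#'
#' @param findings Incremental findings data.frame (patient_id, oncogenic,
#'   clinical_category; optional wes_capturable / rna_capturable).
#' @param n_patients Total cohort size.
#' @param json_path Optional path to write the report as JSON.
#' @return list of class `cohort_report` with the counts and percentages.
#' @export
cohort_report <- function(findings, n_patients, json_path = NULL) {
  stopifnot(n_patients >= 1)
  pct <- function(k, n) if (n == 0) 0 else round_half_up(100 * k / n)
  onc <- findings[findings$oncogenic |
                    (findings$clinical_category == "germline"), , drop = FALSE]
  inc_patients <- unique(onc$patient_id)
  cr <- findings[findings$clinical_category != "none", , drop = FALSE]
  cr_patients <- unique(cr$patient_id)
  cat_pairs <- unique(cr[, c("patient_id", "clinical_category")])
  cat_counts <- table(factor(cat_pairs$clinical_category,
                             levels = category_precedence))
  cat_pct <- stats::setNames(
    vapply(as.integer(cat_counts), pct, numeric(1),
           n = length(cr_patients)),
    names(cat_counts))
  has_cap <- all(c("wes_capturable", "rna_capturable") %in% names(findings))
  cap <- if (has_cap) {
    by_pat <- split(onc, onc$patient_id)
    wes_p <- sum(vapply(by_pat, function(x) any(x$wes_capturable), logical(1)))
    rna_p <- sum(vapply(by_pat, function(x) any(x$rna_capturable), logical(1)))
    comb_p <- sum(vapply(by_pat, function(x)
      any(x$wes_capturable | x$rna_capturable), logical(1)))
    list(wes_patients = wes_p, rna_patients = rna_p,
         combined_patients = comb_p,
         wes_percent = pct(wes_p, length(inc_patients)),
         rna_percent = pct(rna_p, length(inc_patients)),
         combined_percent = pct(comb_p, length(inc_patients)))
  } else NULL
  report <- structure(list(
    schema_version = "1.0",
    n_patients = n_patients,
    patients_with_incremental = length(inc_patients),
    incremental_percent = pct(length(inc_patients), n_patients),
    clinically_relevant_patients = length(cr_patients),
    category_counts = as.list(as.integer(cat_counts)) |>
      stats::setNames(names(cat_counts)),
    category_percent = as.list(cat_pct),
    capturability = cap), class = "cohort_report")
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d (%g%%) with incremental oncogenic findings\n",
              x$n_patients, x$patients_with_incremental,
              x$incremental_percent))
  cat(sprintf("  clinically relevant in %d patients; categories: %s\n",
              x$clinically_relevant_patients,
              paste(sprintf("%s %d (%g%%)", names(x$category_counts),
                            unlist(x$category_counts),
                            unlist(x$category_percent)), collapse = ", ")))
  if (!is.null(x$capturability))
    cat(sprintf("  capturable by WES %d (%g%%), RNA %d (%g%%), combined %d (%g%%)\n",
                x$capturability$wes_patients, x$capturability$wes_percent,
                x$capturability$rna_patients, x$capturability$rna_percent,
                x$capturability$combined_patients,
                x$capturability$combined_percent))
  invisible(x)
}
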