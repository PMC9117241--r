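#' Configuration for a synthetic tumor
#'
#' Defines the clone tree (truncal clone at CCF 1 plus nested subclones), tumor
#' purity, per-clone mutation counts, signature mixture(s), copy-number events
#' and SV/fusion counts used by [simulate_tumor()].
#'
#' @param purity Tumor purity in (0, 1].
#' @param clones data.frame with columns `clone_id`, `parent_id` (NA for the
#'   truncal clone) and `ccf`.  The truncal clone must have CCF 1 and every
#'   child CCF must not exceed its parent's.
#' @param n_snv,n_indel Integer vectors of per-clone mutation counts, recycled
#'   to the number of clones.
#' @param n_sv,n_fusion Counts of structural variants / fusions (assigned to
#'   the truncal clone).
#' @param signature_mix Named numeric vector of exposure fractions over the
#'   catalog (sums to 1), or a list with one such vector per clone.
#' @param catalog A `signature_catalog` (default the bundled synthetic one).
#' @param n_cn_events Number of non-diploid copy-number segments to place.
#' @param cn_segments Optional explicit data.frame (contig, start, end,
#'   total_cn, major_cn) overriding `n_cn_events`.
#' @return A list of class `tumor_config`.
#' @export
tumor_config <- function(purity = 0.6,
                         clones = data.frame(clone_id = c("C1", "C2"),
                                             parent_id = c(NA, "C1"),
                                             ccf = c(1, 0.4)),
                         n_snv = c(300, 150),
                         n_indel = c(30, 15),
                         n_sv = 8,
                         n_fusion = 2,
                         signature_mix = c(SBS_A = 0.6, SBS_B = 0.4),
                         catalog = synthetic_signature_catalog(),
                         n_cn_events = 3,
                         cn_segments = NULL) {
  if (purity <= 0 || purity > 1) stop_config("purity must lie in (0, 1]")
  if (abs(clones$ccf[1] - 1) > 1e-12)
    stop_config("the truncal (first) clone must have CCF = 1")
  for (i in seq_len(nrow(clones))) {
    p <- clones$parent_id[i]
    if (!is.na(p)) {
      pc <- clones$ccf[match(p, clones$clone_id)]
      if (is.na(pc)) stop_config("unknown parent clone '%s'", p)
      if (clones$ccf[i] > pc + 1e-12)
        stop_config("clone '%s' CCF (%g) exceeds its parent's (%g)",
                    clones$clone_id[i], clones$ccf[i], pc)
    }
  }
  if (any(clones$ccf <= 0)) stop_config("clone CCFs must be positive")
  mixes <- if (is.list(signature_mix)) signature_mix else
    rep(list(signature_mix), nrow(clones))
  if (length(mixes) != nrow(clones))
    stop_config("signature_mix list must have one entry per clone")
  for (mx in mixes) {
    if (abs(sum(mx) - 1) > 1e-9)
      stop_config("signature mix must sum to 1 (got %g)", sum(mx))
    if (!all(names(mx) %in% catalog$signatures))
      stop_config("signature mix names must be catalog signatures")
  }
  structure(list(purity = purity, clones = clones,
                 n_snv = rep_len(as.integer(n_snv), nrow(clones)),
                 n_indel = rep_len(as.integer(n_indel), nrow(clones)),
                 n_sv = as.integer(n_sv), n_fusion = as.integer(n_fusion),
                 signature_mixes = mixes, catalog = catalog,
                 n_cn_events = as.integer(n_cn_events),
                 cn_segments = cn_segments),
            class = "tumor_config")
}

#' Expected variant allele fraction of a mutation
#'
#' For a mutation present in a fraction `ccf` of tumor cells at multiplicity
#' `multiplicity` on a segment of total copy number `total_cn`, in a sample of
#' purity `purity` (normal cells diploid), the expected VAF is
#' `m * ccf * p / (p * CNt + 2 * (1 - p))`.  This is the exact inverse of
#' [ccf_from_vaf()].
#'
#' @param ccf Cancer cell fraction in (0, 1].
#' @param purity Sample purity (or cfDNA tumor fraction) in (0, 1].
#' @param total_cn Total tumor copy number at the locus (>= 1).
#' @param multiplicity Mutation copies per tumor cell, 1 <= m <= total_cn.
#' @return Expected VAF, in (0, 1].
#' @export
expected_vaf <- function(ccf, purity, total_cn, multiplicity = 1) {
  n <- max(length(ccf), length(purity), length(total_cn), length(multiplicity))
  ccf <- rep_len(ccf, n); purity <- rep_len(purity, n)
  total_cn <- rep_len(total_cn, n); multiplicity <- rep_len(multiplicity, n)
  if (any(ccf <= 0 | ccf > 1)) stop_config("ccf must lie in (0, 1]")
  if (any(purity <= 0 | purity > 1)) stop_config("purity must lie in (0, 1]")
  if (any(total_cn < 1)) stop_config("total_cn must be >= 1")
  if (any(multiplicity < 1)) stop_config("multiplicity must be >= 1")
  if (any(multiplicity > total_cn))
    stop_config("multiplicity cannot exceed total_cn")
  multiplicity * ccf * purity / (purity * total_cn + 2 * (1 - purity))
}

# default CN landscape: diploid background plus a few altered segments
default_cn_segments <- function(genome, n_events) {
  segs <- data.frame(contig = genome$contigs$name, start = 0,
                     end = genome$contigs$length, total_cn = 2, major_cn = 1)
  if (n_events == 0) return(segs)
  event_types <- data.frame(total_cn = c(3, 8, 1, 4),
                            major_cn = c(2, 7, 1, 2))
  out <- list()
  for (i in seq_len(nrow(segs))) {
    ct <- segs$contig[i]; len <- segs$end[i]
    k <- sum(seq_len(n_events) %% nrow(segs) == (i - 1) %% nrow(segs))
    if (k == 0) { out[[length(out) + 1]] <- segs[i, ]; next }
    # carve k event windows out of the diploid contig
    bounds <- sort(sample(seq(1000, len - 1000, by = 1000), 2 * k))
    cur <- 0
    for (j in seq_len(k)) {
      ev <- event_types[((i + j) %% nrow(event_types)) + 1, ]
      if (bounds[2 * j - 1] > cur)
        out[[length(out) + 1]] <- data.frame(contig = ct, start = cur,
                                             end = bounds[2 * j - 1],
                                             total_cn = 2, major_cn = 1)
      out[[length(out) + 1]] <- data.frame(contig = ct,
                                           start = bounds[2 * j - 1],
                                           end = bounds[2 * j],
                                           total_cn = ev$total_cn,
                                           major_cn = ev$major_cn)
      cur <- bounds[2 * j]
    }
    if (cur < len)
      out[[length(out) + 1]] <- data.frame(contig = ct, start = cur, end = len,
                                           total_cn = 2, major_cn = 1)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Total/major copy number at genomic positions
#'
#' @param cn_segments data.frame (contig, start, end, total_cn, major_cn);
#'   0-based half-open segments.
#' @param contig,pos Vectors of 1-based positions.
#' @return data.frame with columns total_cn, major_cn (diploid 2/1 where no
#'   segment covers the position).
#' @export
cn_at <- function(cn_segments, contig, pos) {
  total <- rep(2, length(pos)); major <- rep(1, length(pos))
  if (!is.null(cn_segments) && nrow(cn_segments) > 0) {
    for (i in seq_len(nrow(cn_segments))) {
      hit <- contig == cn_segments$contig[i] &
        pos - 1 >= cn_segments$start[i] & pos - 1 < cn_segments$end[i]
      total[hit] <- cn_segments$total_cn[i]
      major[hit] <- cn_segments$major_cn[i]
    }
  }
  data.frame(total_cn = total, major_cn = major)
}

#' Simulate a synthetic tumor from a genome
#'
#' Draws clone-labelled SNVs (with trinucleotide contexts sampled from the
#' configured signature mixture and placed at genome positions actually
#' carrying those contexts), indels (1-10 bp), structural variants (breakpoint
#' pairs with orientation) and gene fusions, on top of a copy-number landscape.
#' Variant loci are unique.  Deterministic for a fixed seed.
#'
#' @param genome A `synthetic_genome`.
#' @param config A [tumor_config()].
#' @param seed Integer seed.
#' @return A list of class `tumor_truth`: `purity`, `clones`, `variants`
#'   (data.frame with id, class, clone_id, ccf, loci, alleles, multiplicity,
#'   context), `cn_segments`, `signature_mixes`, `catalog`, `genome`.
#' @export
simulate_tumor <- function(genome, config = tumor_config(), seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(config, "tumor_config"))
  with_seed(seed, {
    cn_segs <- config$cn_segments %||% default_cn_segments(genome, config$n_cn_events)
    ctx_index <- build_context_index(genome)
    clones <- config$clones
    ctx_names <- sbs_contexts()
    ctx_info <- parse_context(ctx_names)
    # pyrimidine-context key as stored in the index ("<up><ref><down>")
    ctx_tri <- paste0(ctx_info$up, ctx_info$ref, ctx_info$down)

    vrows <- list()
    vid <- 0L
    add_row <- function(df) vrows[[length(vrows) + 1L]] <<- df

    # ---- SNVs: contexts from the signature mixture, loci from the index ----
    # per (clone, context) demand, then one draw per context bucket: buckets
    # are disjoint by construction so SNV loci are automatically unique
    demand <- matrix(0L, nrow = 96, ncol = nrow(clones))
    for (ci in seq_len(nrow(clones))) {
      n <- config$n_snv[ci]
      if (n == 0) next
      mix <- config$signature_mixes[[ci]]
      p96 <- as.vector(config$catalog$matrix[, names(mix), drop = FALSE] %*% mix)
      demand[, ci] <- as.vector(stats::rmultinom(1, n, p96))
    }
    for (k in which(rowSums(demand) > 0)) {
      need <- sum(demand[k, ])
      bucket <- ctx_index[[ctx_tri[k]]]
      if (is.null(bucket) || nrow(bucket) < need)
        stop_config("genome too small to place %d SNVs in context %s",
                    need, ctx_tri[k])
      pick <- bucket[sample.int(nrow(bucket), need), , drop = FALSE]
      clone_lab <- rep(clones$clone_id, demand[k, ])
      ccf_lab <- rep(clones$ccf, demand[k, ])
      b <- substring(genome$sequence[pick$contig], pick$pos, pick$pos)
      alt <- ifelse(b %in% c("C", "T"), ctx_info$alt[k],
                    chartr("ACGT", "TGCA", ctx_info$alt[k]))
      add_row(data.frame(
        id = sprintf("V%05d", vid + seq_len(need)), class = "SNV",
        clone_id = clone_lab, ccf = ccf_lab,
        contig = pick$contig, pos = pick$pos, ref = b, alt = alt,
        context = ctx_names[k], stringsAsFactors = FALSE))
      vid <- vid + need
    }

    used_keys <- if (length(vrows))
      unlist(lapply(vrows, function(d) paste0(d$contig, ":", d$pos))) else
        character(0)
    sample_free_locus <- function(margin = 12L) {
      repeat {
        ct <- sample(genome$contigs$name, 1,
                     prob = genome$contigs$length)
        len <- genome$contigs$length[genome$contigs$name == ct]
        p <- sample.int(len - 2L * margin, 1L) + margin
        key <- paste0(ct, ":", p)
        if (!key %in% used_keys) {
          used_keys <<- c(used_keys, key)
          return(list(contig = ct, pos = p))
        }
      }
    }

    # ---- indels: 1-10 bp, VCF-style anchored representation ----
    for (ci in seq_len(nrow(clones))) {
      n <- config$n_indel[ci]
      for (j in seq_len(n)) {
        loc <- sample_free_locus()
        vid <- vid + 1L
        ilen <- sample.int(10L, 1L)
        if (stats::runif(1) < 0.5) {  # deletion
          ref <- substring(genome$sequence[[loc$contig]], loc$pos, loc$pos + ilen)
          alt <- substring(ref, 1, 1)
        } else {                      # insertion
          ref <- base_at(genome, loc$contig, loc$pos)
          alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), ilen,
                                          replace = TRUE), collapse = ""))
        }
        add_row(data.frame(
          id = sprintf("V%05d", vid), class = "indel",
          clone_id = clones$clone_id[ci], ccf = clones$ccf[ci],
          contig = loc$contig, pos = loc$pos, ref = ref, alt = alt,
          context = NA_character_, stringsAsFactors = FALSE))
      }
    }

    # ---- SVs: breakpoint pairs with orientation ----
    sv_types <- c("DEL", "DUP", "INV", "TRA")
    sv_orient <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                      INV = c("+", "+"), TRA = NULL)
    svs <- list()
    for (j in seq_len(config$n_sv)) {
      type <- sv_types[((j - 1) %% 4) + 1]
      if (type == "TRA" && nrow(genome$contigs) >= 2) {
        cts <- sample(genome$contigs$name, 2)
        a <- sample_free_locus(); b <- sample_free_locus()
        o <- sample(c("+", "-"), 2, replace = TRUE)
      } else {
        a <- sample_free_locus(); b <- sample_free_locus()
        while (b$contig != a$contig) b <- sample_free_locus()
        if (b$pos < a$pos) { tmp <- a; a <- b; b <- tmp }
        o <- sv_orient[[type]] %||% sample(c("+", "-"), 2, replace = TRUE)
      }
      vid <- vid + 1L
      svs[[length(svs) + 1L]] <- data.frame(
        id = sprintf("V%05d", vid), class = "SV",
        clone_id = clones$clone_id[1], ccf = 1,
        contig = a$contig, pos = a$pos, contig2 = b$contig, pos2 = b$pos,
        strand1 = o[1], strand2 = o[2], svtype = type,
        stringsAsFactors = FALSE)
    }

    # ---- fusions: SVs joining two gene bodies, ordered 5' -> 3' ----
    fusions <- list()
    if (config$n_fusion > 0 && nrow(genome$genes) >= 2) {
      for (j in seq_len(config$n_fusion)) {
        gs <- genome$genes[sample.int(nrow(genome$genes), 2), ]
        p1 <- sample(seq(gs$start[1] + 1, gs$end[1]), 1)
        p2 <- sample(seq(gs$start[2] + 1, gs$end[2]), 1)
        vid <- vid + 1L
        fusions[[length(fusions) + 1L]] <- data.frame(
          id = sprintf("V%05d", vid), class = "fusion",
          clone_id = clones$clone_id[1], ccf = 1,
          contig = gs$contig[1], pos = p1, contig2 = gs$contig[2], pos2 = p2,
          strand1 = "+", strand2 = "-", svtype = "TRA",
          gene5 = gs$gene[1], gene3 = gs$gene[2],
          stringsAsFactors = FALSE)
      }
    }

    small <- if (length(vrows)) do.call(rbind, vrows) else NULL
    pad <- function(df, cols) { for (cc in cols) df[[cc]] <- df[[cc]] %||% NA; df }
    all_cols <- c("id", "class", "clone_id", "ccf", "contig", "pos", "ref",
                  "alt", "context", "contig2", "pos2", "strand1", "strand2",
                  "svtype", "gene5", "gene3")
    fill <- function(df) {
      if (is.null(df)) return(NULL)
      for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA
      df[, all_cols]
    }
    variants <- do.call(rbind, Filter(Negate(is.null), list(
      fill(small),
      fill(if (length(svs)) do.call(rbind, svs) else NULL),
      fill(if (length(fusions)) do.call(rbind, fusions) else NULL))))
    rownames(variants) <- NULL

    # multiplicity: 1, or up to the major CN for a minority of clonal SNVs
    cn <- cn_at(cn_segs, variants$contig, variants$pos)
    mult <- rep(1L, nrow(variants))
    upgradable <- which(cn$major_cn > 1 & variants$ccf == 1 &
                          variants$class %in% c("SNV", "indel"))
    if (length(upgradable) > 0) {
      up <- upgradable[stats::runif(length(upgradable)) < 0.25]
      mult[up] <- cn$major_cn[up]
    }
    variants$multiplicity <- mult
    variants$total_cn <- cn$total_cn
    variants$major_cn <- cn$major_cn

    structure(list(purity = config$purity, clones = clones,
                   variants = variants, cn_segments = cn_segs,
                   signature_mixes = config$signature_mixes,
                   catalog = config$catalog, genome = genome,
                   config = config),
              class = "tumor_truth")
  })
}

#' Configuration of a sequencing assay over a simulated tumor
#'
#' @param name Assay label (`"wgs"`, `"panel"`, `"cfdna"`, ...).
#' @param mean_depth Mean sequencing depth (negative-binomial mean).
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed; default 10 mimics real WGS depth spread).
#' @param purity Assay-specific purity; defaults to the tumor's purity.  A
#'   panel biopsy may carry its own purity.
#' @param clones Optional character vector of clone ids present in this
#'   biopsy (ITH scenarios); variants of absent clones yield zero alt reads.
#' @param classes Variant classes to observe.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(name = "wgs", mean_depth = 100, dispersion = 10,
                         purity = NULL, clones = NULL,
                         classes = c("SNV", "indel")) {
  if (mean_depth <= 0) stop_config("mean_depth must be positive")
  if (dispersion <= 0) stop_config("dispersion must be positive")
  if (!is.null(purity) && (purity <= 0 || purity > 1))
    stop_config("assay purity must lie in (0, 1]")
  structure(list(name = name, mean_depth = mean_depth, dispersion = dispersion,
                 purity = purity, clones = clones, classes = classes),
            class = "assay_config")
}

#' Simulate per-variant read observations for an assay
#'
#' Depth is drawn per variant from a negative binomial around the assay mean;
#' alt reads are binomial with success probability [expected_vaf()] given the
#' variant's CCF, the assay purity and the local copy number.  Variants of
#' clones absent from the assay's biopsy have expected VAF 0.
#'
#' @param truth A `tumor_truth`.
#' @param config An [assay_config()].
#' @param seed Integer seed.
#' @return data.frame of observations: variant_id, assay, class, contig, pos,
#'   ref, alt, depth, alt_reads, purity, local_cn, multiplicity, ccf,
#'   vaf_true.
#' @export
simulate_assay <- function(truth, config = assay_config(), seed = 1L) {
  stopifnot(inherits(truth, "tumor_truth"), inherits(config, "assay_config"))
  with_seed(seed, {
    v <- truth$variants[truth$variants$class %in% config$classes, , drop = FALSE]
    purity <- config$purity %||% truth$purity
    present <- if (is.null(config$clones)) rep(TRUE, nrow(v)) else
      v$clone_id %in% config$clones
    vaf <- numeric(nrow(v))
    if (any(present))
      vaf[present] <- expected_vaf(v$ccf[present], purity, v$total_cn[present],
                                   v$multiplicity[present])
    depth <- stats::rnbinom(nrow(v), size = config$dispersion,
                            mu = config$mean_depth)
    alt <- stats::rbinom(nrow(v), depth, vaf)
    data.frame(variant_id = v$id, assay = config$name, class = v$class,
               contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
               depth = depth, alt_reads = alt, purity = purity,
               local_cn = v$total_cn, multiplicity = v$multiplicity,
               ccf = ifelse(present, v$ccf, 0), vaf_true = vaf,
               stringsAsFactors = FALSE)
  })
}

#' Simulate cell-free DNA observations
#'
#' cfDNA is modelled as a WGS assay whose purity is the circulating tumor
#' fraction.  Optionally a cfDNA-private subclone (variants absent from the
#' tissue truth) is added, emulating therapy-exposed subclones in circulation.
#'
#' @param truth A `tumor_truth`.
#' @param tumor_fraction Circulating tumor DNA fraction, strictly in (0, 1).
#' @param mean_depth,dispersion Depth model (default 100x).
#' @param private_clone Optional list(`ccf`, `n_snv`) describing a
#'   cfDNA-private subclone.
#' @param seed Integer seed.
#' @return list with `observations` (as [simulate_assay()]), `truth`
#'   (possibly extended with the private clone) and `private_variant_ids`.
#' @export
simulate_cfdna <- function(truth, tumor_fraction, mean_depth = 100,
                           dispersion = 10, private_clone = NULL, seed = 1L) {
  if (tumor_fraction <= 0 || tumor_fraction >= 1)
    stop_config("tumor_fraction must lie strictly in (0, 1)")
  with_seed(seed, {
    cf_truth <- truth
    private_ids <- character(0)
    if (!is.null(private_clone)) {
      pc_ccf <- private_clone$ccf %||% 0.3
      n_priv <- private_clone$n_snv %||% 50
      genome <- truth$genome
      existing <- paste0(truth$variants$contig, ":", truth$variants$pos)
      rows <- list()
      while (length(rows) < n_priv) {
        ct <- sample(genome$contigs$name, 1, prob = genome$contigs$length)
        len <- genome$contigs$length[genome$contigs$name == ct]
        p <- sample.int(len - 20L, 1L) + 10L
        key <- paste0(ct, ":", p)
        if (key %in% existing) next
        existing <- c(existing, key)
        b <- base_at(genome, ct, p)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("CF%05d", length(rows) + 1L), class = "SNV",
          clone_id = "CF_PRIVATE", ccf = pc_ccf, contig = ct, pos = p,
          ref = b, alt = sample(setdiff(c("A", "C", "G", "T"), b), 1),
          context = NA_character_, contig2 = NA, pos2 = NA, strand1 = NA,
          strand2 = NA, svtype = NA, gene5 = NA, gene3 = NA,
          stringsAsFactors = FALSE)
      }
      priv <- do.call(rbind, rows)
      cn <- cn_at(truth$cn_segments, priv$contig, priv$pos)
      priv$multiplicity <- 1L
      priv$total_cn <- cn$total_cn
      priv$major_cn <- cn$major_cn
      cf_truth$variants <- rbind(truth$variants, priv)
      cf_truth$clones <- rbind(truth$clones,
                               data.frame(clone_id = "CF_PRIVATE",
                                          parent_id = truth$clones$clone_id[1],
                                          ccf = pc_ccf))
      private_ids <- priv$id
    }
    obs <- simulate_assay(cf_truth,
                          assay_config(name = "cfdna", mean_depth = mean_depth,
                                       dispersion = dispersion,
                                       purity = tumor_fraction),
                          seed = sample.int(.Machine$integer.max, 1))
    list(observations = obs, truth = cf_truth,
         private_variant_ids = private_ids)
  })
}
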