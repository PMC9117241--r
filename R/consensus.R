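#' Normalize small-variant records before merging
#'
#' Splits multi-allelic records into biallelic ones, trims shared
#' leading/trailing bases, and (when the reference genome is supplied)
#' left-aligns indels, so that callers emitting different padded
#' representations of the same event merge onto one key of
#' (chromosome, position, ref, alt).
#'
#' @param calls Call data.frame (contig, pos, ref, alt, ...).
#' @param genome Optional `synthetic_genome` for left-alignment.
#' @return Normalized call data.frame.
#' @export
normalize_small_variants <- function(calls, genome = NULL) {
  if (nrow(calls) == 0) return(calls)
  multi <- grepl(",", calls$alt, fixed = TRUE)
  if (any(multi)) {
    split_rows <- lapply(which(multi), function(i) {
      alts <- strsplit(calls$alt[i], ",", fixed = TRUE)[[1]]
      r <- calls[rep(i, length(alts)), , drop = FALSE]
      r$alt <- alts
      r
    })
    calls <- rbind(calls[!multi, , drop = FALSE], do.call(rbind, split_rows))
  }
  getbase <- if (is.null(genome)) NULL else
    function(ct, p) base_at(genome, ct, p)
  for (i in seq_len(nrow(calls))) {
    nm <- normalize_allele(calls$contig[i], calls$pos[i], calls$ref[i],
                           calls$alt[i], getbase)
    calls$pos[i] <- nm$pos; calls$ref[i] <- nm$ref; calls$alt[i] <- nm$alt
  }
  rownames(calls) <- NULL
  calls
}

# trim + left-align a single (pos, ref, alt) against the reference
normalize_allele <- function(contig, pos, ref, alt, getbase = NULL) {
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn > 0 && an > 0 && (rn > 1 || an > 1) &&
        substr(ref, rn, rn) == substr(alt, an, an)) {
      ref <- substr(ref, 1, rn - 1); alt <- substr(alt, 1, an - 1)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (is.null(getbase) || pos <= 1) {
          # cannot extend left; re-anchor with the chopped base and stop
          b <- substr(paste0(ref, alt, "N"), 1, 1)
          ref <- paste0(ref, b); alt <- paste0(alt, b)
          break
        }
        pos <- pos - 1
        b <- getbase(contig, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

check_contig_namespaces <- function(callsets, genome = NULL) {
  contigs <- unique(unlist(lapply(callsets, function(x) unique(x$contig))))
  if (is.null(contigs) || length(contigs) == 0) return(invisible(TRUE))
  if (!is.null(genome)) {
    bad <- setdiff(contigs, genome$contigs$name)
    if (length(bad) > 0)
      stop_config("callset contigs not in reference: %s",
                  paste(bad, collapse = ", "))
  } else {
    pref <- grepl("^chr", contigs)
    if (any(pref) && !all(pref))
      stop_config("mismatched contig namespaces across callsets (chr-prefixed and bare names)")
  }
  invisible(TRUE)
}

#' Merge per-caller small-variant call sets into consensus variants
#'
#' Records are keyed by (chromosome, position, reference allele, alternative
#' allele) after normalization; a variant is high-confidence when passed by at
#' least 2 callers and not flagged by the panel of normals.
#'
#' @param callsets Named list of per-caller call data.frames (contig, pos,
#'   ref, alt; optional class, filter, truth_id columns).  Only records with
#'   `filter == "PASS"` are merged when a filter column is present.
#' @param genome Optional `synthetic_genome` for indel left-alignment.
#' @param pon_alt_counts Optional panel-of-normals alt-read count matrix (rows
#'   named by variant key) passed to [pon_filter()].
#' @return data.frame of class `consensus_calls`: key, contig, pos, ref, alt,
#'   class, callers (comma-joined), n_callers, pon_filtered, high_confidence,
#'   truth_id.
#' @export
merge_small_variants <- function(callsets, genome = NULL,
                                 pon_alt_counts = NULL) {
  stopifnot(is.list(callsets))
  if (is.null(names(callsets)) || any(names(callsets) == ""))
    names(callsets) <- paste0("caller", seq_along(callsets))
  check_contig_namespaces(callsets, genome)
  recs <- list()
  for (cn in names(callsets)) {
    x <- callsets[[cn]]
    if (is.null(x) || nrow(x) == 0) next
    if ("filter" %in% names(x)) x <- x[x$filter == "PASS", , drop = FALSE]
    if (nrow(x) == 0) next
    x <- normalize_small_variants(x, genome)
    x$caller <- cn
    if (!"class" %in% names(x))
      x$class <- ifelse(nchar(x$ref) == 1 & nchar(x$alt) == 1, "SNV", "indel")
    if (!"truth_id" %in% names(x)) x$truth_id <- NA_character_
    recs[[cn]] <- x[, c("contig", "pos", "ref", "alt", "class", "caller",
                        "truth_id")]
  }
  if (length(recs) == 0) return(empty_consensus())
  all <- do.call(rbind, recs)
  all$key <- variant_key(all$contig, all$pos, all$ref, all$alt)
  sp <- split(all, all$key)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(key = g$key[1], contig = g$contig[1], pos = g$pos[1],
               ref = g$ref[1], alt = g$alt[1], class = g$class[1],
               callers = paste(sort(unique(g$caller)), collapse = ","),
               n_callers = length(unique(g$caller)),
               truth_id = if (all(is.na(g$truth_id))) NA_character_ else
                 stats::na.omit(g$truth_id)[1],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$contig, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$pon_filtered <- FALSE
  out$high_confidence <- out$n_callers >= 2
  class(out) <- c("consensus_calls", "data.frame")
  if (!is.null(pon_alt_counts)) out <- pon_filter(out, pon_alt_counts)
  out
}

empty_consensus <- function() {
  out <- data.frame(key = character(), contig = character(), pos = numeric(),
                    ref = character(), alt = character(), class = character(),
                    callers = character(), n_callers = integer(),
                    truth_id = character(), pon_filtered = logical(),
                    high_confidence = logical())
  class(out) <- c("consensus_calls", "data.frame")
  out
}

#' Panel-of-normals artifact filter
#'
#' A variant is flagged as a recurrent sequencing artifact when at least
#' `min_alt` mutant alleles are observed in at least `min_fraction` (default
#' 1%, inclusive boundary) of the unmatched normal samples.  Variants missing
#' from the count table are treated as absent from all normals.
#'
#' @param consensus A `consensus_calls` data.frame.
#' @param pon_alt_counts Matrix of alt-read counts, rows named by variant key
#'   (`contig:pos:ref:alt`), one column per normal sample.
#' @param min_alt Minimum mutant alleles per normal (default 3).
#' @param min_fraction Minimum fraction of normals (default 0.01).
#' @return The consensus data.frame with `pon_filtered` set and
#'   `high_confidence` updated (>= 2 callers and not PoN-filtered).
#' @export
pon_filter <- function(consensus, pon_alt_counts, min_alt = 3,
                       min_fraction = 0.01) {
  n_normals <- ncol(pon_alt_counts)
  if (is.null(n_normals) || n_normals == 0)
    stop_config("panel of normals must contain at least one sample")
  frac <- rep(0, nrow(consensus))
  hit <- consensus$key %in% rownames(pon_alt_counts)
  if (any(hit)) {
    counts <- pon_alt_counts[consensus$key[hit], , drop = FALSE]
    frac[hit] <- rowSums(counts >= min_alt) / n_normals
  }
  consensus$pon_filtered <- frac >= min_fraction
  consensus$high_confidence <- consensus$n_callers >= 2 & !consensus$pon_filtered
  consensus
}

#' Merge per-caller structural-variant call sets
#'
#' Records are single-linkage clustered: two records join when both
#' breakpoints lie within `window_bp` and their orientations match.  The
#' cluster representative takes the median breakpoint positions; support is
#' the number of distinct callers in the cluster.
#'
#' @param callsets Named list of SV call data.frames (contig, pos, strand1,
#'   contig2, pos2, strand2, svtype; optional truth_id).
#' @param window_bp Breakpoint clustering window (default 200 bp).
#' @return data.frame of class `consensus_svs`: contig, pos, strand1,
#'   contig2, pos2, strand2, svtype, callers, n_callers, high_confidence,
#'   truth_id.
#' @export
merge_svs <- function(callsets, window_bp = 200) {
  if (is.null(names(callsets)) || any(names(callsets) == ""))
    names(callsets) <- paste0("caller", seq_along(callsets))
  recs <- list()
  for (cn in names(callsets)) {
    x <- callsets[[cn]]
    if (is.null(x) || nrow(x) == 0) next
    bad <- is.na(x$contig2) | is.na(x$pos2)
    if (any(bad)) {
      warning(sprintf("%s: %d SV record(s) missing mate information, excluded",
                      cn, sum(bad)))
      x <- x[!bad, , drop = FALSE]
    }
    if (nrow(x) == 0) next
    x$caller <- cn
    if (!"truth_id" %in% names(x)) x$truth_id <- NA_character_
    # canonical breakpoint order so reciprocal representations compare equal
    swap <- x$contig2 < x$contig | (x$contig2 == x$contig & x$pos2 < x$pos)
    if (any(swap)) {
      tmp <- x[swap, c("contig", "pos", "strand1")]
      x[swap, c("contig", "pos", "strand1")] <-
        x[swap, c("contig2", "pos2", "strand2")]
      x[swap, c("contig2", "pos2", "strand2")] <- tmp
    }
    recs[[cn]] <- x
  }
  if (length(recs) == 0)
    return(structure(data.frame(contig = character(), pos = numeric(),
                                strand1 = character(), contig2 = character(),
                                pos2 = numeric(), strand2 = character(),
                                svtype = character(), callers = character(),
                                n_callers = integer(),
                                high_confidence = logical(),
                                truth_id = character()),
                     class = c("consensus_svs", "data.frame")))
  all <- do.call(rbind, lapply(recs, function(x)
    x[, c("contig", "pos", "strand1", "contig2", "pos2", "strand2", "svtype",
          "caller", "truth_id")]))
  rownames(all) <- NULL
  n <- nrow(all)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    ok <- all$contig[i] == all$contig[j] & all$contig2[i] == all$contig2[j] &
      all$strand1[i] == all$strand1[j] & all$strand2[i] == all$strand2[j] &
      abs(all$pos[i] - all$pos[j]) <= window_bp &
      abs(all$pos2[i] - all$pos2[j]) <= window_bp
    edges <- cbind(i[ok], j[ok])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    grp <- all[idx, , drop = FALSE]
    data.frame(contig = grp$contig[1],
               pos = stats::median(grp$pos),
               strand1 = grp$strand1[1],
               contig2 = grp$contig2[1],
               pos2 = stats::median(grp$pos2),
               strand2 = grp$strand2[1],
               svtype = grp$svtype[1],
               callers = paste(sort(unique(grp$caller)), collapse = ","),
               n_callers = length(unique(grp$caller)),
               truth_id = if (all(is.na(grp$truth_id))) NA_character_ else
                 stats::na.omit(grp$truth_id)[1],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$contig, out$pos, out$contig2, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out$high_confidence <- out$n_callers >= 2
  class(out) <- c("consensus_svs", "data.frame")
  out
}

#' Merge per-caller fusion call sets by ordered gene pair
#'
#' @param callsets Named list of fusion call data.frames with columns
#'   `gene5`, `gene3` (ordered 5' to 3'); records with only an unordered
#'   `gene_a`/`gene_b` pair are normalized alphabetically with a warning.
#' @return data.frame of class `consensus_fusions`: gene5, gene3, callers,
#'   n_callers, high_confidence (>= 2 callers), truth_id.
#' @export
merge_fusions <- function(callsets) {
  if (is.null(names(callsets)) || any(names(callsets) == ""))
    names(callsets) <- paste0("caller", seq_along(callsets))
  recs <- list()
  for (cn in names(callsets)) {
    x <- callsets[[cn]]
    if (is.null(x) || nrow(x) == 0) next
    if (!all(c("gene5", "gene3") %in% names(x))) {
      if (all(c("gene_a", "gene_b") %in% names(x))) {
        warning(sprintf("%s: unordered gene pairs normalized alphabetically", cn))
        x$gene5 <- pmin(x$gene_a, x$gene_b)
        x$gene3 <- pmax(x$gene_a, x$gene_b)
      } else stop_config("fusion callset '%s' lacks gene pair columns", cn)
    }
    x$caller <- cn
    if (!"truth_id" %in% names(x)) x$truth_id <- NA_character_
    recs[[cn]] <- x[, c("gene5", "gene3", "caller", "truth_id")]
  }
  if (length(recs) == 0)
    return(structure(data.frame(gene5 = character(), gene3 = character(),
                                callers = character(), n_callers = integer(),
                                high_confidence = logical(),
                                truth_id = character()),
                     class = c("consensus_fusions", "data.frame")))
  all <- do.call(rbind, recs)
  all$pair <- paste(all$gene5, all$gene3, sep = "|")
  out <- do.call(rbind, lapply(split(all, all$pair), function(g) {
    data.frame(gene5 = g$gene5[1], gene3 = g$gene3[1],
               callers = paste(sort(unique(g$caller)), collapse = ","),
               n_callers = length(unique(g$caller)),
               truth_id = if (all(is.na(g$truth_id))) NA_character_ else
                 stats::na.omit(g$truth_id)[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$high_confidence <- out$n_callers >= 2
  class(out) <- c("consensus_fusions", "data.frame")
  out
}

#' Merge germline call sets from exactly two callers
#'
#' Germline variants called by both callers are high-confidence; variants
#' called by a single caller are retained at low confidence.
#'
#' @param callsets Named list of exactly two call data.frames.
#' @param genome Optional `synthetic_genome` for normalization.
#' @return A `consensus_calls` data.frame (high_confidence = called by both).
#' @export
merge_germline <- function(callsets, genome = NULL) {
  if (length(callsets) != 2)
    stop_config("germline merging requires exactly 2 callsets, got %d",
                length(callsets))
  out <- merge_small_variants(callsets, genome = genome)
  out$high_confidence <- out$n_callers == 2
  out
}
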