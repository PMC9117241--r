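#' Configuration for a synthetic reference genome
#'
#' The simulator works against a small random genome rather than GRCh37 so that
#' trinucleotide contexts and coding masks are computable offline; the genome is
#' writable as FASTA + BED so downstream modules need no special-casing.
#'
#' @param contigs Named integer vector of contig lengths in bp.
#' @param coding_fraction Fraction of the genome covered by coding intervals,
#'   strictly inside (0, 1).
#' @param n_genes Number of gene models to place.
#' @param cancer_gene_fraction Fraction of genes flagged as cancer genes.
#' @param exon_bp Width of individual coding intervals.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(contigs = c(chr1 = 1e6, chr2 = 1e6),
                          coding_fraction = 0.01,
                          n_genes = 40,
                          cancer_gene_fraction = 0.25,
                          exon_bp = 150) {
  if (!is.numeric(coding_fraction) || coding_fraction <= 0 || coding_fraction >= 1)
    stop_config("coding_fraction must lie strictly in (0, 1), got %s", coding_fraction)
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop_config("contigs must be a named vector of lengths")
  if (any(contigs < 1000)) stop_config("contig lengths must be >= 1000 bp")
  structure(list(contigs = contigs, coding_fraction = coding_fraction,
                 n_genes = as.integer(n_genes),
                 cancer_gene_fraction = cancer_gene_fraction,
                 exon_bp = as.integer(exon_bp)),
            class = "genome_config")
}

#' Simulate a synthetic reference genome
#'
#' Generates random nucleotide sequence per contig, a non-overlapping set of
#' coding intervals totalling `coding_fraction` of the genome (0-based,
#' half-open, BED convention), and a gene table.  Deterministic for a fixed
#' seed.
#'
#' @param config A [genome_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_genome` with elements `contigs`
#'   (data.frame: name, length), `sequence` (named character vector),
#'   `coding_regions` (data.frame: contig, start, end; 0-based half-open),
#'   and `genes` (data.frame: gene, contig, start, end, strand,
#'   is_cancer_gene; 0-based half-open).
#' @export
simulate_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(config$contigs, function(len) {
      paste(sample(bases, len, replace = TRUE), collapse = "")
    }, character(1))

    coding <- do.call(rbind, lapply(names(config$contigs), function(ct) {
      len <- config$contigs[[ct]]
      target <- round(len * config$coding_fraction)
      n_ex <- max(1L, ceiling(target / config$exon_bp))
      widths <- rep(config$exon_bp, n_ex)
      widths[n_ex] <- target - config$exon_bp * (n_ex - 1L)
      widths <- widths[widths > 0]
      n_ex <- length(widths)
      # one exon per equal slot, jittered, so intervals never overlap
      slot <- floor(len / n_ex)
      offs <- vapply(seq_len(n_ex), function(i) {
        room <- slot - widths[i]
        (i - 1L) * slot + if (room > 0) sample.int(room, 1L) - 1L else 0L
      }, numeric(1))
      data.frame(contig = ct, start = offs, end = offs + widths)
    }))
    rownames(coding) <- NULL

    genes <- if (config$n_genes > 0) {
      per_contig <- table(sample(names(config$contigs), config$n_genes,
                                 replace = TRUE,
                                 prob = config$contigs / sum(config$contigs)))
      g <- do.call(rbind, lapply(names(per_contig), function(ct) {
        n <- per_contig[[ct]]
        if (n == 0) return(NULL)
        len <- config$contigs[[ct]]
        slot <- floor(len / n)
        width <- pmin(sample(5000:20000, n, replace = TRUE), slot - 2L)
        start <- (seq_len(n) - 1L) * slot +
          vapply(slot - width, function(r) sample.int(max(r, 1L), 1L) - 1L, numeric(1))
        data.frame(contig = ct, start = start, end = start + width)
      }))
      g <- g[order(g$contig, g$start), , drop = FALSE]
      g$gene <- sprintf("GENE%03d", seq_len(nrow(g)))
      g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
      n_cancer <- round(nrow(g) * config$cancer_gene_fraction)
      g$is_cancer_gene <- seq_len(nrow(g)) %in% sample.int(nrow(g), n_cancer)
      rownames(g) <- NULL
      g[, c("gene", "contig", "start", "end", "strand", "is_cancer_gene")]
    } else {
      data.frame(gene = character(), contig = character(), start = numeric(),
                 end = numeric(), strand = character(), is_cancer_gene = logical())
    }

    structure(list(
      contigs = data.frame(name = names(config$contigs),
                           length = unname(config$contigs)),
      sequence = seqs,
      coding_regions = coding,
      genes = genes,
      config = config
    ), class = "synthetic_genome")
  })
}

#' Write a synthetic genome as FASTA
#' @param genome A `synthetic_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dss <- Biostrings::DNAStringSet(genome$sequence)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Write coding regions as BED (0-based half-open)
#' @param genome A `synthetic_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coding_bed <- function(genome, path) {
  stopifnot(inherits(genome, "synthetic_genome"))
  utils::write.table(genome$coding_regions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3+ column BED file of intervals
#'
#' @param path BED file (0-based half-open; tab-separated, no header).
#' @return data.frame with columns contig, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(contig = character(), start = numeric(), end = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3 || is.na(suppressWarnings(as.numeric(p[2]))) ||
        is.na(suppressWarnings(as.numeric(p[3]))))
      stop_config("malformed BED line %d: '%s'", i, lines[i])
  }
  data.frame(contig = vapply(parts, `[`, "", 1L),
             start = as.numeric(vapply(parts, `[`, "", 2L)),
             end = as.numeric(vapply(parts, `[`, "", 3L)))
}

#' Trinucleotide context at each genomic position of a contig set
#'
#' Builds an index from pyrimidine-normalized trinucleotide context to the
#' genome positions (1-based) carrying it, used to place simulated SNVs so the
#' written genome really contains the sampled contexts.
#' @noRd
build_context_index <- function(genome) {
  idx <- list()
  for (ct in names(genome$sequence)) {
    s <- strsplit(genome$sequence[[ct]], "", fixed = TRUE)[[1]]
    n <- length(s)
    centre <- s[2:(n - 1)]
    tri <- paste0(s[1:(n - 2)], centre, s[3:n])
    pos <- 2:(n - 1)
    pur <- centre %in% c("A", "G")
    tri[pur] <- revcomp3(tri[pur])
    sp <- split(pos, tri)
    for (k in names(sp)) {
      idx[[k]] <- rbind(idx[[k]],
                        data.frame(contig = ct, pos = sp[[k]]))
    }
  }
  idx
}

#' Vectorized reverse complement of 3-mers
#' @noRd
revcomp3 <- function(x) {
  paste0(chartr("ACGT", "TGCA", substr(x, 3, 3)),
         chartr("ACGT", "TGCA", substr(x, 2, 2)),
         chartr("ACGT", "TGCA", substr(x, 1, 1)))
}

#' Reverse complement of character DNA strings
#' @noRd
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Base at a 1-based position of a contig
#' @noRd
base_at <- function(genome, contig, pos) {
  substring(genome$sequence[[contig]], pos, pos)
}
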