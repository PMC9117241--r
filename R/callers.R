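#' A synthetic variant-caller error model
#'
#' @param name Caller label.
#' @param min_alt_reads Minimum alt reads for the caller to emit a call.
#' @param miss_prob Per-call probability of missing a callable variant.
#' @param fp_rate_per_mb Expected false-positive calls per megabase.
#' @return A list of class `caller_model`.
#' @export
caller_model <- function(name, min_alt_reads = 2, miss_prob = 0,
                         fp_rate_per_mb = 0) {
  if (miss_prob < 0 || miss_prob > 1)
    stop_config("miss_prob must lie in [0, 1]")
  if (fp_rate_per_mb < 0) stop_config("fp_rate_per_mb must be >= 0")
  if (min_alt_reads < 0) stop_config("min_alt_reads must be >= 0")
  structure(list(name = name, min_alt_reads = min_alt_reads,
                 miss_prob = miss_prob, fp_rate_per_mb = fp_rate_per_mb),
            class = "caller_model")
}

#' The default three-caller ensemble
#' @param min_alt_reads,miss_prob,fp_rate_per_mb Shared model parameters.
#' @return list of three [caller_model()]s.
#' @export
default_caller_models <- function(min_alt_reads = 2, miss_prob = 0.02,
                                  fp_rate_per_mb = 0.5) {
  lapply(c("callerA", "callerB", "callerC"), caller_model,
         min_alt_reads = min_alt_reads, miss_prob = miss_prob,
         fp_rate_per_mb = fp_rate_per_mb)
}

#' Simulate per-caller small-variant call sets from assay observations
#'
#' Each caller emits a call for an observed variant when `alt_reads >=
#' min_alt_reads` and an independent per-call miss does not occur; false
#' positives are placed uniformly at random at non-truth loci at the model's
#' rate per Mb (Poisson).  The truth id is carried so recall can be scored.
#'
#' @param observations Output of [simulate_assay()].
#' @param genome The `synthetic_genome` (for false-positive placement).
#' @param caller_models List of [caller_model()]s.
#' @param seed Integer seed.
#' @return Named list (per caller) of call data.frames: contig, pos, ref,
#'   alt, class, filter, truth_id, caller.
#' @export
simulate_caller_outputs <- function(observations, genome,
                                    caller_models = default_caller_models(),
                                    seed = 1L) {
  with_seed(seed, {
    genome_mb <- sum(genome$contigs$length) / 1e6
    truth_keys <- paste0(observations$contig, ":", observations$pos)
    out <- list()
    for (cm in caller_models) {
      callable <- observations$alt_reads >= cm$min_alt_reads
      missed <- stats::runif(nrow(observations)) < cm$miss_prob
      keep <- callable & !missed
      calls <- data.frame(contig = observations$contig[keep],
                          pos = observations$pos[keep],
                          ref = observations$ref[keep],
                          alt = observations$alt[keep],
                          class = observations$class[keep],
                          filter = rep("PASS", sum(keep)),
                          truth_id = observations$variant_id[keep],
                          stringsAsFactors = FALSE)
      n_fp <- stats::rpois(1, cm$fp_rate_per_mb * genome_mb)
      if (n_fp > 0) {
        fp <- list()
        while (length(fp) < n_fp) {
          ct <- sample(genome$contigs$name, 1, prob = genome$contigs$length)
          len <- genome$contigs$length[genome$contigs$name == ct]
          p <- sample.int(len - 4L, 1L) + 2L
          if (paste0(ct, ":", p) %in% truth_keys) next
          b <- base_at(genome, ct, p)
          fp[[length(fp) + 1L]] <- data.frame(
            contig = ct, pos = p, ref = b,
            alt = sample(setdiff(c("A", "C", "G", "T"), b), 1),
            class = "SNV", filter = "PASS", truth_id = NA_character_,
            stringsAsFactors = FALSE)
        }
        calls <- rbind(calls, do.call(rbind, fp))
      }
      calls$caller <- rep(cm$name, nrow(calls))
      calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
      rownames(calls) <- NULL
      out[[cm$name]] <- calls
    }
    out
  })
}

#' Simulate per-caller SV call sets
#'
#' Callers report the truth breakpoints jittered by a few bp (emulating
#' caller-specific breakpoint resolution) and miss events independently.
#'
#' @param truth A `tumor_truth`.
#' @param caller_models List of [caller_model()]s (`miss_prob` used).
#' @param jitter_bp Max per-breakpoint positional jitter.
#' @param seed Integer seed.
#' @return Named list of SV call data.frames: contig, pos, strand1, contig2,
#'   pos2, strand2, svtype, truth_id, caller.
#' @export
simulate_sv_calls <- function(truth, caller_models = default_caller_models(),
                              jitter_bp = 10, seed = 1L) {
  svs <- truth$variants[truth$variants$class %in% c("SV", "fusion"), , drop = FALSE]
  with_seed(seed, {
    out <- list()
    for (cm in caller_models) {
      keep <- stats::runif(nrow(svs)) >= cm$miss_prob
      s <- svs[keep, , drop = FALSE]
      n <- nrow(s)
      calls <- data.frame(contig = s$contig,
                          pos = s$pos + sample(-jitter_bp:jitter_bp, n, TRUE),
                          strand1 = s$strand1,
                          contig2 = s$contig2,
                          pos2 = s$pos2 + sample(-jitter_bp:jitter_bp, n, TRUE),
                          strand2 = s$strand2,
                          svtype = s$svtype,
                          truth_id = s$id, caller = cm$name,
                          stringsAsFactors = FALSE)
      rownames(calls) <- NULL
      out[[cm$name]] <- calls
    }
    out
  })
}

#' Simulate per-caller fusion call sets (ordered 5'/3' gene pairs)
#'
#' @param truth A `tumor_truth`.
#' @param caller_models List of [caller_model()]s (`miss_prob` used).
#' @param seed Integer seed.
#' @return Named list of fusion call data.frames: gene5, gene3, truth_id,
#'   caller.
#' @export
simulate_fusion_calls <- function(truth,
                                  caller_models = default_caller_models(),
                                  seed = 1L) {
  fus <- truth$variants[truth$variants$class == "fusion", , drop = FALSE]
  with_seed(seed, {
    out <- list()
    for (cm in caller_models) {
      keep <- stats::runif(nrow(fus)) >= cm$miss_prob
      f <- fus[keep, , drop = FALSE]
      out[[cm$name]] <- data.frame(gene5 = f$gene5, gene3 = f$gene3,
                                   truth_id = f$id, caller = cm$name,
                                   stringsAsFactors = FALSE)
    }
    out
  })
}

vcf_header <- function(genome, caller) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=wgtsbench-%s", caller),
    sprintf("##contig=<ID=%s,length=%d>", genome$contigs$name,
            genome$contigs$length),
    "##INFO=<ID=TRUTH_ID,Number=1,Type=String,Description=\"Simulated truth variant id\">",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
}

#' Write a small-variant call set as VCF v4.2
#'
#' @param calls A call data.frame from [simulate_caller_outputs()].
#' @param genome The `synthetic_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, genome, path) {
  caller <- calls$caller[1] %||% "caller"
  info <- paste0(ifelse(is.na(calls$truth_id), "",
                        paste0("TRUTH_ID=", calls$truth_id, ";")),
                 "VCLASS=", calls$class)
  body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt, ".",
                calls$filter %||% "PASS", info, sep = "\t")
  writeLines(c(vcf_header(genome, caller), body), path)
  invisible(path)
}

#' Write an SV call set as paired BND records (VCF v4.2)
#'
#' Each SV emits two breakend records linked by `MATEID`; orientation is
#' encoded in the bracket notation of the BND ALT allele.
#'
#' @param calls An SV call data.frame from [simulate_sv_calls()].
#' @param genome The `synthetic_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, genome, path) {
  caller <- calls$caller[1] %||% "caller"
  lines <- character(0)
  bnd_alt <- function(base, mate_ct, mate_pos, strand_here, strand_mate) {
    mate <- paste0(mate_ct, ":", mate_pos)
    if (strand_here == "+" && strand_mate == "-") paste0(base, "[", mate, "[")
    else if (strand_here == "+" && strand_mate == "+") paste0(base, "]", mate, "]")
    else if (strand_here == "-" && strand_mate == "+") paste0("]", mate, "]", base)
    else paste0("[", mate, "[", base)
  }
  for (i in seq_len(nrow(calls))) {
    id1 <- sprintf("bnd_%d_1", i); id2 <- sprintf("bnd_%d_2", i)
    b1 <- base_at(genome, calls$contig[i], calls$pos[i])
    b2 <- base_at(genome, calls$contig2[i], calls$pos2[i])
    info <- sprintf("SVTYPE=BND;MATEID=%%s;VCLASS=SV%s",
                    ifelse(is.na(calls$truth_id[i]), "",
                           paste0(";TRUTH_ID=", calls$truth_id[i])))
    lines <- c(lines,
      paste(calls$contig[i], calls$pos[i], id1, b1,
            bnd_alt(b1, calls$contig2[i], calls$pos2[i],
                    calls$strand1[i], calls$strand2[i]),
            ".", "PASS", sprintf(info, id2), sep = "\t"),
      paste(calls$contig2[i], calls$pos2[i], id2, b2,
            bnd_alt(b2, calls$contig[i], calls$pos[i],
                    calls$strand2[i], calls$strand1[i]),
            ".", "PASS", sprintf(info, id1), sep = "\t"))
  }
  writeLines(c(vcf_header(genome, caller), lines), path)
  invisible(path)
}

#' Read a small-variant VCF written by this package (or any flat VCF)
#'
#' @param path VCF file.
#' @return Call data.frame: contig, pos, ref, alt, class, filter, truth_id.
#' @export
read_caller_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(contig = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      class = character(), filter = character(),
                      truth_id = character()))
  f <- strsplit(body, "\t", fixed = TRUE)
  getfield <- function(i) vapply(f, `[`, "", i)
  info <- getfield(8)
  grab <- function(tag) {
    m <- regmatches(info, regexpr(paste0(tag, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(tag, "="), info)
    out[hit] <- sub(paste0(tag, "="), "", m)
    out
  }
  data.frame(contig = getfield(1), pos = as.numeric(getfield(2)),
             ref = getfield(4), alt = getfield(5),
             class = grab("VCLASS"), filter = getfield(7),
             truth_id = grab("TRUTH_ID"), stringsAsFactors = FALSE)
}

#' Write the tumor truth as JSON
#' @param truth A `tumor_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(purity = truth$purity, clones = truth$clones,
         variants = truth$variants, cn_segments = truth$cn_segments,
         signature_mixes = truth$signature_mixes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
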