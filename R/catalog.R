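#' The 96 trinucleotide substitution contexts
#'
#' Standard SBS ordering: substitutions C>A, C>G, C>T, T>A, T>C, T>G, each with
#' the 16 combinations of 5' and 3' flanking bases, written as e.g. `A[C>A]G`.
#' The mutated base is always expressed as its pyrimidine partner.
#'
#' @return Character vector of length 96.
#' @export
sbs_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flanks <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (f5 in flanks) for (f3 in flanks)
    out <- c(out, paste0(f5, "[", s, "]", f3))
  out
}

#' Split a context label into (5' base, ref, alt, 3' base)
#' @noRd
parse_context <- function(ctx) {
  data.frame(up = substr(ctx, 1, 1),
             ref = substr(ctx, 3, 3),
             alt = substr(ctx, 5, 5),
             down = substr(ctx, 7, 7))
}

#' A synthetic, well-separated signature catalog
#'
#' Five synthetic signatures over the 96 contexts, each concentrating
#' `1 - smoothing` of its mass on a private block of contexts plus a small
#' uniform floor.  Two columns are named for the treatment-associated processes
#' (platinum, temozolomide) so treatment flagging is exercisable; the profiles
#' themselves are synthetic, not COSMIC data.
#'
#' @param smoothing Uniform mass spread over all 96 contexts (default 0.02).
#' @return A `signature_catalog`: list with `matrix` (96 x 5, columns sum to
#'   1) and `signatures` (column names).
#' @export
synthetic_signature_catalog <- function(smoothing = 0.02) {
  ctx <- sbs_contexts()
  sig_names <- c("SBS_A", "SBS_B", "SBS_C", "SBS_platinum", "SBS_temozolomide")
  blocks <- split(seq_len(96), cut(seq_len(96), 5, labels = FALSE))
  m <- matrix(smoothing / 96, nrow = 96, ncol = 5,
              dimnames = list(ctx, sig_names))
  for (j in seq_len(5)) {
    b <- blocks[[j]]
    # mild within-block shape so no two contexts are exactly tied
    w <- seq(2, 1, length.out = length(b))
    m[b, j] <- m[b, j] + (1 - smoothing) * w / sum(w)
  }
  new_signature_catalog(m)
}

new_signature_catalog <- function(m) {
  validate_catalog(m)
  structure(list(matrix = m, signatures = colnames(m)),
            class = "signature_catalog")
}

validate_catalog <- function(m) {
  if (nrow(m) != 96) stop_config("signature catalog must have 96 context rows")
  if (any(m < 0)) stop_config("signature catalog entries must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop_config("signature catalog columns must sum to 1 (max deviation %g)",
                max(abs(cs - 1)))
  invisible(m)
}

#' Read a signature catalog from TSV
#'
#' Expects a header row of signature names, a first column of the 96 context
#' labels (any order; rows are re-ordered to [sbs_contexts()]), and one column
#' per signature with probabilities summing to 1.  This is the layout of
#' COSMIC SBS text exports.
#'
#' @param path TSV file.
#' @return A `signature_catalog`.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  missing <- setdiff(sbs_contexts(), rn)
  if (length(missing) > 0)
    stop_config("catalog is missing %d contexts (e.g. %s)",
                length(missing), missing[1])
  new_signature_catalog(m[sbs_contexts(), , drop = FALSE])
}

#' Write a signature catalog as TSV
#' @param catalog A `signature_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "signature_catalog"))
  df <- data.frame(context = rownames(catalog$matrix), catalog$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
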