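#' Read a simulation run configuration from YAML
#'
#' Parses a YAML file with optional `genome`, `tumor` and `assays` sections
#' into validated config objects.  Unknown keys raise an error so that typos
#' in run configs fail fast.
#'
#' ```yaml
#' genome: {coding_fraction: 0.01, n_genes: 40}
#' tumor:
#'   purity: 0.8
#'   clones: [{clone_id: C1, ccf: 1.0}, {clone_id: C2, parent_id: C1, ccf: 0.4}]
#'   n_snv: [300, 150]
#' assays:
#'   - {name: wgs, mean_depth: 100}
#'   - {name: panel, mean_depth: 500}
#' ```
#'
#' @param path YAML file path.
#' @return list with elements `genome` ([genome_config()]), `tumor`
#'   ([tumor_config()]) and `assays` (list of [assay_config()]), using
#'   defaults for absent sections.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      stop_config("unknown %s config key(s): %s", where,
                  paste(bad, collapse = ", "))
  }
  check_keys(raw, c("genome", "tumor", "assays"), "run")

  g <- raw$genome %||% list()
  check_keys(g, c("contigs", "coding_fraction", "n_genes",
                  "cancer_gene_fraction", "exon_bp"), "genome")
  if (!is.null(g$contigs)) g$contigs <- unlist(g$contigs)
  genome <- do.call(genome_config, g)

  t <- raw$tumor %||% list()
  check_keys(t, c("purity", "clones", "n_snv", "n_indel", "n_sv", "n_fusion",
                  "signature_mix", "n_cn_events"), "tumor")
  if (!is.null(t$clones)) {
    t$clones <- do.call(rbind, lapply(t$clones, function(cl)
      data.frame(clone_id = cl$clone_id,
                 parent_id = cl$parent_id %||% NA_character_,
                 ccf = cl$ccf)))
  }
  if (!is.null(t$n_snv)) t$n_snv <- unlist(t$n_snv)
  if (!is.null(t$n_indel)) t$n_indel <- unlist(t$n_indel)
  if (!is.null(t$signature_mix)) t$signature_mix <- unlist(t$signature_mix)
  tumor <- do.call(tumor_config, t)

  assays <- lapply(raw$assays %||% list(list(name = "wgs")), function(a) {
    check_keys(a, c("name", "mean_depth", "dispersion", "purity", "clones",
                    "classes"), "assay")
    if (!is.null(a$clones)) a$clones <- unlist(a$clones)
    do.call(assay_config, a)
  })
  list(genome = genome, tumor = tumor, assays = assays)
}
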