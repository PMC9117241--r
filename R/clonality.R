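#' Estimate mutation multiplicity from VAF, purity and local copy number
#'
#' `m = clamp(round(vaf * (purity * CNt + 2 * (1 - purity)) / purity), 1,
#' max(1, major_cn))`: the number of mutated copies per tumor cell most
#' consistent with the observed allele fraction assuming the mutation is
#' clonal.
#'
#' @param vaf Observed variant allele fraction.
#' @param purity Sample purity in (0, 1].
#' @param total_cn Total tumor copy number at the locus.
#' @param major_cn Major allele copy number (upper clamp); defaults to
#'   `total_cn`.
#' @return Integer multiplicity >= 1.
#' @export
estimate_multiplicity <- function(vaf, purity, total_cn, major_cn = total_cn) {
  if (any(purity <= 0)) stop_config("purity must be positive")
  raw <- round(vaf * (purity * total_cn + 2 * (1 - purity)) / purity)
  as.integer(clamp(raw, 1, pmax(1, major_cn)))
}

#' Cancer cell fraction from VAF, corrected for purity and local copy number
#'
#' `ccf = vaf * (purity * CNt + 2 * (1 - purity)) / (m * purity)` — the exact
#' inverse of [expected_vaf()].
#'
#' @param vaf Variant allele fraction.
#' @param purity Sample purity in (0, 1].
#' @param total_cn Total tumor copy number.
#' @param multiplicity Mutation multiplicity (>= 1).
#' @return Cancer cell fraction (may exceed 1 when multiplicity is
#'   misestimated; see [clamp_ccf()]).
#' @export
ccf_from_vaf <- function(vaf, purity, total_cn, multiplicity = 1) {
  if (any(multiplicity == 0)) stop_config("multiplicity must be >= 1")
  if (any(purity <= 0 | purity > 1)) stop_config("purity must lie in (0, 1]")
  vaf * (purity * total_cn + 2 * (1 - purity)) / (multiplicity * purity)
}

#' Clamp CCF values for reporting
#'
#' CCFs above 1 usually indicate multiplicity misestimates; values are
#' clamped to 1.5 and flagged.
#'
#' @param ccf Numeric CCF vector.
#' @return data.frame with columns `ccf` (clamped to [0, 1.5]) and
#'   `flag_super_clonal` (TRUE where raw CCF > 1).
#' @export
clamp_ccf <- function(ccf) {
  data.frame(ccf = clamp(ccf, 0, 1.5), flag_super_clonal = ccf > 1)
}

#' Is a mutation subclonal?
#'
#' A mutation is flagged subclonal when its cancer cell fraction is below 90%.
#'
#' @param ccf Cancer cell fraction (>= 0).
#' @return Logical vector: TRUE iff `ccf < 0.9`.
#' @export
subclonal_flag <- function(ccf) {
  stopifnot(all(ccf >= 0))
  ccf < 0.9
}

# weighted binomial log-likelihood of cluster CCF pi given per-variant
# linear coefficients c_i (vaf_i = pi * c_i)
cluster_loglik <- function(pi_k, alt, depth, coef, w = NULL) {
  p <- clamp(pi_k * coef, 1e-9, 1 - 1e-9)
  ll <- alt * log(p) + (depth - alt) * log(1 - p)
  if (is.null(w)) sum(ll) else sum(w * ll)
}

#' Cluster mutations into clones by binomial-mixture EM on CCF
#'
#' Each variant's read counts are modelled as Binomial(depth, ccf_k * c_i)
#' where c_i = m_i * purity / (purity * CNt_i + 2 (1 - purity)) maps CCF to
#' expected VAF at that locus.  A finite mixture over k = 1..max_k cluster
#' CCFs is fitted by EM (k-means initialization on naive per-variant CCFs,
#' multiple restarts) and k is selected by BIC.  Every variant is assigned to
#' exactly one cluster (maximum responsibility).
#'
#' @param variants data.frame with columns alt_reads, depth, purity,
#'   local_cn and (optionally) multiplicity — [simulate_assay()] output
#'   works directly.  Multiplicity is estimated via
#'   [estimate_multiplicity()] when absent.
#' @param max_k Maximum number of clusters considered (default 5).
#' @param seed Integer seed (k-means restarts).
#' @param max_iter,tol EM iteration cap (default 500) and relative
#'   log-likelihood convergence tolerance (default 1e-6).
#' @param n_restarts k-means restarts (default 10).
#' @return list of class `clone_clusters`: `clusters` (data.frame:
#'   cluster_id, ccf_mean, mutation_count), `assignment` (per-variant cluster
#'   id), `k`, `bic` (per candidate k), `converged`, `warning_flag`.
#' @export
cluster_ccf <- function(variants, max_k = 5, seed = 1L, max_iter = 500,
                        tol = 1e-6, n_restarts = 10) {
  stopifnot(all(c("alt_reads", "depth", "purity", "local_cn") %in%
                  names(variants)))
  v <- variants[variants$depth > 0, , drop = FALSE]
  if (nrow(v) == 0) stop_config("no variants with positive depth")
  vaf <- v$alt_reads / v$depth
  mult <- if ("multiplicity" %in% names(v)) v$multiplicity else
    estimate_multiplicity(vaf, v$purity, v$local_cn)
  coef <- mult * v$purity / (v$purity * v$local_cn + 2 * (1 - v$purity))
  naive <- clamp(vaf / coef, 0, 1.5)
  n <- nrow(v)
  max_k <- min(max_k, length(unique(round(naive, 6))))

  with_seed(seed, {
    fits <- list()
    for (k in seq_len(max_k)) {
      fit <- em_binom_mixture(v$alt_reads, v$depth, coef, naive, k,
                              max_iter, tol, n_restarts)
      fit$bic <- -2 * fit$loglik + (2 * k - 1) * log(n)
      fits[[k]] <- fit
    }
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    best <- fits[[which.min(bics)]]
    ord <- order(best$ccf, decreasing = TRUE)
    remap <- match(seq_along(ord), ord)
    assignment <- remap[best$assignment]
    clusters <- data.frame(cluster_id = seq_along(ord),
                           ccf_mean = best$ccf[ord],
                           mutation_count = as.vector(table(factor(
                             assignment, levels = seq_along(ord)))))
    structure(list(clusters = clusters, assignment = assignment,
                   k = length(ord), bic = bics,
                   converged = best$converged,
                   warning_flag = !best$converged,
                   variant_index = which(variants$depth > 0)),
              class = "clone_clusters")
  })
}

em_binom_mixture <- function(alt, depth, coef, naive, k, max_iter, tol,
                             n_restarts) {
  n <- length(alt)
  if (k == 1) {
    opt <- stats::optimize(cluster_loglik, interval = c(1e-4, 1.5),
                           alt = alt, depth = depth, coef = coef,
                           maximum = TRUE, tol = 1e-8)
    return(list(ccf = opt$maximum, weights = 1,
                assignment = rep(1L, n), loglik = opt$objective,
                converged = TRUE))
  }
  centers <- if (length(unique(naive)) >= k) {
    km <- suppressWarnings(stats::kmeans(naive, centers = k,
                                         nstart = n_restarts))
    as.vector(km$centers)
  } else sort(stats::runif(k, 0.05, 1.2))
  pi_k <- clamp(sort(centers, decreasing = TRUE), 1e-3, 1.5)
  w_k <- rep(1 / k, k)
  ll_old <- -Inf; converged <- FALSE
  upper <- 1.5
  for (it in seq_len(max_iter)) {
    # E step
    logdens <- sapply(seq_len(k), function(j) {
      p <- clamp(pi_k[j] * coef, 1e-9, 1 - 1e-9)
      log(w_k[j]) + alt * log(p) + (depth - alt) * log(1 - p)
    })
    mx <- apply(logdens, 1, max)
    resp <- exp(logdens - mx)
    rs <- rowSums(resp)
    resp <- resp / rs
    ll <- sum(mx + log(rs))
    # M step
    w_k <- colMeans(resp)
    for (j in seq_len(k)) {
      if (w_k[j] < 1e-8) next
      opt <- stats::optimize(cluster_loglik, interval = c(1e-4, upper),
                             alt = alt, depth = depth, coef = coef,
                             w = resp[, j], maximum = TRUE, tol = 1e-8)
      pi_k[j] <- opt$maximum
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning best-so-far fit")
  assignment <- max.col(resp)
  list(ccf = pi_k, weights = w_k, assignment = assignment, loglik = ll,
       converged = converged)
}

#' Per-clone mutational signature exposures
#'
#' Signatures are refitted in each clone cluster independently: the member
#' SNVs' 96-context counts are accumulated per cluster and passed to
#' [refit_signatures()].  Clusters with fewer than `min_snvs` members are
#' flagged low-confidence.
#'
#' @param clusters A `clone_clusters` object from [cluster_ccf()].
#' @param contexts Per-variant context labels (as [sbs_contexts()]), aligned
#'   with the variants passed to [cluster_ccf()].
#' @param catalog A `signature_catalog`.
#' @param min_snvs Minimum SNVs for a confident refit (default 20).
#' @return Named list per cluster: `exposures` ([refit_signatures()] result)
#'   and `low_confidence` flag.
#' @export
clone_level_signatures <- function(clusters, contexts, catalog,
                                   min_snvs = 20) {
  stopifnot(inherits(clusters, "clone_clusters"))
  contexts <- contexts[clusters$variant_index]
  out <- list()
  for (cid in clusters$clusters$cluster_id) {
    member <- contexts[clusters$assignment == cid & !is.na(contexts)]
    if (length(member) == 0)
      stop_config("cluster %s has no SNVs with context assignments", cid)
    vec <- table(factor(member, levels = sbs_contexts()))
    vec <- stats::setNames(as.numeric(vec), sbs_contexts())
    out[[as.character(cid)]] <- list(
      exposures = refit_signatures(vec, catalog),
      low_confidence = length(member) < min_snvs)
  }
  out
}
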