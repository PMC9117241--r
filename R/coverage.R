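#' Thin read observations to a lower target depth
#'
#' Emulates BAM subsampling exactly at the read-count level: with thinning
#' fraction `f = target / original`, the retained depth is Binomial(depth, f)
#' and the retained alt reads follow the hypergeometric law of drawing the
#' new depth from the original reads without replacement.
#'
#' @param observations Observation data.frame (depth, alt_reads).
#' @param target_depth Target median depth.
#' @param original_median_depth Median depth of the input (default: computed).
#' @param seed Integer seed.
#' @return The observations with thinned `depth` and `alt_reads`.
#' @export
thin_observations <- function(observations, target_depth,
                              original_median_depth = NULL, seed = 1L) {
  orig <- original_median_depth %||% stats::median(observations$depth)
  f <- target_depth / orig
  if (f > 1) stop_config("cannot thin upwards: target %g > original %g",
                         target_depth, orig)
  if (f == 1) return(observations)
  with_seed(seed, {
    d <- observations$depth
    a <- observations$alt_reads
    d2 <- stats::rbinom(length(d), d, f)
    a2 <- stats::rhyper(length(d), m = a, n = d - a, k = d2)
    observations$depth <- d2
    observations$alt_reads <- a2
    observations
  })
}

#' Check that thinned data hit the target depth
#'
#' @param thinned Thinned observation data.frame.
#' @param target Target depth.
#' @param tol Allowed deviation of the median (default 5x, inclusive).
#' @return TRUE iff |median depth - target| <= tol.
#' @export
verify_target_depth <- function(thinned, target, tol = 5) {
  stopifnot(nrow(thinned) > 0)
  abs(stats::median(thinned$depth) - target) <= tol
}

#' Effective coverage: median depth times purity
#'
#' The sequencing depth "seen" by tumor-derived alleles.
#'
#' @param median_depth Median sequencing depth.
#' @param purity Tumor purity.
#' @return Effective coverage in x units.
#' @export
effective_coverage <- function(median_depth, purity) median_depth * purity

#' Analytic binomial detection power
#'
#' Probability of obtaining at least 2 variant reads given effective local
#' coverage `n` and variant allele fraction `p`:
#' `1 - (1-p)^n - n p (1-p)^(n-1)`, i.e. P(X >= 2) for X ~ Binomial(n, p).
#' Non-integer coverage is rounded.
#'
#' @param n Effective local coverage (rounded to integer).
#' @param p Variant allele fraction in [0, 1].
#' @param min_alt_reads Detection threshold (default 2 reads).
#' @return Detection probability in [0, 1].
#' @export
detection_power <- function(n, p, min_alt_reads = 2) {
  len <- max(length(n), length(p))
  n <- round(rep_len(n, len)); p <- rep_len(p, len)
  stopifnot(all(n >= 0), all(p >= 0 & p <= 1))
  out <- stats::pbinom(min_alt_reads - 1, n, p, lower.tail = FALSE)
  out[n < min_alt_reads] <- 0
  out
}

#' Recall-by-depth sensitivity curve
#'
#' For each depth tier, the full-depth observations are thinned with
#' [thin_observations()], re-called by `detect_fn`, and the fraction of
#' reference variants re-detected is reported with a Wilson 95% CI, overall
#' and per variant class (plus a `clinical` stratum when the observations
#' carry a `clinical` flag).
#'
#' @param observations Full-depth observation data.frame
#'   ([simulate_assay()] output; optional logical `clinical` column).
#' @param reference_ids Variant ids defining the reference set (defaults to
#'   variants detected by `detect_fn` at full depth, mirroring the use of
#'   full-depth calls as reference).
#' @param tiers Target depths (default c(100, 80, 60, 35); the 30-40x tier
#'   is realized as 35x).
#' @param detect_fn Function(observations) -> character vector of detected
#'   variant ids.  Default: deterministic >= 2-caller consensus equivalent,
#'   i.e. variants with alt_reads >= 2.
#' @param seed Integer seed.
#' @param conf CI level (default 0.95).
#' @return data.frame of class `sensitivity_curve`: tier, class, n_reference,
#'   n_recalled, recall, ci_low, ci_high.
#' @export
recall_at_depths <- function(observations, reference_ids = NULL,
                             tiers = c(100, 80, 60, 35),
                             detect_fn = detect_min_alt_reads,
                             seed = 1L, conf = 0.95) {
  if (nrow(observations) == 0) stop_config("empty reference call set")
  orig <- stats::median(observations$depth)
  if (any(tiers > orig)) {
    warning(sprintf("dropping tier(s) above the original median depth %g: %s",
                    orig, paste(tiers[tiers > orig], collapse = ", ")))
    tiers <- tiers[tiers <= orig]
    if (length(tiers) == 0) stop_config("no tier at or below original depth")
  }
  if (is.null(reference_ids)) reference_ids <- detect_fn(observations)
  if (length(reference_ids) == 0) stop_config("empty reference call set")
  ref <- observations[observations$variant_id %in% reference_ids, ,
                      drop = FALSE]
  strata <- list(all = rep(TRUE, nrow(ref)))
  for (cls in unique(ref$class)) strata[[cls]] <- ref$class == cls
  if ("clinical" %in% names(ref)) strata$clinical <- ref$clinical
  rows <- list()
  with_seed(seed, {
    for (tier in sort(tiers, decreasing = TRUE)) {
      thinned <- thin_observations(ref, tier, original_median_depth = orig,
                                   seed = sample.int(.Machine$integer.max, 1))
      called <- detect_fn(thinned)
      hit <- ref$variant_id %in% called
      for (snm in names(strata)) {
        sel <- strata[[snm]]
        n <- sum(sel); k <- sum(hit & sel)
        ci <- wilson_ci(k, n, conf)
        rows[[length(rows) + 1L]] <- data.frame(
          tier = tier, class = snm, n_reference = n, n_recalled = k,
          recall = if (n > 0) k / n else NA_real_,
          ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Default deterministic detector: at least 2 alt reads observed
#' @param observations Observation data.frame.
#' @return Detected variant ids.
#' @export
detect_min_alt_reads <- function(observations) {
  observations$variant_id[observations$alt_reads >= 2]
}

#' Lowest depth tier attaining near-optimal sensitivity
#'
#' Reports the lowest tier whose overall recall is within `margin` of the
#' best tier's recall.
#'
#' @param curve A `sensitivity_curve` from [recall_at_depths()].
#' @param margin Allowed recall deficit (default 0.01).
#' @param class Stratum to evaluate (default "all").
#' @return list: optimal_tier, best_recall, recall_at_optimal.
#' @export
optimal_depth_report <- function(curve, margin = 0.01, class = "all") {
  cc <- curve[curve$class == class, , drop = FALSE]
  if (nrow(cc) == 0) stop_config("no rows for class '%s' in curve", class)
  best <- max(cc$recall)
  ok <- cc[cc$recall >= best - margin, , drop = FALSE]
  tier <- min(ok$tier)
  list(optimal_tier = tier, best_recall = best,
       recall_at_optimal = cc$recall[cc$tier == tier][1])
}
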