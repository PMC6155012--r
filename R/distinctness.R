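# Bootstrap z-score test for whether a focal subpopulation (e.g. the
# CD45RB+ cells inside the naive bubble) has a marker profile distinct from
# its parent population.
#
# Null model: draw n_focal events with replacement from the parent B times;
# record the per-marker median of each resample.  The observed focal medians
# are then standardised against this null distribution.

#' Bootstrap null distribution of subpopulation medians
#'
#' Resamples `n_focal` events with replacement from the parent population
#' `B` times and records the per-marker median of every resample.  The null
#' SD uses denominator `B` (the resample-median vector is the full
#' Monte-Carlo null, not a sample estimate of one).
#'
#' @param parent Event table of the parent population (arcsinh scale).
#' @param n_focal Resample size: the observed focal-population size (>= 1).
#' @param B Number of bootstrap replicates, default 10000.
#' @param seed Integer seed; bit-identical nulls on re-run.
#' @return A `bootstrap_null`: list with `medians` (B x markers matrix),
#'   `null_mean`, `null_sd` (named vectors), `n_focal`, `B`, `seed`.
#' @export
bootstrap_null <- function(parent, n_focal, B = 10000, seed = NULL) {
  if (nrow(parent) < 1) stopf("parent population is empty")
  if (n_focal < 1) stopf("n_focal must be >= 1")
  if (B < 1) stopf("B must be >= 1")
  mk <- marker_names(parent)
  X <- as.matrix(parent[mk])
  med <- with_seed(seed, {
    idx <- matrix(sample.int(nrow(X), n_focal * B, replace = TRUE), nrow = B)
    out <- matrix(NA_real_, B, length(mk), dimnames = list(NULL, mk))
    for (j in seq_along(mk)) {
      v <- X[, j]
      out[, j] <- apply(idx, 1L, function(i) stats::median(v[i]))
    }
    out
  })
  mu <- colMeans(med)
  sdv <- sqrt(colMeans(sweep(med, 2, mu)^2))  # denominator B
  structure(
    list(medians = med, null_mean = mu, null_sd = sdv,
         n_focal = n_focal, B = B, seed = seed),
    class = "bootstrap_null"
  )
}

#' Z-scores of focal medians against a bootstrap null
#'
#' For each marker, `z = (observed focal median - null mean) / null SD`.
#' When the null SD is zero, z is 0 if the observed median equals the null
#' mean and signed infinite otherwise.  Empirical p-values (rank of the
#' observed median among the null medians, with +1 smoothing, two-sided) are
#' reported alongside, since medians can be non-normal at small `n_focal`.
#'
#' @param focal Event table of the focal subpopulation.
#' @param null A `bootstrap_null` built from the parent.
#' @return Data frame: `marker`, `focal_median`, `null_mean`, `null_sd`,
#'   `z`, `p_emp`, `direction` (`"over"`/`"under"`/`"none"`), `n_markers`.
#' @export
zscore_markers <- function(focal, null) {
  stopifnot(inherits(null, "bootstrap_null"))
  if (nrow(focal) < 1) stopf("focal population is empty")
  mk <- colnames(null$medians)
  if (!all(mk %in% marker_names(focal))) stopf("marker sets do not match")
  obs <- vapply(mk, function(m) stats::median(focal[[m]]), numeric(1))
  z <- ifelse(null$null_sd > 0,
              (obs - null$null_mean) / null$null_sd,
              ifelse(obs == null$null_mean, 0, sign(obs - null$null_mean) * Inf))
  p_emp <- vapply(seq_along(mk), function(j) {
    lo <- sum(null$medians[, j] <= obs[j])
    hi <- sum(null$medians[, j] >= obs[j])
    min(1, 2 * (min(lo, hi) + 1) / (null$B + 1))
  }, numeric(1))
  data.frame(
    marker = mk,
    focal_median = unname(obs),
    null_mean = unname(null$null_mean),
    null_sd = unname(null$null_sd),
    z = unname(z),
    p_emp = p_emp,
    direction = ifelse(z > 0, "over", ifelse(z < 0, "under", "none")),
    n_markers = length(mk),
    stringsAsFactors = FALSE
  )
}

#' Flag significant markers on a z-score result
#'
#' Two-sided: flagged iff `|z| >= threshold` (boundary inclusive).  No
#' multiple-testing correction is applied; `n_markers` is carried in the
#' result so users may correct.
#'
#' @param result Data frame from [zscore_markers()].
#' @param threshold Positive |z| cutoff, default 2.
#' @return `result` with a logical `flag` column.
#' @export
significance_call <- function(result, threshold = 2) {
  if (threshold <= 0) stopf("threshold must be > 0")
  result$flag <- abs(result$z) >= threshold
  result
}

#' Bootstrap distinctness test of a focal subpopulation
#'
#' Convenience wrapper: builds the bootstrap null from the parent with
#' `n_focal = nrow(focal)`, computes z-scores and flags.  By default the
#' parent includes the focal events (resampling from the full parent bubble
#' as observed); set `exclude_focal = TRUE` to resample from the complement,
#' in which case `focal_ids` must identify focal rows via `event_id`.
#'
#' @param parent Parent event table.
#' @param focal Focal event table (a subset of the parent population).
#' @param B Bootstrap replicates, default 10000.
#' @param threshold |z| cutoff, default 2.
#' @param exclude_focal Drop focal events from the parent before resampling.
#' @param seed Integer seed.
#' @return Flagged z-score data frame (see [zscore_markers()]).
#' @export
distinctness_test <- function(parent, focal, B = 10000, threshold = 2,
                              exclude_focal = FALSE, seed = NULL) {
  if (exclude_focal) {
    if (is.null(parent$event_id) || is.null(focal$event_id)) {
      stopf("exclude_focal requires event_id columns")
    }
    parent <- parent[!(parent$event_id %in% focal$event_id), , drop = FALSE]
  }
  null <- bootstrap_null(parent, n_focal = nrow(focal), B = B, seed = seed)
  significance_call(zscore_markers(focal, null), threshold = threshold)
}
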