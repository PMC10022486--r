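#' Cascade k-means clustering of metabolite profiles
#'
#' Standardizes each metabolite profile (z-score across samples, since
#' LC-MS abundances span orders of magnitude), then runs k-means over a
#' range of cluster numbers via [vegan::cascadeKM()] with the
#' Calinski-Harabasz criterion; the partition at the criterion's argmax k
#' is returned (ties break toward smaller k).
#'
#' @param metab Metabolites-by-samples numeric matrix.
#' @param k_range Integer vector `c(min_k, max_k)` (default `c(2, 12)`).
#' @param n_init Random starts per k (default 25).
#' @param seed RNG seed (default 1).
#' @return A list of class `cluster_partition`: `k`, `labels` (named
#'   integer vector in `1..k`), `criterion` (named per-k values), and
#'   `centroids` (k-by-samples matrix on the standardized scale).
#' @export
kmeans_cascade <- function(metab, k_range = c(2L, 12L), n_init = 25L,
                           seed = 1L) {
  k_lo <- as.integer(k_range[1L]); k_hi <- as.integer(k_range[length(k_range)])
  if (k_lo < 2L) stopf("minimum k must be >= 2")
  if (k_hi > nrow(metab) - 1L)
    stopf("max k (%d) must be < number of metabolites (%d)", k_hi, nrow(metab))
  z <- t(scale(t(metab)))
  if (anyNA(z)) stopf("zero-variance metabolite profile cannot be standardized")
  set.seed(seed)
  cas <- vegan::cascadeKM(z, inf.gr = k_lo, sup.gr = k_hi, iter = n_init,
                          criterion = "calinski")
  crit <- unname(cas$results["calinski", ])
  best_col <- which.max(crit)  # ties resolve to the smaller k
  k <- k_lo + best_col - 1L
  labels <- as.integer(cas$partition[, best_col])
  names(labels) <- rownames(metab)
  centroids <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(z[labels == cl, , drop = FALSE])))
  rownames(centroids) <- seq_len(k)
  log_stage("kmeans_cascade", k = k, criterion = crit[best_col])
  structure(list(k = k, labels = labels,
                 criterion = stats::setNames(crit, seq(k_lo, k_hi)),
                 centroids = centroids),
            class = "cluster_partition")
}

#' Metabolite accumulation rate between consecutive sampling times
#'
#' For metabolite n and consecutive time points t, t+1:
#' `V[t, n] = (M[t+1, n] - M[t, n]) / (T[t+1] - T[t])`, i.e. the finite
#' difference of content per unit time (content units per day when times
#' are days after flowering).
#'
#' @param metab Metabolites-by-timepoints numeric matrix (one column per
#'   sampling time, in time order).
#' @param times Strictly increasing numeric sampling times, one per column.
#' @return A metabolites-by-intervals matrix of rates; interval columns are
#'   named `"T1-T2"` style from the time values.
#' @examples
#' accumulation_rate(rbind(m = c(2, 5, 11, 23)), c(45, 60, 75, 90))
#' @export
accumulation_rate <- function(metab, times) {
  metab <- as.matrix(metab)
  if (length(times) != ncol(metab))
    stopf("need one sampling time per content column")
  if (length(times) < 2L) stopf("need at least two time points")
  if (any(diff(times) <= 0)) stopf("sampling times must be strictly increasing")
  n_int <- length(times) - 1L
  v <- (metab[, -1L, drop = FALSE] - metab[, -ncol(metab), drop = FALSE]) /
    matrix(diff(times), nrow = nrow(metab), ncol = n_int, byrow = TRUE)
  colnames(v) <- paste0(times[-length(times)], "-", times[-1L])
  v
}

#' Module-metabolite integration correlation grid
#'
#' Correlates every module eigengene profile with every metabolite profile
#' over the shared sample axis, then summarizes each (module, cluster) cell
#' as the unweighted mean of the member metabolites' Pearson r. To
#' integrate accumulation rates, pass rate matrices for both sides (the
#' eigengene profile reduced by the same finite difference).
#'
#' @param eigengenes Samples-by-modules matrix (or intervals-by-modules for
#'   rates).
#' @param metab Metabolites-by-samples matrix (or metabolites-by-intervals).
#' @param partition A `cluster_partition` from [kmeans_cascade()], or a
#'   named integer vector of cluster labels.
#' @return A list of class `integration_cor`: `mean_r` (modules-by-clusters
#'   grid), `per_metabolite` (long data.frame of module, metabolite,
#'   cluster, r), `top` (the grid's argmax cell).
#' @export
correlate_modules_metabolites <- function(eigengenes, metab, partition) {
  labels <- if (inherits(partition, "cluster_partition")) partition$labels
  else partition
  if (is.null(names(labels)) || !all(rownames(metab) %in% names(labels)))
    stopf("cluster labels must be named for every metabolite")
  if (nrow(eigengenes) != ncol(metab))
    stopf("eigengenes and metabolites must share the sample/interval axis (%d vs %d)",
          nrow(eigengenes), ncol(metab))
  if (nrow(eigengenes) < 3L)
    stopf("fewer than 3 shared points: correlation undefined")
  labels <- labels[rownames(metab)]
  r_all <- suppressWarnings(stats::cor(eigengenes, t(metab)))
  clusters <- sort(unique(labels))
  mean_r <- sapply(clusters, function(cl)
    rowMeans(r_all[, labels == cl, drop = FALSE]))
  mean_r <- matrix(mean_r, nrow = ncol(eigengenes),
                   dimnames = list(colnames(eigengenes), clusters))
  per <- data.frame(
    module = rep(colnames(eigengenes), times = ncol(r_all)),
    metabolite = rep(colnames(r_all), each = nrow(r_all)),
    cluster = rep(labels[colnames(r_all)], each = nrow(r_all)),
    r = as.vector(r_all), stringsAsFactors = FALSE)
  top_idx <- which(mean_r == base::max(mean_r, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  structure(list(
    mean_r = mean_r,
    per_metabolite = per,
    top = list(module = rownames(mean_r)[top_idx[1L]],
               cluster = colnames(mean_r)[top_idx[2L]],
               mean_r = mean_r[top_idx[1L], top_idx[2L]])),
    class = "integration_cor")
}

#' Total anthocyanin content from absorbance readings
#'
#' `(A530 - 0.25 * A657) / fresh_weight`, the differential absorbance
#' correction for chlorophyll interference divided by sample fresh weight
#' in grams. Vectorized over records.
#'
#' @param a530,a657 Absorbance at 530 nm and 657 nm (>= 0).
#' @param fresh_weight Sample fresh weight in grams (> 0).
#' @return Anthocyanin value per gram fresh weight.
#' @examples
#' anthocyanin_value(0.5, 0.2, 1) # 0.45
#' @export
anthocyanin_value <- function(a530, a657, fresh_weight) {
  if (any(a530 < 0) || any(a657 < 0)) stopf("absorbances must be >= 0")
  if (any(fresh_weight <= 0)) stopf("fresh_weight must be > 0")
  (a530 - 0.25 * a657) / fresh_weight
}
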