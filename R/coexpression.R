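utils::globalVariables(c("gap", "pos", "code", "cluster", ".", ":="))

#' Soft-threshold power scan for scale-free topology
#'
#' For each candidate power, builds the unsigned weighted adjacency
#' `a_ij = |cor(x_i, x_j)|^beta`, computes connectivities
#' `k_i = sum_{j != i} a_ij`, and measures the scale-free fit as the R^2 of
#' the regression of `log10` bin frequency on `log10` mean bin connectivity
#' over `n_bins` connectivity bins. The selected power is the smallest one
#' reaching `r2_cut`, falling back to the power maximizing R^2 when none
#' does.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns (>= 20
#'   genes). Zero-variance genes are excluded with a message.
#' @param powers Integer candidate powers (default 1:20).
#' @param r2_cut Scale-free R^2 cut (default 0.8).
#' @param n_bins Connectivity bins (default 10).
#' @return A list of class `soft_threshold_scan`: `powers`, `r2`,
#'   `mean_connectivity`, `selected_power`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_cut = 0.8,
                                n_bins = 10L) {
  expr <- drop_zero_variance(expr)
  if (nrow(expr) < 20L) stopf("soft-threshold scan needs >= 20 genes")
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  r2 <- numeric(length(powers))
  meank <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- ac^powers[i]
    k <- rowSums(a)
    meank[i] <- mean(k)
    r2[i] <- scale_free_r2(k, n_bins)
  }
  hit <- which(r2 >= r2_cut)
  selected <- if (length(hit)) powers[base::min(hit)] else powers[which.max(r2)]
  log_stage("pick_soft_threshold", selected_power = selected,
            r2 = r2[match(selected, powers)])
  structure(list(powers = powers, r2 = r2, mean_connectivity = meank,
                 selected_power = selected),
            class = "soft_threshold_scan")
}

scale_free_r2 <- function(k, n_bins = 10L) {
  if (diff(range(k)) == 0) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3L) return(0)
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  summary(fit)$r.squared
}

drop_zero_variance <- function(expr) {
  v <- apply(expr, 1L, stats::var)
  bad <- v == 0 | is.na(v)
  if (any(bad)) {
    log_stage("drop_zero_variance", excluded = sum(bad))
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}

#' Topological overlap matrix of an unsigned co-expression network
#'
#' With adjacency `a_ij = |cor|^power` (diagonal 0) and connectivity
#' `k_i = sum_u a_iu`:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, and `TOM_ii = 1`. The result is symmetric with entries in
#' `[0, 1]`.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param power Soft-threshold power (>= 1).
#' @return The TOM as a symmetric numeric matrix with gene dimnames.
#' @export
tom_similarity <- function(expr, power) {
  if (power < 1) stopf("power must be >= 1")
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  tom_from_adjacency(a)
}

#' @rdname tom_similarity
#' @param adj A symmetric adjacency matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
tom_from_adjacency <- function(adj) {
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Cut a TOM dendrogram into co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut statically at `cut_height` expressed as a fraction of the span of
#' merge heights (0 cuts below the tightest merge, 1 above the loosest).
#' Clusters smaller than `min_module_size` are set aside as `"unassigned"`
#' (the grey module). Memberships are then refined by module eigengene
#' correlation (kME): each gene joins the module it correlates with best,
#' provided that correlation reaches `kme_min`, iterated to a fixed point.
#' Finally, modules whose eigengenes correlate above `1 - merge_cut` are
#' merged until stable. The whole stage is deterministic.
#'
#' @param tom TOM from [tom_similarity()].
#' @param expr The genes-by-samples matrix the TOM was built from (needed
#'   for eigengene-based refinement and merging).
#' @param min_module_size Minimum genes per module (default 30; must be
#'   >= 2).
#' @param cut_height Static tree cut as a fraction of the merge-height
#'   span (default 0.9: a liberal cut whose contamination the kME
#'   refinement removes).
#' @param merge_cut Modules with eigengene correlation > `1 - merge_cut`
#'   are merged (default 0.25).
#' @param kme_min Minimum gene-to-eigengene correlation to stay in a
#'   module during refinement (default 0.7).
#' @return A list of class `module_partition`: `labels` (named character
#'   vector, `"M1"`, `"M2"`, ... or `"unassigned"`), `sizes`.
#' @export
cut_modules <- function(tom, expr, min_module_size = 30L,
                        cut_height = 0.9, merge_cut = 0.25,
                        kme_min = 0.7) {
  if (min_module_size < 2L) stopf("min_module_size must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- rownames(expr)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  hmin <- base::min(hc$height); hmax <- base::max(hc$height)
  h <- hmin + cut_height * (hmax - hmin)
  raw <- stats::cutree(hc, h = h)
  labels <- rep("unassigned", length(raw))
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  # stable module numbering: by decreasing size, ties by first gene index
  keep <- keep[order(-sizes[as.character(keep)],
                     vapply(keep, function(cl) base::min(which(raw == cl)),
                            numeric(1)))]
  for (i in seq_along(keep)) labels[raw == keep[i]] <- paste0("M", i)
  names(labels) <- genes
  labels <- refine_by_kme(expr, labels, kme_min, min_module_size)
  labels <- merge_close_modules(labels, expr, merge_cut)
  structure(list(labels = labels, sizes = table(labels)),
            class = "module_partition")
}

# Iterative kME reassignment: genes move to their best-correlated module
# eigengene when that correlation reaches kme_min, otherwise become
# unassigned; undersized modules dissolve. Converges to a fixed point.
refine_by_kme <- function(expr, labels, kme_min, min_module_size,
                          max_iter = 10L) {
  for (it in seq_len(max_iter)) {
    mods <- setdiff(unique(labels), "unassigned")
    if (!length(mods)) return(labels)
    eig <- module_eigengenes(expr, labels)
    kme <- suppressWarnings(stats::cor(t(expr), eig))
    kme[is.na(kme)] <- 0
    best_col <- max.col(kme, ties.method = "first")
    best_val <- kme[cbind(seq_len(nrow(kme)), best_col)]
    new <- ifelse(best_val >= kme_min, colnames(kme)[best_col], "unassigned")
    names(new) <- rownames(expr)
    sz <- table(new[new != "unassigned"])
    new[new %in% names(sz)[sz < min_module_size]] <- "unassigned"
    if (identical(unname(new), unname(labels))) break
    labels <- new
  }
  labels
}

merge_close_modules <- function(labels, expr, merge_cut) {
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2L) return(labels)
    eig <- module_eigengenes(expr, labels)
    cm <- stats::cor(eig)
    diag(cm) <- -Inf
    top <- which(cm == base::max(cm), arr.ind = TRUE)[1L, ]
    if (cm[top[1L], top[2L]] <= 1 - merge_cut) return(labels)
    from <- colnames(cm)[base::max(top)]
    into <- colnames(cm)[base::min(top)]
    labels[labels == from] <- into
  }
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal direction of its
#' genes-by-samples submatrix after standardizing each gene, scaled to unit
#' variance across samples and sign-aligned so that it correlates
#' non-negatively with the module's mean expression profile. A one-gene
#' module's eigengene is that gene's standardized profile.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param labels Named gene-to-module assignment (a `module_partition`'s
#'   `labels`, or any named character vector); `"unassigned"` genes are
#'   skipped.
#' @return A samples-by-modules numeric matrix of eigengene values.
#' @export
module_eigengenes <- function(expr, labels) {
  if (inherits(labels, "module_partition")) labels <- labels$labels
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) stopf("no assigned modules")
  mods <- mods[order(as.integer(sub("^M", "", mods)), mods, na.last = TRUE)]
  out <- sapply(mods, function(m) {
    x <- expr[names(labels)[labels == m], , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[is.na(xs)] <- 0
    e <- if (nrow(xs) == 1L) as.numeric(xs) else svd(xs, nu = 0, nv = 1)$v[, 1L]
    if (stats::sd(e) > 0) e <- e / stats::sd(e)
    mp <- colMeans(xs)
    if (stats::sd(mp) > 0 && stats::cor(e, mp) < 0) e <- -e
    e
  })
  rownames(out) <- colnames(expr)
  out
}

#' Module-trait Pearson correlation with significance flags
#'
#' Pearson r of every eigengene against every trait column, with two-sided
#' p-values from the t transform on `n - 2` degrees of freedom. A cell is
#' flagged significant when `|r| > r_cut` and `p < p_cut` (defaults 0.8 and
#' 0.001). Constant traits give `NA` r and are never significant.
#'
#' @param eigengenes Samples-by-modules matrix from [module_eigengenes()].
#' @param traits Samples-by-traits numeric matrix (0/1 indicators or
#'   covariates), rows matching the eigengene samples.
#' @param r_cut,p_cut Significance thresholds.
#' @return A list of class `module_trait_cor`: matrices `r`, `p`,
#'   `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     r_cut = 0.8, p_cut = 0.001) {
  if (nrow(eigengenes) != nrow(traits))
    stopf("eigengenes and traits must share the sample axis")
  n <- nrow(eigengenes)
  if (n < 3L) stopf("need >= 3 samples")
  traits <- as.matrix(traits)
  const <- apply(traits, 2L, function(tr) stats::sd(tr) == 0)
  r <- suppressWarnings(stats::cor(eigengenes, traits))
  r[, const] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- !is.na(r) & abs(r) > r_cut & p < p_cut
  structure(list(r = r, p = p, significant = sig), class = "module_trait_cor")
}

#' Full co-expression pipeline
#'
#' Soft-threshold scan, TOM, module cut, eigengenes and (optionally)
#' trait correlation in one deterministic call.
#'
#' @param expr Genes-by-samples matrix.
#' @param traits Optional samples-by-traits matrix.
#' @param config A [pipeline_config()].
#' @return A list with `scan`, `tom`, `partition`, `eigengenes`, and
#'   `trait_cor` (NULL when no traits given).
#' @export
coexpression_pipeline <- function(expr, traits = NULL,
                                  config = pipeline_config()) {
  expr <- drop_zero_variance(expr)
  scan <- pick_soft_threshold(expr, powers = config$powers,
                              r2_cut = config$r2_cut)
  power <- if (identical(config$power, "auto")) scan$selected_power
  else config$power
  tom <- tom_similarity(expr, power)
  part <- cut_modules(tom, expr,
                      min_module_size = config$min_module_size,
                      cut_height = config$cut_height,
                      merge_cut = config$merge_cut)
  eig <- if (length(setdiff(unique(part$labels), "unassigned")))
    module_eigengenes(expr, part) else NULL
  tc <- if (!is.null(traits) && !is.null(eig))
    module_trait_correlation(eig, traits) else NULL
  list(scan = scan, tom = tom, partition = part,
       eigengenes = eig, trait_cor = tc)
}
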