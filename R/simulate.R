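#' Simulate an aligned codon pair with controlled NG86 divergence
#'
#' Generates a stop-free ancestral codon sequence (uniform over sense
#' codons, optionally GC-biased) and plants synonymous and nonsynonymous
#' single-nucleotide differences so that the expected NG86-counted
#' divergences equal `true_ds` and `true_dn` under Jukes-Cantor geometry:
#' a site differs with probability `p = (3/4)(1 - exp(-4 d / 3))`. Each
#' codon carries at most one planted change, assigned to either lineage
#' with equal probability; changes that would create a stop codon are never
#' proposed.
#'
#' @param n_codons Number of codons (>= 30).
#' @param true_ds Target synonymous divergence (Ks), >= 0.
#' @param true_dn Target nonsynonymous divergence (Ka), >= 0 (default 0).
#' @param seed RNG seed.
#' @param gc Background GC content of the ancestral draw (default 0.5; a
#'   plant nuclear genome is nearer 0.4).
#' @return A list with `cds_a`, `cds_b`, `ancestor` and the parameters.
#' @export
simulate_codon_pair <- function(n_codons, true_ds, true_dn = 0, seed = 1L,
                                gc = 0.5) {
  if (n_codons < 30L) stopf("n_codons must be >= 30")
  if (true_ds < 0 || true_dn < 0 || !is.finite(true_ds) || !is.finite(true_dn))
    stopf("divergences must be finite and >= 0")
  p_s <- 0.75 * (1 - exp(-4 * true_ds / 3))
  p_n <- 0.75 * (1 - exp(-4 * true_dn / 3))
  tab <- .codon_tables
  opt <- .option_matrices
  set.seed(seed)
  w <- codon_weights(gc)
  idx <- sample(length(tab$sense), n_codons, replace = TRUE, prob = w)
  pr_s <- p_s * opt$syn_n[idx] / 3
  pr_n <- p_n * opt$nonsyn_n[idx] / 3
  if (any(pr_s + pr_n > 1))
    stopf("divergence targets unreachable (per-codon change probability > 1)")
  u <- stats::runif(n_codons)
  syn_hit <- u < pr_s
  non_hit <- !syn_hit & u < pr_s + pr_n
  new_codon <- rep(NA_character_, n_codons)
  if (any(syn_hit)) {
    pickc <- floor(stats::runif(sum(syn_hit)) * opt$syn_n[idx[syn_hit]]) + 1L
    new_codon[syn_hit] <- opt$syn[cbind(idx[syn_hit], pickc)]
  }
  if (any(non_hit)) {
    pickc <- floor(stats::runif(sum(non_hit)) * opt$nonsyn_n[idx[non_hit]]) + 1L
    new_codon[non_hit] <- opt$nonsyn[cbind(idx[non_hit], pickc)]
  }
  anc <- tab$sense[idx]
  a <- anc; b <- anc
  changed <- !is.na(new_codon)
  to_a <- changed & stats::runif(n_codons) < 0.5
  a[to_a] <- new_codon[to_a]
  b[changed & !to_a] <- new_codon[changed & !to_a]
  list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
       ancestor = paste(anc, collapse = ""),
       n_codons = n_codons, true_ds = true_ds, true_dn = true_dn, seed = seed)
}

codon_weights <- function(gc) {
  sense <- .codon_tables$sense
  n_gc <- vapply(strsplit(sense, "", fixed = TRUE),
                 function(s) sum(s %in% c("G", "C")), numeric(1))
  (gc / 2)^n_gc * ((1 - gc) / 2)^(3 - n_gc)
}

#' Simulate a batch of codon pairs at one true divergence
#'
#' @param n_pairs Number of replicate pairs.
#' @param n_codons Codons per pair.
#' @param true_ds,true_dn Target divergences.
#' @param seed Base seed; pair i uses `seed + i`.
#' @return A data.frame ready for [ks_batch()].
#' @export
simulate_codon_pairs <- function(n_pairs, n_codons, true_ds, true_dn = 0,
                                 seed = 1L) {
  sims <- lapply(seq_len(n_pairs), function(i)
    simulate_codon_pair(n_codons, true_ds, true_dn, seed = seed + i))
  data.frame(pair_id = sprintf("pair%04d", seq_len(n_pairs)),
             cds_a = vapply(sims, `[[`, character(1), "cds_a"),
             cds_b = vapply(sims, `[[`, character(1), "cds_b"),
             stringsAsFactors = FALSE)
}

#' Simulate chromosomes with planted telomeres and a centromeric satellite
#'
#' Each chromosome gets a `CCCTAAA` array at its 5' end and a `TTTAGGG`
#' array at its 3' end (`telomere_copies` exact units each), and one
#' mid-chromosome tandem array of `centromere_copies` copies of a random
#' monomer, each copy independently mutated by substitutions at
#' `mutation_rate` per base. Ground-truth intervals are returned alongside
#' the sequences (0-based half-open).
#'
#' @param n_chromosomes Number of chromosomes (default 3).
#' @param chromosome_length Length in bp (default 2e6).
#' @param telomere_copies Heptamer units per end (default 150).
#' @param monomer_length Centromeric monomer length in bp (default 422; the
#'   other classic plant satellite scale is 153).
#' @param centromere_copies Monomer copies (default 500).
#' @param mutation_rate Per-base substitution rate applied to each monomer
#'   copy (default 0.02).
#' @param gc Background GC content (default 0.4, typical of a plant
#'   nuclear genome).
#' @param seed RNG seed.
#' @return A list with `genome` (named character vector) and `truth`
#'   (data.frame: `chrom`, `type`, `start`, `stop`, `detail`).
#' @export
simulate_genome <- function(n_chromosomes = 3L, chromosome_length = 2e6,
                            telomere_copies = 150L, monomer_length = 422L,
                            centromere_copies = 500L, mutation_rate = 0.02,
                            gc = 0.4, seed = 1L) {
  L <- as.integer(chromosome_length)
  tel_len <- 7L * telomere_copies
  cen_len <- monomer_length * centromere_copies
  if (2L * tel_len + cen_len + 2000L > L)
    stopf("planted arrays (%d bp) do not fit in a %d bp chromosome",
          2L * tel_len + cen_len, L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  genome <- character(n_chromosomes)
  names(genome) <- sprintf("chr%d", seq_len(n_chromosomes))
  truth <- list()
  # one satellite family genome-wide: all chromosomes share the monomer
  monomer <- paste(sample(bases, monomer_length, replace = TRUE, prob = pb),
                   collapse = "")
  for (ci in seq_len(n_chromosomes)) {
    copies <- vapply(seq_len(centromere_copies), function(j)
      mutate_string(monomer, mutation_rate, bases), character(1))
    cen <- paste(copies, collapse = "")
    cen_start <- as.integer(L / 2 - cen_len / 2)
    left_bg <- paste(sample(bases, cen_start - tel_len, replace = TRUE,
                            prob = pb), collapse = "")
    right_bg <- paste(sample(bases, L - cen_start - cen_len - tel_len,
                             replace = TRUE, prob = pb), collapse = "")
    tel5 <- if (telomere_copies > 0)
      strrep(TELOMERE_FWD, telomere_copies) else ""
    tel3 <- if (telomere_copies > 0)
      strrep(TELOMERE_REV, telomere_copies) else ""
    genome[ci] <- paste0(tel5, left_bg, cen, right_bg, tel3)
    ch <- names(genome)[ci]
    rows <- data.frame(
      chrom = ch,
      type = c("telomere_5p", "telomere_3p", "centromere"),
      start = c(0L, L - tel_len, cen_start),
      stop = c(tel_len, L, cen_start + cen_len),
      detail = c(TELOMERE_FWD, TELOMERE_REV,
                 sprintf("monomer_%dbp_x%d", monomer_length,
                         centromere_copies)),
      stringsAsFactors = FALSE)
    if (telomere_copies == 0) rows <- rows[rows$type == "centromere", ]
    truth[[ci]] <- rows
  }
  list(genome = genome, truth = do.call(rbind, truth))
}

mutate_string <- function(x, rate, bases) {
  if (rate <= 0) return(x)
  s <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(bases, s[i]), 1L)
  paste(s, collapse = "")
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Samples are split into contiguous blocks, one per module; module m's
#' latent profile is the standardized indicator of its block, so each
#' module is locked to one sample trait. A gene in module m is
#' `load * latent_m + noise` with `load ~ U(0.5, 1)` and Gaussian noise;
#' background genes are pure standard noise.
#'
#' @param n_samples Number of samples (>= 4; default 10).
#' @param n_modules Planted modules (default 4; 0 gives pure noise).
#' @param genes_per_module Genes per module (default 50).
#' @param n_background Pure-noise genes (default 100).
#' @param noise_sd Within-module noise standard deviation (default 0.3).
#' @param seed RNG seed.
#' @return A list with `expr` (genes x samples), `labels` (truth:
#'   `"M1"`... or `"unassigned"`), `latents` (samples x modules), `traits`
#'   (samples x modules 0/1 design).
#' @export
simulate_expression <- function(n_samples = 10L, n_modules = 4L,
                                genes_per_module = 50L, n_background = 100L,
                                noise_sd = 0.3, seed = 1L) {
  if (n_samples < 4L) stopf("need >= 4 samples")
  set.seed(seed)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  n_genes <- n_modules * genes_per_module + n_background
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
                 dimnames = list(gene_ids, sample_ids))
  labels <- rep("unassigned", n_genes)
  names(labels) <- gene_ids
  latents <- NULL; traits <- NULL
  if (n_modules > 0L) {
    block <- sort(rep_len(seq_len(n_modules), n_samples))
    traits <- sapply(seq_len(n_modules), function(m) as.integer(block == m))
    dimnames(traits) <- list(sample_ids, sprintf("trait%d", seq_len(n_modules)))
    latents <- apply(traits, 2L, function(ind) as.numeric(scale(ind)))
    colnames(latents) <- sprintf("M%d", seq_len(n_modules))
    for (m in seq_len(n_modules)) {
      rows <- (m - 1L) * genes_per_module + seq_len(genes_per_module)
      load <- stats::runif(genes_per_module, 0.5, 1)
      expr[rows, ] <- outer(load, latents[, m]) +
        matrix(stats::rnorm(genes_per_module * n_samples, sd = noise_sd),
               nrow = genes_per_module)
      labels[rows] <- sprintf("M%d", m)
    }
  }
  list(expr = expr, labels = labels, latents = latents, traits = traits)
}

#' Simulate metabolite time courses with planted abundance clusters
#'
#' Cluster latent time-courses are orthogonal contrast shapes over the
#' sampling times (optionally, cluster 1 is locked to a supplied latent
#' profile to exercise expression-metabolome integration); each metabolite
#' is a noisy copy of its cluster latent.
#'
#' @param n_clusters Planted clusters (default 3).
#' @param per_cluster Metabolites per cluster (default 20).
#' @param times Sampling times in days after flowering (default
#'   `c(45, 60, 75, 90)`, a four-stage fruit schedule whose last interval
#'   is 75 to 90 days).
#' @param noise_sd Noise standard deviation (default 0.2).
#' @param link Optional numeric latent (length `length(times)`) to which
#'   cluster 1 is locked.
#' @param seed RNG seed.
#' @return A list with `metab` (metabolites x timepoints, columns named
#'   `T<day>`), `labels` (truth cluster per metabolite), `latents`
#'   (timepoints x clusters), `times`.
#' @export
simulate_metabolites <- function(n_clusters = 3L, per_cluster = 20L,
                                 times = c(45, 60, 75, 90), noise_sd = 0.2,
                                 link = NULL, seed = 1L) {
  n_t <- length(times)
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (n_clusters >= n_t + 1L && is.null(link))
    stopf("at most %d orthogonal cluster shapes exist for %d time points",
          n_t - 1L, n_t)
  set.seed(seed)
  contr <- stats::contr.helmert(n_t)  # orthogonal, zero-sum columns
  latents <- apply(contr[, seq_len(base::min(n_clusters, ncol(contr))),
                         drop = FALSE], 2L, function(z) as.numeric(scale(z)))
  if (ncol(latents) < n_clusters)
    latents <- cbind(latents, matrix(stats::rnorm(n_t * (n_clusters - ncol(latents))),
                                     nrow = n_t))
  if (!is.null(link)) {
    if (length(link) != n_t) stopf("`link` must have one value per time point")
    latents[, 1L] <- as.numeric(scale(link))
  }
  colnames(latents) <- sprintf("C%d", seq_len(n_clusters))
  rownames(latents) <- paste0("T", times)
  n_m <- n_clusters * per_cluster
  ids <- sprintf("met%03d", seq_len(n_m))
  labels <- rep(seq_len(n_clusters), each = per_cluster)
  names(labels) <- ids
  metab <- latents[, labels, drop = FALSE]
  metab <- t(metab) + matrix(stats::rnorm(n_m * n_t, sd = noise_sd),
                             nrow = n_m)
  dimnames(metab) <- list(ids, paste0("T", times))
  list(metab = metab, labels = labels, latents = latents, times = times)
}
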