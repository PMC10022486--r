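#' Expected synonymous and nonsynonymous site counts (NG86)
#'
#' For every codon and each of its three positions, the synonymous fraction
#' is the number of the three possible single-nucleotide changes that
#' preserve the encoded amino acid, divided by three. Changes producing a
#' stop codon are classed nonsynonymous. Fractions sum over the sequence
#' into `S`; `N = 3 * n_codons - S`.
#'
#' @param cds A coding DNA string (A/C/G/T), length a multiple of 3, no
#'   internal stop codons. A terminal stop codon is trimmed with a warning.
#' @return A list with elements `S` and `N`.
#' @examples
#' count_sites("TTT") # S = 1/3: only TTT -> TTC is synonymous
#' @export
count_sites <- function(cds) {
  codons <- validate_cds(cds)
  S <- sum(.codon_tables$syn_sites[codons])
  list(S = S, N = 3 * length(codons) - S)
}

#' Pathway-averaged synonymous and nonsynonymous difference counts (NG86)
#'
#' Codons differing at one position contribute one difference classified
#' directly; codons differing at two or three positions average the
#' synonymous/nonsynonymous split over all 2 (or 6) mutational pathways,
#' excluding pathways that pass through a stop codon. Per-codon
#' contributions sum to `Sd` and `Nd`, and `Sd + Nd` equals the observed
#' nucleotide difference count.
#'
#' @param cds_a,cds_b Aligned coding DNA strings of equal length.
#' @return A list with elements `Sd` and `Nd`.
#' @export
count_differences <- function(cds_a, cds_b) {
  pair <- validate_codon_pair(cds_a, cds_b)
  idx <- cbind(match(pair$a, .codon_tables$sense),
               match(pair$b, .codon_tables$sense))
  list(Sd = sum(.pair_diff_matrices$SD[idx]),
       Nd = sum(.pair_diff_matrices$ND[idx]))
}

#' Nei-Gojobori (1986) Ka/Ks estimate for one aligned codon pair
#'
#' Site counts are averaged over the two sequences; proportions
#' `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - (4/3) p)`, giving Ks (dS) and Ka (dN). Pairs with
#' `pS >= 3/4` or `pN >= 3/4` are flagged `saturated` (the corresponding
#' distance is `NA`), never dropped. `omega = Ka/Ks` is `NA` when `Ks = 0`.
#'
#' @param cds_a,cds_b Aligned coding DNA strings: equal length, a multiple
#'   of 3, no gaps, no internal stop codons.
#' @param pair_id Optional identifier carried into the result.
#' @return A one-row data.frame with columns `pair_id`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`, `status`
#'   (`ok`/`saturated`/`undefined`).
#' @examples
#' ng86("TTTGGGAAA", "TTCGGGAAA") # Ks = -0.75 * log(0.2), Ka = 0
#' @export
ng86 <- function(cds_a, cds_b, pair_id = NA_character_) {
  pair <- validate_codon_pair(cds_a, cds_b)
  ia <- match(pair$a, .codon_tables$sense)
  ib <- match(pair$b, .codon_tables$sense)
  Sa <- sum(.codon_tables$syn_sites[ia])
  Sb <- sum(.codon_tables$syn_sites[ib])
  n_cod <- length(pair$a)
  S <- (Sa + Sb) / 2
  N <- 3 * n_cod - S
  sd <- sum(.pair_diff_matrices$SD[cbind(ia, ib)])
  nd <- sum(.pair_diff_matrices$ND[cbind(ia, ib)])
  pS <- if (S > 0) sd / S else NA_real_
  pN <- if (N > 0) nd / N else NA_real_
  status <- "ok"
  if (is.na(pS) || is.na(pN)) status <- "undefined"
  else if (pS >= 0.75 || pN >= 0.75) status <- "saturated"
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  data.frame(pair_id = pair_id, S = S, N = N, Sd = sd, Nd = nd,
             pS = pS, pN = pN, Ks = Ks, Ka = Ka, omega = omega,
             status = status, stringsAsFactors = FALSE)
}

#' Jukes-Cantor distance from a difference proportion
#'
#' `d = -(3/4) log(1 - (4/3) p)`; returns `NA` at or beyond the saturation
#' bound `p >= 3/4`.
#'
#' @param p Proportion of differing sites, in `[0, 1]`.
#' @return Corrected distance, or `NA` if saturated or `p` is `NA`.
#' @export
jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p < 0) stopf("difference proportion must be >= 0")
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 estimates for a table of codon pairs
#'
#' @param pairs A data.frame with columns `pair_id`, `cds_a`, `cds_b`.
#' @return A data.frame with one [ng86()] row per pair, input order
#'   preserved; serializable to TSV with [write_ks_table()].
#' @export
ks_batch <- function(pairs) {
  req <- c("pair_id", "cds_a", "cds_b")
  if (!is.data.frame(pairs) || !all(req %in% names(pairs)))
    stopf("`pairs` must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  if (nrow(pairs) == 0L)
    return(ng86("AAA", "AAA")[0L, ])
  if (anyDuplicated(pairs$pair_id))
    stopf("duplicate pair_id: %s", pairs$pair_id[duplicated(pairs$pair_id)][1L])
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rows[[i]] <- tryCatch(
      ng86(pairs$cds_a[i], pairs$cds_b[i], pair_id = pairs$pair_id[i]),
      error = function(e)
        stopf("invalid pair '%s': %s", pairs$pair_id[i], conditionMessage(e)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read codon pairs from two matched FASTA files
#'
#' Sequences are matched by order; ids are joined as `idA|idB`.
#'
#' @param path_a,path_b FASTA files with the same number of records.
#' @return A data.frame suitable for [ks_batch()].
#' @export
read_codon_pairs <- function(path_a, path_b) {
  a <- read_fasta(path_a); b <- read_fasta(path_b)
  if (length(a) != length(b))
    stopf("paired FASTA files differ in record count (%d vs %d)",
          length(a), length(b))
  data.frame(pair_id = paste(names(a), names(b), sep = "|"),
             cds_a = unname(a), cds_b = unname(b),
             stringsAsFactors = FALSE)
}

#' Write an NG86 result table as TSV
#'
#' @param ks_table Result of [ks_batch()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ks_table <- function(ks_table, path) {
  utils::write.table(ks_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- validation -------------------------------------------------------------

validate_cds <- function(cds, what = "sequence") {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds))
    stopf("%s must be a single DNA string", what)
  cds <- toupper(cds)
  if (grepl("-", cds, fixed = TRUE))
    stopf("%s contains gap characters; input must be gap-free codon-aligned",
          what)
  if (grepl("[^ACGT]", cds))
    stopf("%s contains characters other than A,C,G,T", what)
  if (nchar(cds) == 0L || nchar(cds) %% 3L != 0L)
    stopf("%s length (%d) is not a positive multiple of 3", what, nchar(cds))
  codons <- split_codons(cds)
  aa <- .codon_tables$aa[codons]
  stops <- which(aa == "*")
  if (length(stops)) {
    if (length(stops) == 1L && stops == length(codons)) {
      warnf("terminal stop codon trimmed from %s", what)
      codons <- codons[-length(codons)]
      if (length(codons) == 0L) stopf("%s is a bare stop codon", what)
    } else {
      stopf("internal stop codon at codon %d of %s", stops[1L], what)
    }
  }
  codons
}

validate_codon_pair <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stopf("codon pair sequences differ in length (%d vs %d)",
          nchar(cds_a), nchar(cds_b))
  a <- validate_cds(cds_a, "sequence a")
  b <- validate_cds(cds_b, "sequence b")
  if (length(a) != length(b))
    stopf("codon pair misaligned after terminal-stop trimming")
  list(a = a, b = b)
}
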