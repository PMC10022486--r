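# Independent oracles for the NG86 engine, plus small shared utilities.
# These re-derive expected values from first principles (standard genetic
# code, exhaustive enumeration) without touching the package's counting
# internals.

options(evomics.verbose = FALSE)

GC_TAB <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) GC_TAB[[codon]]

codon_split <- function(cds)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))

# Hand-enumeration oracle for expected synonymous sites: try all 9
# single-nucleotide changes of every codon and count the amino-acid
# preserving ones (changes to stop codons count as nonsynonymous).
oracle_sites <- function(cds) {
  S <- 0
  for (codon in codon_split(cds)) {
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- b
        if (translate_codon(alt) != "*" &&
            translate_codon(alt) == translate_codon(codon))
          S <- S + 1 / 3
      }
    }
  }
  list(S = S, N = 3 * nchar(cds) / 3 - S)
}

# Exhaustive pathway oracle: recursively enumerate every ordering of the
# differing positions, classify each step, drop orderings that visit a
# stop codon (keep all orderings if none survives).
oracle_codon_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(cur, remaining, through_stop_ok) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (translate_codon(nxt) == "*" && !through_stop_ok) next
      step <- if (translate_codon(nxt) != "*" &&
                  translate_codon(cur) != "*" &&
                  translate_codon(nxt) == translate_codon(cur))
        c(1, 0) else c(0, 1)
      for (restpath in walk(nxt, setdiff(remaining, p), through_stop_ok))
        out[[length(out) + 1]] <- step + restpath
    }
    out
  }
  paths <- walk(c1, pos, FALSE)
  if (!length(paths)) paths <- walk(c1, pos, TRUE)
  colMeans(do.call(rbind, paths))
}

oracle_differences <- function(a, b) {
  ca <- codon_split(a); cb <- codon_split(b)
  tot <- c(0, 0)
  for (i in seq_along(ca)) tot <- tot + oracle_codon_diff(ca[i], cb[i])
  list(Sd = tot[1], Nd = tot[2])
}

# NG86 Ks/Ka re-derived from the oracles only.
oracle_ng86 <- function(a, b) {
  sa <- oracle_sites(a); sb <- oracle_sites(b)
  S <- (sa$S + sb$S) / 2
  N <- (sa$N + sb$N) / 2
  d <- oracle_differences(a, b)
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d$Sd, Nd = d$Nd,
       Ks = jc(if (S > 0) d$Sd / S else NA), Ka = jc(if (N > 0) d$Nd / N else NA))
}

# Random stop-free codon sequence, and a pair derived by random mutation.
SENSE_CODONS <- names(GC_TAB)[GC_TAB != "*"]
random_cds <- function(n_codons)
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")

random_pair <- function(n_codons, n_mut = 2) {
  a <- random_cds(n_codons)
  repeat {
    b <- a
    for (i in sample(nchar(a), min(n_mut, nchar(a)))) {
      substr(b, i, i) <- sample(setdiff(BASES, substr(b, i, i)), 1)
    }
    cods <- codon_split(b)
    if (all(GC_TAB[cods] != "*")) return(list(a = a, b = b))
  }
}

count_seq_diffs <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Map each recovered module to the planted latent it best matches.
match_modules_to_latents <- function(eigengenes, latents) {
  r <- cor(eigengenes, latents)
  apply(abs(r), 1, function(x) colnames(latents)[which.max(x)])
}
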