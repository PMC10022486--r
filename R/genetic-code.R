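# Precomputed standard-genetic-code tables used by the NG86 engine and the
# codon-pair simulator. Changes that create a stop codon are classed
# nonsynonymous for site counting and are excluded from the simulator's
# proposal sets.

.codon_tables <- local({
  bases <- c("A", "C", "G", "T")
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  sense <- codons[aa != "*"]

  mutate1 <- function(codon, pos, base) {
    s <- strsplit(codon, "", fixed = TRUE)[[1L]]
    s[pos] <- base
    paste(s, collapse = "")
  }

  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  syn_changes <- vector("list", length(sense))     # synonymous single-nt moves
  nonsyn_changes <- vector("list", length(sense))  # nonsynonymous, stop-free
  names(syn_changes) <- names(nonsyn_changes) <- sense

  for (cd in sense) {
    s_pos <- character(0); s_to <- character(0)
    n_pos <- character(0); n_to <- character(0)
    frac <- 0
    for (pos in 1:3) {
      cur <- substr(cd, pos, pos)
      for (b in setdiff(bases, cur)) {
        nb <- mutate1(cd, pos, b)
        if (gc_tab[[nb]] == "*") next  # stop-creating: nonsyn site, no move
        if (gc_tab[[nb]] == gc_tab[[cd]]) {
          frac <- frac + 1 / 3
          s_pos <- c(s_pos, pos); s_to <- c(s_to, nb)
        } else {
          n_pos <- c(n_pos, pos); n_to <- c(n_to, nb)
        }
      }
    }
    syn_sites[[cd]] <- frac
    syn_changes[[cd]] <- s_to
    nonsyn_changes[[cd]] <- n_to
  }

  list(gc = gc_tab, codons = codons, aa = stats::setNames(aa, codons),
       sense = sense, syn_sites = syn_sites,
       syn_changes = syn_changes, nonsyn_changes = nonsyn_changes)
})

.perms3 <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Pathway-averaged (Sd, Nd) for one codon pair, memoized: orderings of the
# differing positions define mutational pathways; pathways visiting a stop
# codon are dropped from the average (all pathways kept if none survives).
.ng86_pair_cache <- new.env(parent = emptyenv())

codon_pair_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  hit <- .ng86_pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- .codon_tables
  s1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  s2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  diff_pos <- which(s1 != s2)
  nd_tot <- length(diff_pos)
  paths <- .perms3[[nd_tot]]
  acc <- matrix(NA_real_, nrow = length(paths), ncol = 2L)
  for (i in seq_along(paths)) {
    ord <- diff_pos[paths[[i]]]
    cur <- s1
    sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      prev_codon <- paste(cur, collapse = "")
      cur[pos] <- s2[pos]
      next_codon <- paste(cur, collapse = "")
      if (tab$aa[[next_codon]] == "*") { ok <- FALSE; break }
      if (tab$aa[[next_codon]] == tab$aa[[prev_codon]]) sd <- sd + 1
      else nd <- nd + 1
    }
    if (ok) acc[i, ] <- c(sd, nd)
  }
  valid <- !is.na(acc[, 1L])
  if (!any(valid)) {
    # every ordering crosses a stop; fall back to counting through stops
    for (i in seq_along(paths)) {
      ord <- diff_pos[paths[[i]]]
      cur <- s1
      sd <- 0; nd <- 0
      for (pos in ord) {
        prev_codon <- paste(cur, collapse = "")
        cur[pos] <- s2[pos]
        next_codon <- paste(cur, collapse = "")
        same <- tab$aa[[next_codon]] != "*" && tab$aa[[prev_codon]] != "*" &&
          tab$aa[[next_codon]] == tab$aa[[prev_codon]]
        if (same) sd <- sd + 1 else nd <- nd + 1
      }
      acc[i, ] <- c(sd, nd)
    }
    valid <- rep(TRUE, length(paths))
  }
  res <- c(sd = mean(acc[valid, 1L]), nd = mean(acc[valid, 2L]))
  assign(key, res, envir = .ng86_pair_cache)
  res
}

split_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
}

# Dense sense-codon-pair lookup of pathway-averaged (Sd, Nd), built once at
# install time from codon_pair_diff; lets ng86 run fully vectorized.
.pair_diff_matrices <- local({
  sense <- .codon_tables$sense
  n <- length(sense)
  SD <- matrix(0, n, n, dimnames = list(sense, sense))
  ND <- SD
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- codon_pair_diff(sense[i], sense[j])
    SD[i, j] <- d[["sd"]]
    ND[i, j] <- d[["nd"]]
  }
  list(SD = SD, ND = ND)
})

# Option matrices for the codon-pair simulator: row = ancestral sense
# codon, columns = its synonymous / stop-free nonsynonymous neighbors.
.option_matrices <- local({
  sc <- .codon_tables$syn_changes
  nc <- .codon_tables$nonsyn_changes
  pad <- function(lst) {
    w <- max(lengths(lst))
    t(vapply(lst, function(x) c(x, rep(NA_character_, w - length(x))),
             character(w)))
  }
  list(syn = pad(sc), syn_n = lengths(sc),
       nonsyn = pad(nc), nonsyn_n = lengths(nc))
})
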