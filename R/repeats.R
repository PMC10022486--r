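TELOMERE_FWD <- "CCCTAAA"
TELOMERE_REV <- "TTTAGGG"  # reverse complement of the plant heptamer

#' Detect telomeric heptamer arrays at chromosome ends
#'
#' Scans the first and last `window` bp of a chromosome for maximal runs of
#' the plant telomere heptamer (`CCCTAAA`, and its reverse complement
#' `TTTAGGG`); both orientations are searched at both ends and reported as
#' found. A run may contain mutated heptamer units as long as the mutated
#' fraction stays at or below `max_divergence`. Coordinates are 0-based
#' half-open.
#'
#' @param chrom A single DNA string.
#' @param chrom_name Chromosome id carried into the calls.
#' @param window Terminal window in bp (default 10000). Chromosomes shorter
#'   than twice the window are scanned whole, with a warning.
#' @param min_copies Minimum heptamer units per reported run (default 10).
#' @param max_divergence Maximum fraction of mutated units in a run
#'   (default 0.1).
#' @return A data.frame with columns `chrom`, `end`
#'   (`five_prime`/`three_prime`), `start`, `stop`, `copies`, `matched`,
#'   `motif`.
#' @export
find_telomeres <- function(chrom, chrom_name = "chr",
                           window = 10000L, min_copies = 10L,
                           max_divergence = 0.1) {
  if (window < 7L * min_copies)
    stopf("window (%d) must be >= 7 * min_copies", window)
  chrom <- toupper(chrom)
  L <- nchar(chrom)
  if (L < 2L * window) {
    warnf("chromosome %s (%d bp) shorter than twice the terminal window; scanning whole sequence",
          chrom_name, L)
    regions <- list(list(offset = 0L, seq = chrom, end = NA_character_))
  } else {
    regions <- list(
      list(offset = 0L, seq = substr(chrom, 1L, window), end = "five_prime"),
      list(offset = L - window,
           seq = substr(chrom, L - window + 1L, L), end = "three_prime"))
  }
  calls <- list()
  for (reg in regions) {
    for (motif in c(TELOMERE_FWD, TELOMERE_REV)) {
      runs <- heptamer_runs(reg$seq, motif, min_copies, max_divergence)
      if (nrow(runs) == 0L) next
      runs$start <- runs$start + reg$offset
      runs$stop <- runs$stop + reg$offset
      runs$motif <- motif
      runs$end <- if (is.na(reg$end)) {
        ifelse((runs$start + runs$stop) / 2 < L / 2, "five_prime", "three_prime")
      } else reg$end
      runs$chrom <- chrom_name
      calls[[length(calls) + 1L]] <- runs
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(0), end = character(0),
                      start = integer(0), stop = integer(0),
                      copies = integer(0), matched = integer(0),
                      motif = character(0)))
  out <- do.call(rbind, calls)
  out <- out[, c("chrom", "end", "start", "stop", "copies", "matched", "motif")]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximal runs of exact motif matches spaced by multiples of 7; skipped
# (mutated) units inside a run count against the divergence budget.
# Coordinates 0-based within `seq`.
heptamer_runs <- function(seq, motif, min_copies, max_divergence) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  empty <- data.frame(start = integer(0), stop = integer(0),
                      copies = integer(0), matched = integer(0))
  if (hits[1L] == -1L) return(empty)
  starts0 <- as.integer(hits) - 1L
  runs <- list()
  run_start <- starts0[1L]; last <- starts0[1L]; matched <- 1L
  flush <- function(run_start, last, matched) {
    copies <- as.integer((last + 7L - run_start) / 7L)
    if (matched >= min_copies &&
        (copies - matched) / copies <= max_divergence)
      data.frame(start = run_start, stop = last + 7L,
                 copies = copies, matched = matched)
    else empty
  }
  for (p in starts0[-1L]) {
    gap <- p - last
    if (gap %% 7L == 0L && gap <= 7L * 5L) {
      last <- p; matched <- matched + 1L
    } else {
      runs[[length(runs) + 1L]] <- flush(run_start, last, matched)
      run_start <- p; last <- p; matched <- 1L
    }
  }
  runs[[length(runs) + 1L]] <- flush(run_start, last, matched)
  do.call(rbind, runs)
}

#' Detect tandem-repeat arrays by k-mer lag chaining
#'
#' A simplified tandem-repeat finder for high-copy satellites: exact
#' 13-mer self-matches at a lag within `[min_period, max_period]` seed
#' candidate arrays; seeds with a consistent lag are chained along the
#' chromosome, the consensus monomer is taken by column majority over the
#' array cut into period-length frames, and arrays are accepted when mean
#' frame-to-consensus identity is at least `min_identity` and the copy
#' number at least `min_copies`. Substitution divergence is handled;
#' insertions/deletions inside the array are not modelled.
#'
#' @param chrom A single DNA string.
#' @param chrom_name Chromosome id carried into the results.
#' @param min_period,max_period Monomer length bounds in bp (defaults 20
#'   and 2000, bracketing typical plant centromeric satellites such as
#'   153 bp and 422 bp monomers).
#' @param min_copies Minimum (real-valued) copy number (default 5).
#' @param min_identity Minimum mean monomer-to-consensus identity
#'   (default 0.8).
#' @param k Seed k-mer length (default 13).
#' @return A data.frame with columns `chrom`, `start`, `stop` (0-based
#'   half-open), `period`, `copies`, `identity`, `monomer` (consensus).
#' @export
find_tandem_arrays <- function(chrom, chrom_name = "chr",
                               min_period = 20L, max_period = 2000L,
                               min_copies = 5, min_identity = 0.8,
                               k = 13L) {
  if (min_period < 2L || max_period < min_period)
    stopf("need 2 <= min_period <= max_period")
  chrom <- toupper(chrom)
  n <- nchar(chrom)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      stop = integer(0), period = integer(0),
                      copies = numeric(0), identity = numeric(0),
                      monomer = character(0), stringsAsFactors = FALSE)
  if (n < 2L * min_period || n < k + min_period) return(empty)
  code <- kmer_codes(chrom, k)
  valid <- which(!is.na(code))
  if (!length(valid)) return(empty)
  dt <- data.table::data.table(pos = valid, code = code[valid])
  data.table::setorderv(dt, c("code", "pos"))
  # gap to the next occurrence of the same k-mer (vectorized; sorted order
  # guarantees the next row is the nearest same-code position when codes match)
  dt[, gap := data.table::shift(pos, -1L) - pos]
  dt[data.table::shift(code, -1L) != code, gap := NA_integer_]
  seeds <- dt[!is.na(gap) & gap >= min_period & gap <= max_period]
  if (nrow(seeds) < 3L) return(empty)
  data.table::setorderv(seeds, "pos")
  # split into clusters at positional jumps larger than max_period
  brk <- c(TRUE, diff(seeds$pos) > max_period)
  seeds[, cluster := cumsum(brk)]
  out <- list()
  for (cl in split(seeds, seeds$cluster)) {
    if (nrow(cl) < 3L) next
    lag_tab <- table(cl$gap)
    period <- as.integer(names(lag_tab)[which.max(lag_tab)])
    cl <- cl[abs(cl$gap - period) <= 2L]
    if (nrow(cl) < 3L) next
    # re-split: members must be within 2 periods of each other
    brk2 <- c(TRUE, diff(cl$pos) > 2L * period)
    for (sub in split(cl, cumsum(brk2))) {
      if (nrow(sub) < 3L) next
      start0 <- sub$pos[1L] - 1L
      stop0 <- base::min(sub$pos[nrow(sub)] - 1L + period + k, n)
      arr <- consensus_monomer(substr(chrom, start0 + 1L, stop0), period)
      if (is.null(arr)) next
      copies <- (stop0 - start0) / period
      if (copies >= min_copies && arr$identity >= min_identity)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom_name, start = start0, stop = stop0,
          period = period, copies = copies, identity = arr$identity,
          monomer = arr$consensus, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Rolling base-4 k-mer codes; positions covering a non-ACGT base are NA.
kmer_codes <- function(seq, k) {
  v <- utf8ToInt(seq)
  map <- rep(NA_real_, 128L)
  map[utf8ToInt("A")] <- 0; map[utf8ToInt("C")] <- 1
  map[utf8ToInt("G")] <- 2; map[utf8ToInt("T")] <- 3
  b <- map[v]
  n <- length(b)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code + b[(1L + j):(m + j)] * 4^(k - 1L - j)
  code
}

# Column-majority consensus over period-length frames; returns consensus
# string and mean frame identity, or NULL if fewer than 2 full frames.
consensus_monomer <- function(region, period) {
  n_frames <- nchar(region) %/% period
  if (n_frames < 2L) return(NULL)
  frames <- substring(region, (seq_len(n_frames) - 1L) * period + 1L,
                      seq_len(n_frames) * period)
  m <- matrix(unlist(strsplit(frames, "", fixed = TRUE)),
              nrow = n_frames, byrow = TRUE)
  cons <- apply(m, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]
  })
  ident <- mean(m == matrix(cons, nrow = n_frames, ncol = period, byrow = TRUE))
  list(consensus = paste(cons, collapse = ""), identity = ident)
}

#' Cluster tandem-array monomers into satellite families
#'
#' Greedy centroid clustering in the style of CD-HIT: arrays are sorted by
#' span length descending; each array joins the first existing family whose
#' representative monomer matches at `identity_threshold` or better, under
#' the best ungapped circular rotation (tandem monomer phase is arbitrary)
#' on either strand; otherwise it founds a new family.
#'
#' @param arrays Result of [find_tandem_arrays()] (rows from one or more
#'   chromosomes).
#' @param identity_threshold Minimum rotation-best identity to join a
#'   family (default 0.8).
#' @return `arrays` with an integer `family` column added; family 1 is the
#'   family founded by the longest array.
#' @export
cluster_monomers <- function(arrays, identity_threshold = 0.8) {
  if (nrow(arrays) == 0L) stopf("no arrays to cluster")
  ord <- order(-(arrays$stop - arrays$start))
  reps <- character(0)
  fam <- integer(nrow(arrays))
  for (i in ord) {
    m <- arrays$monomer[i]
    assigned <- 0L
    for (f in seq_along(reps)) {
      if (rotation_identity(m, reps[f]) >= identity_threshold) {
        assigned <- f; break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, m)
      assigned <- length(reps)
    }
    fam[i] <- assigned
  }
  arrays$family <- fam
  arrays
}

#' Best circular-rotation ungapped identity between two monomers
#'
#' Compared over all rotations of the first monomer, on both strands.
#' Monomers whose lengths differ by more than 10% score 0.
#'
#' @param a,b Monomer DNA strings.
#' @return Identity in `[0, 1]`.
#' @export
rotation_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (base::max(la, lb) == 0) return(0)
  if (abs(la - lb) / base::max(la, lb) > 0.1) return(0)
  L <- base::min(la, lb)
  bb <- strsplit(substr(b, 1L, L), "", fixed = TRUE)[[1L]]
  best <- 0
  for (strand_a in c(a, revcomp(a))) {
    doubled <- strsplit(paste0(strand_a, strand_a), "", fixed = TRUE)[[1L]]
    for (off in 0:(la - 1L)) {
      ident <- mean(doubled[(off + 1L):(off + L)] == bb)
      if (ident > best) best <- ident
    }
  }
  best
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Call one putative centromere per chromosome from satellite families
#'
#' Ranks families by genome-wide summed array length, keeps the top
#' `n_top_families`, and on each chromosome merges member arrays lying
#' within `join_distance` of each other into candidate spans. The span
#' with the greatest total member-array length wins (ties: longer span,
#' then leftmost); at most one call per chromosome.
#'
#' @param arrays Result of [cluster_monomers()] (must carry `family`).
#' @param join_distance Maximum gap between member arrays merged into one
#'   span (default 1e5 bp).
#' @param n_top_families Number of top satellite families considered
#'   (default 2).
#' @return A data.frame with columns `chrom`, `start`, `stop`, `family`,
#'   `monomer_length`, `array_fraction`.
#' @export
call_centromeres <- function(arrays, join_distance = 1e5, n_top_families = 2L) {
  if (is.null(arrays$family)) stopf("run cluster_monomers() first")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      stop = integer(0), family = integer(0),
                      monomer_length = integer(0),
                      array_fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(arrays) == 0L) return(empty)
  fam_len <- tapply(arrays$stop - arrays$start, arrays$family, sum)
  top <- as.integer(names(sort(fam_len, decreasing = TRUE)))
  top <- head(top, n_top_families)
  cand <- arrays[arrays$family %in% top, , drop = FALSE]
  out <- list()
  for (ch in unique(arrays$chrom)) {
    a <- cand[cand$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0L) {
      log_stage("call_centromeres", chrom = ch, note = "no qualifying arrays")
      next
    }
    a <- a[order(a$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, a$start[-1L] - a$stop[-nrow(a)] > join_distance))
    spans <- do.call(rbind, lapply(split(a, grp), function(g) {
      data.frame(start = base::min(g$start), stop = base::max(g$stop),
                 member_len = sum(g$stop - g$start),
                 family = g$family[which.max(g$stop - g$start)],
                 monomer_length = g$period[which.max(g$stop - g$start)])
    }))
    spans <- spans[order(-spans$member_len,
                         -(spans$stop - spans$start), spans$start), ,
                   drop = FALSE]
    best <- spans[1L, ]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = best$start, stop = best$stop,
      family = best$family, monomer_length = best$monomer_length,
      array_fraction = best$member_len / (best$stop - best$start),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Telomere and centromere annotation for a whole assembly
#'
#' Runs [find_telomeres()], [find_tandem_arrays()], [cluster_monomers()]
#' and [call_centromeres()] over every chromosome.
#'
#' @param genome Named character vector of chromosome sequences (e.g. from
#'   [read_fasta()]).
#' @param config A [pipeline_config()].
#' @return A list with `telomeres`, `arrays`, `centromeres` data.frames.
#' @export
annotate_repeats <- function(genome, config = pipeline_config()) {
  tel <- do.call(rbind, lapply(names(genome), function(ch)
    find_telomeres(genome[[ch]], ch,
                   window = config$telomere_window,
                   min_copies = config$telomere_min_copies,
                   max_divergence = config$telomere_max_divergence)))
  arr <- do.call(rbind, lapply(names(genome), function(ch)
    find_tandem_arrays(genome[[ch]], ch,
                       min_period = config$tandem_min_period,
                       max_period = config$tandem_max_period,
                       min_copies = config$tandem_min_copies,
                       min_identity = config$tandem_min_identity)))
  cen <- if (!is.null(arr) && nrow(arr) > 0) {
    arr <- cluster_monomers(arr, config$monomer_identity_threshold)
    call_centromeres(arr, join_distance = config$centromere_join_distance)
  } else NULL
  list(telomeres = tel, arrays = arr, centromeres = cen)
}
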