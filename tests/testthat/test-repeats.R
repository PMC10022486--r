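# Small planted-truth fixtures: chromosomes are built in code, so every
# expected interval is known exactly.

make_chrom <- function(len, seed = 1, tel5 = 0, tel3 = 0,
                       insert = NULL, insert_at = NULL) {
  set.seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
  if (!is.null(insert)) {
    stopifnot(insert_at + nchar(insert) <= len)
    bg <- paste0(substr(bg, 1, insert_at),
                 insert,
                 substr(bg, insert_at + nchar(insert) + 1, len))
  }
  paste0(strrep("CCCTAAA", tel5), bg, strrep("TTTAGGG", tel3))
}

revcomp_str <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("planted telomere arrays are recovered with exact copy numbers", {
  chrom <- make_chrom(30000, seed = 31, tel5 = 150, tel3 = 150)
  calls <- find_telomeres(chrom, "chrT", window = 5000)
  expect_equal(nrow(calls), 2L)
  p5 <- calls[calls$end == "five_prime", ]
  expect_equal(p5$copies, 150L)
  expect_equal(p5$start, 0L)
  expect_equal(p5$stop, 1050L)
  expect_equal(p5$motif, "CCCTAAA")
  p3 <- calls[calls$end == "three_prime", ]
  expect_equal(p3$copies, 150L)
  expect_equal(p3$motif, "TTTAGGG")
  expect_equal(p3$stop, nchar(chrom))
})

test_that("random sequence yields no telomere calls", {
  chrom <- make_chrom(30000, seed = 32)
  expect_equal(nrow(find_telomeres(chrom, window = 5000)), 0L)
})

test_that("telomere scan is strand-symmetric", {
  chrom <- make_chrom(30000, seed = 33, tel5 = 40, tel3 = 25)
  L <- nchar(chrom)
  fwd <- find_telomeres(chrom, window = 5000)
  rev <- find_telomeres(revcomp_str(chrom), window = 5000)
  expect_equal(nrow(rev), nrow(fwd))
  # mirrored coordinates, swapped ends and motifs
  for (i in seq_len(nrow(fwd))) {
    mirrored <- rev[rev$start == L - fwd$stop[i], ]
    expect_equal(nrow(mirrored), 1L)
    expect_equal(mirrored$stop, L - fwd$start[i])
    expect_equal(mirrored$copies, fwd$copies[i])
    expect_false(mirrored$end == fwd$end[i])
    expect_false(mirrored$motif == fwd$motif[i])
  }
})

test_that("short chromosomes are scanned whole with a warning", {
  chrom <- paste0(strrep("CCCTAAA", 20), make_chrom(3000, seed = 34))
  expect_warning(calls <- find_telomeres(chrom, window = 5000,
                                         min_copies = 10),
                 "shorter")
  expect_equal(calls$copies, 20L)
  expect_equal(calls$end, "five_prime")
})

test_that("interrupted heptamer runs tolerate divergence up to the budget", {
  # 30 units with unit 15 mutated: one run of 30 copies, 29 matched
  arr <- paste0(strrep("CCCTAAA", 14), "CCCTGAA", strrep("CCCTAAA", 15))
  chrom <- paste0(arr, make_chrom(20000, seed = 35))
  expect_warning(calls <- find_telomeres(chrom, window = 15000))
  expect_equal(calls$copies, 30L)
  expect_equal(calls$matched, 29L)
})

test_that("planted satellite arrays are recovered with correct period", {
  set.seed(36)
  for (mono_len in c(422L, 153L)) {
    sim <- simulate_genome(n_chromosomes = 1L, chromosome_length = 3e5,
                           telomere_copies = 20L, monomer_length = mono_len,
                           centromere_copies = 120L, mutation_rate = 0.02,
                           seed = 100 + mono_len)
    arr <- find_tandem_arrays(sim$genome[[1]], "chr1")
    expect_equal(nrow(arr), 1L)
    expect_lte(abs(arr$period - mono_len), 2L)
    expect_lt(abs(arr$copies - 120) / 120, 0.05)
    expect_gte(arr$identity, 0.8)
    truth <- sim$truth[sim$truth$type == "centromere", ]
    expect_gte(interval_jaccard(arr$start, arr$stop, truth$start, truth$stop),
               0.9)
  }
})

test_that("shuffled sequence contains no high-copy tandem arrays", {
  sim <- simulate_genome(n_chromosomes = 1L, chromosome_length = 1e5,
                         telomere_copies = 10L, monomer_length = 153L,
                         centromere_copies = 60L, seed = 37)
  s <- strsplit(sim$genome[[1]], "")[[1]]
  set.seed(38)
  for (i in 1:10) {
    shuf <- paste(sample(s), collapse = "")
    arr <- find_tandem_arrays(shuf, "shuf")
    expect_true(nrow(arr) == 0L || all(arr$copies < 10))
  }
})

test_that("monomer clustering is rotation- and strand-invariant", {
  set.seed(39)
  mono <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  rot <- paste0(substr(mono, 41, 100), substr(mono, 1, 40))
  expect_gte(rotation_identity(mono, rot), 0.999)
  expect_gte(rotation_identity(revcomp_str(mono), rot), 0.999)
  arrays <- data.frame(chrom = c("c1", "c2"), start = c(0L, 0L),
                       stop = c(1000L, 900L), period = c(100L, 100L),
                       copies = c(10, 9), identity = c(0.95, 0.95),
                       monomer = c(mono, rot), stringsAsFactors = FALSE)
  fam <- cluster_monomers(arrays)
  expect_equal(fam$family[1], fam$family[2])
})

test_that("different monomer families stay distinct; mutated copies join", {
  set.seed(40)
  m422 <- paste(sample(c("A", "C", "G", "T"), 422, replace = TRUE),
                collapse = "")
  m153 <- paste(sample(c("A", "C", "G", "T"), 153, replace = TRUE),
                collapse = "")
  expect_equal(rotation_identity(m422, m153), 0)
  mutate <- function(x, rate) {
    s <- strsplit(x, "")[[1]]
    idx <- which(runif(length(s)) < rate)
    for (i in idx) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
    paste(s, collapse = "")
  }
  arrays <- data.frame(
    chrom = paste0("c", 1:6),
    start = 0L, stop = c(4220L, 4000L, 3900L, 1530L, 1500L, 1400L),
    period = c(422L, 422L, 422L, 153L, 153L, 153L),
    copies = 10, identity = 0.95,
    monomer = c(m422, mutate(m422, 0.05), mutate(m422, 0.05),
                m153, mutate(m153, 0.05), mutate(m153, 0.05)),
    stringsAsFactors = FALSE)
  fam <- cluster_monomers(arrays, identity_threshold = 0.8)
  expect_equal(length(unique(fam$family[1:3])), 1L)
  expect_equal(length(unique(fam$family[4:6])), 1L)
  expect_false(fam$family[1] == fam$family[4])
})

test_that("one centromere is called per chromosome, at the planted span", {
  sim <- simulate_genome(n_chromosomes = 3L, chromosome_length = 3e5,
                         telomere_copies = 20L, monomer_length = 422L,
                         centromere_copies = 120L, seed = 41)
  ann <- annotate_repeats(sim$genome)
  expect_equal(nrow(ann$centromeres), 3L)
  truth <- sim$truth[sim$truth$type == "centromere", ]
  for (i in seq_len(3)) {
    cen <- ann$centromeres[ann$centromeres$chrom == truth$chrom[i], ]
    expect_equal(nrow(cen), 1L)
    expect_gte(interval_jaccard(cen$start, cen$stop,
                                truth$start[i], truth$stop[i]), 0.9)
  }
  # telomere calls never overlap centromere calls
  for (i in seq_len(nrow(ann$telomeres))) {
    tel <- ann$telomeres[i, ]
    cen <- ann$centromeres[ann$centromeres$chrom == tel$chrom, ]
    expect_true(tel$stop <= cen$start || tel$start >= cen$stop)
  }
})

test_that("centromere ties break to the longer then leftmost span", {
  arrays <- data.frame(
    chrom = "c1", start = c(0L, 500000L), stop = c(1000L, 501000L),
    period = 100L, copies = 10, identity = 0.95, monomer = "A",
    family = 1L, stringsAsFactors = FALSE)
  cen <- call_centromeres(arrays, join_distance = 1000)
  expect_equal(cen$start, 0L) # equal members and spans -> leftmost

  arrays2 <- arrays
  arrays2$stop[2] <- 502000L # second span longer
  cen2 <- call_centromeres(arrays2, join_distance = 1000)
  expect_equal(cen2$start, 500000L)
})

test_that("chromosomes without satellite arrays get no centromere call", {
  arrays <- data.frame(chrom = "c1", start = 0L, stop = 1000L,
                       period = 100L, copies = 10, identity = 0.95,
                       monomer = "A", family = 1L, stringsAsFactors = FALSE)
  cen <- call_centromeres(arrays)
  expect_equal(cen$chrom, "c1")
  expect_equal(nrow(cen), 1L)
})
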