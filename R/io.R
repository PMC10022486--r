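#' Read a DNA FASTA file
#'
#' Reads a FASTA file of DNA sequences, uppercasing sequences and joining
#' wrapped lines. Only `A`, `C`, `G`, `T` and `N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase DNA sequences, one element
#'   per record, in file order; names are the record ids (first whitespace
#'   token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stopf("non-DNA characters in %s (only A,C,G,T,N allowed)", path)
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stopf("FASTA record with empty id in %s", path)
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("record '%s' contains non-DNA characters (only A,C,G,T,N allowed)",
          ids[bad][1L])
  if (any(!nzchar(seqs)))
    stopf("record '%s' has an empty sequence", ids[!nzchar(seqs)][1L])
  stats::setNames(seqs, ids)
}

#' Write DNA sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Read a numeric feature-by-sample matrix from TSV
#'
#' The file must have a header row of sample ids and a first column of
#' feature ids. Every cell must parse as a number; missing values are
#' rejected with the offending row and column named.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("matrix file %s has no data rows", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  col_ids <- header[-1L]
  if (length(col_ids) == 0L) stopf("matrix file %s has no sample columns", path)
  if (anyDuplicated(col_ids)) stopf("duplicate column id in %s", path)
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != length(header)))
    stopf("ragged row %d in %s: %d fields, expected %d",
          which(widths != length(header))[1L] + 1L, path,
          widths[widths != length(header)][1L], length(header))
  row_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(row_ids))
    stopf("duplicate row id '%s' in %s", row_ids[duplicated(row_ids)][1L], path)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(length(col_ids))))
  vals <- matrix(vals, ncol = length(col_ids), byrow = TRUE,
                 dimnames = list(row_ids, col_ids))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("non-numeric or missing cell at row '%s', column '%s' in %s",
          row_ids[idx[1L]], col_ids[idx[2L]], path)
  }
  vals
}

#' Write a numeric matrix as TSV with feature ids in the first column
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the id column (default `"id"`).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write repeat calls as BED6
#'
#' Coordinates are 0-based half-open throughout the package, matching BED.
#' Lines are sorted by chromosome then start.
#'
#' @param calls A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score` (optional, default 0) and `strand` (optional, default `"."`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(calls, path) {
  req <- c("chrom", "start", "end", "name")
  if (!all(req %in% names(calls)))
    stopf("BED calls need columns %s", paste(req, collapse = ", "))
  if (nrow(calls) > 0 && any(calls$start >= calls$end))
    stopf("BED interval with start >= end (row %d)",
          which(calls$start >= calls$end)[1L])
  if (is.null(calls$score)) calls$score <- 0
  if (is.null(calls$strand)) calls$strand <- "."
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  out <- calls[, c("chrom", "start", "end", "name", "score", "strand")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file written by [write_bed()].
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "name", "score", "strand"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Pipeline configuration with documented defaults
#'
#' Collects the tunable parameters of every stage into one validated list.
#' Unknown keys are an error, so typos cannot silently fall back to
#' defaults. All RNG-consuming stages read their seed from here.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of parameters with class `evomics_config`.
#' @section Defaults:
#' \describe{
#'   \item{seed}{1 — master RNG seed.}
#'   \item{ks_filter_min, ks_filter_max}{0.01, 5 — Ks retention bounds.}
#'   \item{kde_n}{512 — KDE grid size.}
#'   \item{peak_min_prominence}{0.05 — prominence floor, fraction of max density.}
#'   \item{telomere_window}{10000 bp; telomere_min_copies 10;
#'     telomere_max_divergence 0.1.}
#'   \item{tandem_min_period, tandem_max_period}{20, 2000 bp;
#'     tandem_min_copies 5; tandem_min_identity 0.8.}
#'   \item{monomer_identity_threshold}{0.8 — satellite family clustering.}
#'   \item{centromere_join_distance}{1e5 bp.}
#'   \item{powers}{1:20; r2_cut 0.8 — soft-threshold scan.}
#'   \item{power}{8 — network power used by the pipeline (the protocol's
#'     lowest scale-free-adequate power); `"auto"` takes it from the scan.}
#'   \item{min_module_size}{30; cut_height 0.9 (fraction of the
#'     merge-height span); merge_cut 0.25.}
#'   \item{k_range}{c(2, 12); n_init 25 — metabolite k-means cascade.}
#' }
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    ks_filter_min = 0.01, ks_filter_max = 5,
    kde_n = 512L, peak_min_prominence = 0.05,
    telomere_window = 10000L, telomere_min_copies = 10L,
    telomere_max_divergence = 0.1,
    tandem_min_period = 20L, tandem_max_period = 2000L,
    tandem_min_copies = 5, tandem_min_identity = 0.8,
    monomer_identity_threshold = 0.8,
    centromere_join_distance = 1e5,
    powers = 1:20, r2_cut = 0.8, power = 8L,
    min_module_size = 30L, cut_height = 0.9, merge_cut = 0.25,
    k_range = c(2L, 12L), n_init = 25L
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stopf("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "evomics_config")
}
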