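# Readers and writers.
#
# All tables use one flat TSV dialect: tab-separated, first line a
# '#'-prefixed header, rows written in sorted key order so outputs are
# diff-able and bitwise reproducible. Sequences are FASTA (via
# Biostrings); coding intervals are BED (0-based, half-open); trees are
# Newick.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (DNA or protein).
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of uppercased sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) .err("dropstrain_io_error", "no such file: %s", path)
  ss <- tryCatch(
    if (type == "DNA") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path),
    error = function(e) .err("dropstrain_parse_error", "%s: %s",
                             path, conditionMessage(e)))
  if (!length(ss)) .err("dropstrain_parse_error", "%s: empty FASTA", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    .err("dropstrain_parse_error", "%s: duplicate id(s): %s", path,
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a table in the package TSV dialect
#'
#' @param df data.frame; rows are written as-is (sort before calling for
#'   reproducible output).
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a table in the package TSV dialect
#'
#' @param path file whose first line is a '#'-prefixed header.
#' @return data.table with columns typed by `utils::type.convert`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) .err("dropstrain_io_error", "no such file: %s", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    .err("dropstrain_parse_error", "%s:1: missing '#'-prefixed header", path)
  cols <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t",
                          colClasses = NULL, na.strings = "NA")
  if (!nrow(dt))
    return(data.table::setnames(data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(cols)), cols)), cols))
  if (ncol(dt) != length(cols))
    .err("dropstrain_parse_error", "%s: %d columns in rows vs %d in header",
         path, ncol(dt), length(cols))
  data.table::setnames(dt, cols)
  dt
}

#' Write / read a pileup table
#'
#' Rows are sorted by (species, contig, pos, sample) on write; on read
#' the header, base composition of `ref`, positivity of `pos` and
#' non-negativity of counts are validated with the offending line
#' reported.
#'
#' @param pileup pileup data.table.
#' @param path TSV file.
#' @return `read_pileup` returns the validated pileup data.table.
#' @export
write_pileup <- function(pileup, path) {
  dt <- data.table::as.data.table(pileup)
  data.table::setorder(dt, species, contig, pos, sample)
  write_tsv(dt, path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  dt <- read_tsv(path)
  req <- c("species", "contig", "pos", "ref", "sample",
           "count_A", "count_C", "count_G", "count_T", "coding")
  if (!all(req %in% names(dt)))
    .err("dropstrain_parse_error", "%s: missing column(s): %s", path,
         paste(setdiff(req, names(dt)), collapse = ", "))
  bad <- which(!dt$ref %in% .BASES)
  if (length(bad))
    .err("dropstrain_parse_error", "%s:%d: reference base not in ACGT",
         path, bad[1] + 1L)
  bad <- which(dt$pos < 1L)
  if (length(bad))
    .err("dropstrain_parse_error", "%s:%d: position must be >= 1 (1-based)",
         path, bad[1] + 1L)
  cnts <- as.matrix(dt[, c("count_A", "count_C", "count_G", "count_T")])
  bad <- which(rowSums(cnts < 0) > 0)
  if (length(bad))
    .err("dropstrain_parse_error", "%s:%d: negative allele count",
         path, bad[1] + 1L)
  dt$coding <- as.logical(dt$coding)
  dt
}

#' Write / read coding intervals as BED (0-based, half-open)
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`
#'   (a `species` column, if present, is carried in the BED name field).
#' @param path BED file.
#' @return `read_bed` returns a data.frame `contig`, `start`, `end`,
#'   `name`.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("species" %in% names(intervals)) intervals$species else "."
  df <- data.frame(intervals$contig, intervals$start, intervals$end, nm)
  df <- df[order(df[[1]], df[[2]]), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .err("dropstrain_io_error", "no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    .err("dropstrain_parse_error", "%s: BED needs >= 3 columns", path)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name" else df$name <- "."
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad))
    .err("dropstrain_parse_error",
         "%s:%d: invalid interval (need 0 <= start < end)", path, bad[1])
  df[, c("contig", "start", "end", "name")]
}

#' Write / read a distance matrix (lossless round-trip)
#'
#' @param d symmetric labelled matrix.
#' @param path TSV file.
#' @return `read_distance` returns the labelled matrix.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  dt <- read_tsv(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  colnames(m) <- names(dt)[-1]
  storage.mode(m) <- "double"
  m
}

#' Write / read a Newick tree
#'
#' @param newick Newick string.
#' @param path output file.
#' @return `read_newick` returns an `ape::phylo`.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
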