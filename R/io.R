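# Plain-text readers and writers. All interval formats keep the 0-based
# half-open BED convention of the rest of the package; FASTA goes through
# Biostrings.

#' Read a FASTA file
#' @param path File path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA (60-column wrap)
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write a clone set as FASTA with truth labels in the headers
#' @param clone_set A `clone_set` from [simulate_clones()].
#' @param path Output path.
#' @export
write_clone_fasta <- function(clone_set, path) {
  stopifnot(inherits(clone_set, "clone_set"))
  tr <- clone_set$truth
  hdr <- sprintf("%s jk=%s offset=%d in_frame=%s seed=%d", tr$clone_id,
                 tr$jk, tr$offset, tr$in_frame, clone_set$seed)
  seqs <- clone_set$sequences
  names(seqs) <- hdr
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read paired-end fragments from a 3-column BED file
#' @param path BED3 path (chrom, start, end; 0-based half-open).
#' @return A [fragment_set()].
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "numeric", "numeric"))
  fragment_set(chrom = df$chrom, start = df$start, end = df$end)
}

#' Write a fragment set as BED3
#' @param fs A [fragment_set()].
#' @param path Output path.
#' @export
write_fragments_bed <- function(fs, path) {
  stopifnot(inherits(fs, "fragment_set"))
  utils::write.table(fs[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of named regions
#' @param path BED6 (or BED4+) path.
#' @return Data frame `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (is.null(df$name)) df$name <- sprintf("region_%d", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "+"
  df
}

#' Write named regions as BED6
#' @param df Data frame with `chrom`, `start`, `end`, `name` and optionally
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name,
                    score = if (is.null(df$score)) 0 else df$score,
                    strand = if (is.null(df$strand)) "+" else df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the planted truth annotations of a synthetic locus as BED6
#'
#' One record per gene body (name = segment), plus records for planted RSS
#' footprints and GAGA motifs.
#' @param locus A `locus` from [build_locus()].
#' @param path Output path.
#' @export
write_locus_truth_bed <- function(locus, path) {
  stopifnot(inherits(locus, "locus"))
  a <- locus$annotations
  recs <- data.frame(chrom = locus$name, start = a$body_start,
                     end = a$body_end, name = a$segment_name, score = 0,
                     strand = "+")
  rss <- a[!is.na(a$heptamer_start), , drop = FALSE]
  if (nrow(rss) > 0L)
    recs <- rbind(recs, data.frame(
      chrom = locus$name, start = rss$heptamer_start,
      end = rss$nonamer_start + 9, name = paste0(rss$segment_name, "_RSS"),
      score = 0, strand = "+"))
  gg <- a[!is.na(a$gaga_start), , drop = FALSE]
  if (nrow(gg) > 0L)
    recs <- rbind(recs, data.frame(
      chrom = locus$name, start = gg$gaga_start, end = gg$gaga_end,
      name = paste0(gg$segment_name, "_GAGA"), score = 0, strand = "+"))
  recs <- recs[order(recs$start), , drop = FALSE]
  write_bed6(recs, path)
}

#' Write a signal track as bedGraph
#'
#' Adjacent bases with equal values are collapsed into one record; values
#' are written with fixed 4-decimal precision.
#' @param track A `signal_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  v <- round(track$values, 4)
  r <- rle(v)
  ends <- track$start + cumsum(r$lengths)
  starts <- c(track$start, ends[-length(ends)])
  lines <- sprintf("%s\t%d\t%d\t%.4f", track$chrom, starts, ends, r$values)
  writeLines(lines, path)
  invisible(path)
}

#' Write a spacing report as TSV
#' @param report A `spacing_report`.
#' @param path Output path.
#' @export
write_spacing_report <- function(report, path) {
  stopifnot(inherits(report, "spacing_report"))
  utils::write.table(report$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Ct table (TSV with columns group, gene, ct)
#' @param path TSV path.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
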