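#' @keywords internal
#' @importFrom Biostrings DNAString DNAStringSet matchPattern
#'   reverseComplement pairwiseAlignment nucleotideSubstitutionMatrix pid
#'   readDNAStringSet writeXStringSet
#' @importFrom BiocGenerics start end width score
#' @importFrom stats rnorm runif dnorm convolve sd var t.test pt setNames
#' @importFrom utils read.table write.table read.delim
"_PACKAGE"

# Shared internal helpers: sequence validation, reverse complement,
# seeded RNG scoping. Coordinates are 0-based half-open throughout the
# package; conversion to R's 1-based strings happens only at substring
# boundaries inside these helpers and the scanners.

.check_dna <- function(seq, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains non-nucleotide characters (allowed: ACGTN, uppercase)",
         call. = FALSE)
  invisible(seq)
}

.revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Random DNA at a given GC fraction, returned as a character vector of bases.
.random_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Count mismatches between pattern and the substring of `chars` (a character
# vector of single bases) starting at 0-based position `at`.
.mm_count <- function(chars, at, pattern_chars) {
  k <- length(pattern_chars)
  sum(chars[(at + 1L):(at + k)] != pattern_chars)
}

# Merge overlapping 0-based half-open intervals given as a two-column matrix;
# returns a matrix with columns start, end, sorted.
.merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L)
    return(cbind(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] < me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}
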