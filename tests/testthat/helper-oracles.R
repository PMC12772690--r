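# Brute-force oracles, deliberately written with base R string operations
# only (no Biostrings), independent of the scanner implementations.

bf_revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

bf_mm <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Exhaustive single-strand RSS enumeration: every (heptamer position, spacer)
# window checked against the default rule set.
bf_scan_rss_plus <- function(seq, spacer_class = 23L, tol = 1L,
                             hep = "CACAGTG", non = "ACAAAAACC",
                             pre = 3L, hep_mm = 1L, non_mm = 2L) {
  n <- nchar(seq)
  rows <- list()
  for (h in 0:(n - 1)) {
    if (h + 7 > n) next
    hw <- substr(seq, h + 1, h + 7)
    if (substr(hw, 1, pre) != substr(hep, 1, pre)) next
    if (bf_mm(hw, hep) > hep_mm) next
    for (sp in (spacer_class - tol):(spacer_class + tol)) {
      ns <- h + 7 + sp
      if (ns + 9 > n) next
      nw <- substr(seq, ns + 1, ns + 9)
      if (bf_mm(nw, non) <= non_mm)
        rows[[length(rows) + 1]] <- data.frame(
          heptamer_start = h, nonamer_start = ns, spacer_len = sp,
          heptamer_mismatches = bf_mm(hw, hep),
          nonamer_mismatches = bf_mm(nw, non))
    }
  }
  if (length(rows) == 0)
    return(data.frame(heptamer_start = integer(0), nonamer_start = integer(0),
                      spacer_len = integer(0),
                      heptamer_mismatches = integer(0),
                      nonamer_mismatches = integer(0)))
  do.call(rbind, rows)
}

bf_scan_rss <- function(seq, spacer_class = 23L) {
  n <- nchar(seq)
  plus <- bf_scan_rss_plus(seq, spacer_class)
  plus$strand <- if (nrow(plus)) "+" else character(0)
  rc <- bf_scan_rss_plus(bf_revcomp(seq), spacer_class)
  if (nrow(rc)) {
    rc$strand <- "-"
    hs <- rc$heptamer_start; ns <- rc$nonamer_start
    rc$heptamer_start <- n - hs - 7
    rc$nonamer_start <- n - ns - 9
  }
  out <- rbind(plus, rc)
  out[order(pmin(out$heptamer_start, out$nonamer_start), out$strand), ,
      drop = FALSE]
}

# All 0-based starts of fixed pattern pat in seq, overlapping allowed.
bf_pattern_starts <- function(seq, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Merged pentamer-tier GAGA hits on both strands.
bf_scan_gaga_pentamer <- function(seq) {
  merge_iv <- function(st, w) {
    if (length(st) == 0) return(NULL)
    st <- sort(st); s <- st[1]; e <- st[1] + w
    out <- NULL
    for (x in st[-1]) {
      if (x < e) e <- x + w
      else { out <- rbind(out, c(s, e)); s <- x; e <- x + w }
    }
    rbind(out, c(s, e))
  }
  rows <- NULL
  for (pp in list(c("GAGAG", "+"), c("CTCTC", "-"))) {
    iv <- merge_iv(bf_pattern_starts(seq, pp[1]), 5L)
    if (!is.null(iv))
      rows <- rbind(rows, data.frame(start = iv[, 1], end = iv[, 2],
                                     strand = pp[2]))
  }
  if (is.null(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  rows[order(rows$start, rows$end, rows$strand), , drop = FALSE]
}

# Random DNA string (iid uniform unless probs given).
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Purine-rich random DNA (plenty of GA repeats / near-GAGAG content).
rand_dna_ga <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.38, 0.12, 0.38, 0.12)),
        collapse = "")
}

# Mutate k random positions of a sequence.
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(ch), min(k, length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Random background with implanted (possibly mutated) RSS-like constructs on
# both orientations, so scanner/oracle comparisons exercise real hit sets.
seq_with_rss_decoys <- function(n = 3000, n_implants = 6,
                                spacer_class = 23L) {
  ch <- strsplit(rand_dna(n), "")[[1]]
  slots <- seq(50, n - 100, length.out = n_implants)
  for (pos in round(slots)) {
    unit <- paste0(mutate_seq("CACAGTG", sample(0:2, 1)),
                   rand_dna(spacer_class + sample(-2:2, 1)),
                   mutate_seq("ACAAAAACC", sample(0:3, 1)))
    if (runif(1) < 0.5) unit <- bf_revcomp(unit)
    ch[pos:(pos + nchar(unit) - 1)] <- strsplit(unit, "")[[1]]
  }
  paste(ch, collapse = "")
}

# Column-wise comparison of hit tables ignoring row names / classes.
expect_same_hits <- function(got, want, cols) {
  got <- as.data.frame(got)[, cols, drop = FALSE]
  want <- as.data.frame(want)[, cols, drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
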