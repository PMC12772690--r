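# RSS and GAGA motif scanning, segment annotation, spacing reports and
# restriction-site genotyping helpers.

#' Parameters for RSS scanning
#'
#' The recombination signal sequence (RSS) is modelled as the canonical
#' heptamer `CACAGTG`, a spacer of approximately 12 or 23 bp, and the
#' nonamer `ACAAAAACC`. The consensus sequences and mismatch tolerances
#' follow the canonical V(D)J literature: the first three heptamer bases
#' (`CAC`) are functionally critical and must match exactly; the heptamer
#' remainder tolerates one mismatch and the nonamer two, by default. All
#' of this is configurable.
#'
#' @param heptamer Heptamer consensus (default `"CACAGTG"`).
#' @param nonamer Nonamer consensus (default `"ACAAAAACC"`).
#' @param heptamer_exact_prefix Number of leading heptamer bases required to
#'   match exactly (default 3).
#' @param heptamer_max_mismatch Maximum mismatches allowed in the heptamer
#'   outside the exact prefix (default 1).
#' @param nonamer_max_mismatch Maximum nonamer mismatches (default 2).
#' @param spacer_tol Spacer length tolerance in bp around the nominal
#'   12 or 23 (default 1).
#' @return A list of class `rss_params`.
#' @export
rss_params <- function(heptamer = "CACAGTG", nonamer = "ACAAAAACC",
                       heptamer_exact_prefix = 3L, heptamer_max_mismatch = 1L,
                       nonamer_max_mismatch = 2L, spacer_tol = 1L) {
  .check_dna(heptamer, "heptamer"); .check_dna(nonamer, "nonamer")
  stopifnot(heptamer_exact_prefix >= 0L,
            heptamer_exact_prefix <= nchar(heptamer),
            heptamer_max_mismatch >= 0L, nonamer_max_mismatch >= 0L,
            spacer_tol >= 0L)
  structure(list(heptamer = heptamer, nonamer = nonamer,
                 heptamer_exact_prefix = as.integer(heptamer_exact_prefix),
                 heptamer_max_mismatch = as.integer(heptamer_max_mismatch),
                 nonamer_max_mismatch = as.integer(nonamer_max_mismatch),
                 spacer_tol = as.integer(spacer_tol)),
            class = "rss_params")
}

# Plus-strand scan of one sequence. Returns 0-based positions.
.scan_rss_plus <- function(seq, spacer_class, params) {
  n <- nchar(seq)
  hep <- params$heptamer; non <- params$nonamer
  hl <- nchar(hep); nl <- nchar(non)
  spacers <- (spacer_class - params$spacer_tol):(spacer_class + params$spacer_tol)
  spacers <- spacers[spacers >= 0L]
  empty <- data.frame(heptamer_start = integer(0), nonamer_start = integer(0),
                      spacer_len = integer(0), strand = character(0),
                      heptamer_mismatches = integer(0),
                      nonamer_mismatches = integer(0))
  if (n < hl + min(spacers) + nl) return(empty)

  # Candidate heptamers: total mismatches <= max allows the exact-prefix
  # filter below to implement "prefix exact, <= max in remainder".
  m <- Biostrings::matchPattern(hep, Biostrings::DNAString(seq),
                                max.mismatch = params$heptamer_max_mismatch)
  hstarts <- BiocGenerics::start(m) - 1L
  if (length(hstarts) == 0L) return(empty)
  pre <- params$heptamer_exact_prefix
  if (pre > 0L) {
    keep <- substring(seq, hstarts + 1L, hstarts + pre) == substr(hep, 1L, pre)
    hstarts <- hstarts[keep]
  }
  if (length(hstarts) == 0L) return(empty)

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hep_chars <- strsplit(hep, "", fixed = TRUE)[[1]]
  non_chars <- strsplit(non, "", fixed = TRUE)[[1]]
  rows <- vector("list", length(hstarts) * length(spacers))
  k <- 0L
  for (h in hstarts) {
    hmm <- .mm_count(chars, h, hep_chars)
    for (sp in spacers) {
      ns <- h + hl + sp
      if (ns + nl > n) next
      nmm <- .mm_count(chars, ns, non_chars)
      if (nmm <= params$nonamer_max_mismatch) {
        k <- k + 1L
        rows[[k]] <- data.frame(heptamer_start = h, nonamer_start = ns,
                                spacer_len = sp, strand = "+",
                                heptamer_mismatches = hmm,
                                nonamer_mismatches = nmm)
      }
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, rows[seq_len(k)])
}

#' Scan a sequence for recombination signal sequences
#'
#' Finds heptamer/spacer/nonamer RSS matches on both strands. A hit requires
#' a heptamer match (exact `CAC` prefix, limited mismatches in the remainder),
#' a spacer of `spacer_class` +/- the configured tolerance, and a nonamer
#' match within its mismatch budget. Positions are 0-based half-open in the
#' coordinates of `seq`; for minus-strand hits, `heptamer_start` and
#' `nonamer_start` give the leftmost base of each element's footprint on the
#' plus strand, while `spacer_len` is measured on the hit's own strand.
#'
#' @param seq Uppercase nucleotide string (`ACGTN`).
#' @param spacer_class Nominal spacer length, 12 or 23.
#' @param params An [rss_params()] object.
#' @return A data frame of class `rss_hits` with columns `heptamer_start`,
#'   `nonamer_start`, `spacer_len`, `strand`, `heptamer_mismatches`,
#'   `nonamer_mismatches`, sorted by footprint start.
#' @examples
#' seq <- paste0("AAAA", "CACAGTG", strrep("C", 23), "ACAAAAACC", "AAAA")
#' scan_rss(seq, 23)
#' @export
scan_rss <- function(seq, spacer_class = 23L, params = rss_params()) {
  .check_dna(seq)
  if (!spacer_class %in% c(12L, 23L))
    stop("spacer_class must be 12 or 23", call. = FALSE)
  n <- nchar(seq)
  plus <- .scan_rss_plus(seq, spacer_class, params)
  rc <- .scan_rss_plus(.revcomp(seq), spacer_class, params)
  if (nrow(rc) > 0L) {
    hl <- nchar(params$heptamer); nl <- nchar(params$nonamer)
    minus <- rc
    minus$heptamer_start <- n - rc$heptamer_start - hl
    minus$nonamer_start <- n - rc$nonamer_start - nl
    minus$strand <- "-"
  } else minus <- rc
  hits <- rbind(plus, minus)
  if (nrow(hits) > 0L) {
    fp <- pmin(hits$heptamer_start, hits$nonamer_start)
    hits <- hits[order(fp, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
  }
  class(hits) <- c("rss_hits", "data.frame")
  hits
}

#' Parameters for GAGA motif scanning
#'
#' Three tiers of GA-rich elements are recognised, reflecting GAGA-factor
#' binding biology: the canonical `GAGAG` pentamer (the primary motif),
#' extended GA-repeat runs, and the minimal `GAG` trinucleotide (off by
#' default; exploratory only).
#'
#' @param min_run_length Minimum length of an extended GA run (default 5 nt).
#' @param min_purity Minimum fraction of overlapping dinucleotides within a
#'   purine run that are `GA`/`AG` for the run tier (default 0.8).
#' @param include_gag Also report minimal `GAG` matches (default `FALSE`).
#' @param tiers Which tiers to report; any of `"pentamer"`, `"run"`, `"gag"`.
#' @return A list of class `gaga_params`.
#' @export
gaga_params <- function(min_run_length = 5L, min_purity = 0.8,
                        include_gag = FALSE,
                        tiers = c("pentamer", "run")) {
  stopifnot(min_run_length >= 3L, min_purity >= 0, min_purity <= 1)
  if (include_gag) tiers <- union(tiers, "gag")
  structure(list(min_run_length = as.integer(min_run_length),
                 min_purity = min_purity, tiers = tiers),
            class = "gaga_params")
}

# All 0-based start positions of fixed pattern `pat` in `seq` (plus strand),
# including overlapping occurrences.
.fixed_starts <- function(seq, pat) {
  if (nchar(seq) < nchar(pat)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq))
  BiocGenerics::start(m) - 1L
}

# Merged exact-pattern hits on one strand -> data.frame rows.
.gaga_pattern_tier <- function(seq, pat, strand, tier) {
  st <- .fixed_starts(seq, pat)
  if (length(st) == 0L)
    return(NULL)
  iv <- .merge_intervals(st, st + nchar(pat))
  data.frame(start = iv[, 1], end = iv[, 2], strand = strand, tier = tier,
             run_length = iv[, 2] - iv[, 1])
}

# Maximal GA-purity runs on the plus-strand alphabet {bases}; a run
# qualifies if long enough and its overlapping dinucleotides are mostly
# alternating (GA/AG on +, TC/CT on -).
.gaga_run_tier <- function(seq, strand, params) {
  if (strand == "+") {
    rx <- "[GA]+"; good <- c("GA", "AG")
  } else {
    rx <- "[CT]+"; good <- c("TC", "CT")
  }
  m <- gregexpr(rx, seq)[[1]]
  if (m[1] == -1L) return(NULL)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  keep_s <- integer(0); keep_e <- integer(0); keep_l <- integer(0)
  for (i in seq_along(starts)) {
    if (lens[i] < params$min_run_length) next
    run <- substring(seq, starts[i] + 1L, starts[i] + lens[i])
    di <- substring(run, seq_len(lens[i] - 1L), seq_len(lens[i] - 1L) + 1L)
    if (mean(di %in% good) >= params$min_purity) {
      keep_s <- c(keep_s, starts[i]); keep_e <- c(keep_e, starts[i] + lens[i])
      keep_l <- c(keep_l, lens[i])
    }
  }
  if (length(keep_s) == 0L) return(NULL)
  data.frame(start = keep_s, end = keep_e, strand = strand, tier = "run",
             run_length = keep_l)
}

#' Scan a sequence for GAGA motifs
#'
#' Reports GA-rich elements on both strands within an optional search window,
#' in tiers: `GAGAG` pentamer matches (overlapping matches merged), maximal
#' GA-repeat runs of sufficient length and dinucleotide purity, and (if
#' enabled) minimal `GAG` matches. A minus-strand hit is a pentamer/run on
#' the reverse complement, reported in plus-strand coordinates.
#'
#' @param seq Uppercase nucleotide string.
#' @param window Optional `c(start, end)` 0-based half-open window restricting
#'   the scan; hits are reported in full-sequence coordinates.
#' @param params A [gaga_params()] object.
#' @return A data frame of class `gaga_hits` with columns `start`, `end`,
#'   `strand`, `tier`, `run_length`, sorted by start.
#' @examples
#' scan_gaga("CCCGAGAGCCC")
#' @export
scan_gaga <- function(seq, window = NULL, params = gaga_params()) {
  .check_dna(seq)
  n <- nchar(seq)
  off <- 0L
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 0L, window[2] <= n,
              window[2] > window[1])
    off <- as.integer(window[1])
    seq <- substring(seq, window[1] + 1L, window[2])
  }
  out <- list()
  if ("pentamer" %in% params$tiers) {
    out <- c(out, list(.gaga_pattern_tier(seq, "GAGAG", "+", "pentamer"),
                       .gaga_pattern_tier(seq, "CTCTC", "-", "pentamer")))
  }
  if ("run" %in% params$tiers) {
    out <- c(out, list(.gaga_run_tier(seq, "+", params),
                       .gaga_run_tier(seq, "-", params)))
  }
  if ("gag" %in% params$tiers) {
    out <- c(out, list(.gaga_pattern_tier(seq, "GAG", "+", "gag"),
                       .gaga_pattern_tier(seq, "CTC", "-", "gag")))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    hits <- data.frame(start = integer(0), end = integer(0),
                       strand = character(0), tier = character(0),
                       run_length = integer(0))
  } else {
    hits <- do.call(rbind, out)
    hits$start <- hits$start + off
    hits$end <- hits$end + off
    hits <- hits[order(hits$start, hits$end, hits$tier, hits$strand), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  class(hits) <- c("gaga_hits", "data.frame")
  hits
}

#' Parameters for segment annotation
#'
#' @param spacer_class RSS spacer class expected at these segments (23 for
#'   J segments of Igk/IgH).
#' @param max_rss_distance Maximum gap in bp between the RSS 3' end and the
#'   gene-body start for the RSS to be paired with the segment (default 150).
#' @param gaga_window Size in bp of the 5' window upstream of the nonamer
#'   searched for GAGA motifs (default 1000, accommodating the ~80 bp spacing
#'   seen at Jk and up to ~980 bp at Ja).
#' @param gaga_tier Which tier counts towards the functional call
#'   (default `"pentamer"`).
#' @param ja_mode If `TRUE`, a 3'-only GAGA motif (recorded with negative
#'   distance) also satisfies the functional call, as at the two Ja segments
#'   that carry only downstream motifs.
#' @param rss Scanning parameters, [rss_params()].
#' @param gaga Scanning parameters, [gaga_params()].
#' @return A list of class `annotate_params`.
#' @export
annotate_params <- function(spacer_class = 23L, max_rss_distance = 150L,
                            gaga_window = 1000L, gaga_tier = "pentamer",
                            ja_mode = FALSE, rss = rss_params(),
                            gaga = gaga_params()) {
  stopifnot(max_rss_distance >= 0L, gaga_window > 0L,
            gaga_tier %in% c("pentamer", "run", "gag"))
  structure(list(spacer_class = as.integer(spacer_class),
                 max_rss_distance = as.integer(max_rss_distance),
                 gaga_window = as.integer(gaga_window),
                 gaga_tier = gaga_tier, ja_mode = isTRUE(ja_mode),
                 rss = rss, gaga = gaga),
            class = "annotate_params")
}

# Annotate plus-strand gene bodies against precomputed hit tables.
.annotate_plus <- function(bodies, rss_hits, gaga_hits, params) {
  nl <- nchar(params$rss$nonamer)
  res <- vector("list", nrow(bodies))
  for (i in seq_len(nrow(bodies))) {
    bs <- bodies$start[i]
    row <- list(segment_name = bodies$name[i], body_start = bodies$start[i],
                body_end = bodies$end[i], strand = "+",
                rss_heptamer_start = NA_integer_, rss_nonamer_start = NA_integer_,
                rss_spacer_len = NA_integer_, gaga_start = NA_integer_,
                gaga_end = NA_integer_, gaga_tier = NA_character_,
                gaga_run_length = NA_integer_, distance_to_rss = NA_integer_,
                functional_call = FALSE)
    cand <- rss_hits[rss_hits$strand == "+", , drop = FALSE]
    if (nrow(cand) > 0L) {
      ne <- cand$nonamer_start + nl
      ok <- ne <= bs & (bs - ne) <= params$max_rss_distance &
        cand$heptamer_start < cand$nonamer_start
      cand <- cand[ok, , drop = FALSE]
    }
    has_rss <- nrow(cand) > 0L
    if (has_rss) {
      # nearest upstream RSS: largest nonamer end, then fewest mismatches
      o <- order(-(cand$nonamer_start),
                 cand$heptamer_mismatches + cand$nonamer_mismatches)
      best <- cand[o[1], ]
      row$rss_heptamer_start <- best$heptamer_start
      row$rss_nonamer_start <- best$nonamer_start
      row$rss_spacer_len <- best$spacer_len
    }
    anchor <- if (has_rss) row$rss_nonamer_start else bs
    g <- gaga_hits[gaga_hits$tier == params$gaga_tier, , drop = FALSE]
    gaga5 <- gaga3 <- NULL
    if (nrow(g) > 0L) {
      d <- anchor - g$end            # >0: motif 3' end upstream of nonamer
      up <- d > 0L & d <= params$gaga_window
      dn <- d <= 0L & g$start >= anchor & (g$start - anchor) < params$gaga_window
      if (any(up)) {
        gu <- g[up, , drop = FALSE]; du <- d[up]
        o <- order(du, -gu$run_length, gu$start)
        gaga5 <- cbind(gu[o[1], ], distance = du[o[1]])
      }
      if (any(dn)) {
        gd <- g[dn, , drop = FALSE]; dd <- d[dn]
        o <- order(abs(dd), -gd$run_length, gd$start)
        gaga3 <- cbind(gd[o[1], ], distance = dd[o[1]])
      }
    }
    pick <- if (!is.null(gaga5)) gaga5 else gaga3
    if (!is.null(pick)) {
      row$gaga_start <- pick$start; row$gaga_end <- pick$end
      row$gaga_tier <- pick$tier; row$gaga_run_length <- pick$run_length
      row$distance_to_rss <- pick$distance
    }
    gaga_ok <- !is.null(gaga5) || (params$ja_mode && !is.null(gaga3))
    row$functional_call <- has_rss && gaga_ok
    res[[i]] <- as.data.frame(row)
  }
  do.call(rbind, res)
}

#' Annotate gene segments with their RSS and 5' GAGA motif
#'
#' For each gene body, finds the nearest upstream RSS (within
#' `max_rss_distance` of the body start) and the nearest qualifying GAGA
#' motif within the 5' search window of the RSS nonamer. The functional
#' call requires both an RSS and a 5' GAGA motif: a segment with an RSS but
#' no GAGA motif in the window is called non-functional, matching the
#' observation that an RSS alone does not restore recombination. A 3'-only
#' GAGA motif is recorded with a negative distance and counts towards the
#' functional call only in `ja_mode`.
#'
#' Distances follow the convention: 3' end of the GAGA hit to the 5' start
#' of the nonamer, in the segment's coding orientation (positive = motif
#' upstream). Minus-strand gene bodies are handled by reflection: the scan
#' runs on the reverse complement and coordinates are mapped back, so
#' distances remain coding-orientation values.
#'
#' @param seq Locus sequence (uppercase `ACGTN`).
#' @param gene_bodies Data frame with columns `name`, `start`, `end` and
#'   optionally `strand` (default `"+"`); 0-based half-open, non-overlapping.
#' @param params An [annotate_params()] object.
#' @return A data frame of class `segment_annotations`, one row per gene
#'   body, with RSS and GAGA coordinates, `distance_to_rss` and
#'   `functional_call`.
#' @export
annotate_segments <- function(seq, gene_bodies, params = annotate_params()) {
  .check_dna(seq)
  stopifnot(all(c("name", "start", "end") %in% names(gene_bodies)),
            nrow(gene_bodies) >= 1L)
  if (is.null(gene_bodies$strand)) gene_bodies$strand <- "+"
  gb <- gene_bodies[order(gene_bodies$start), , drop = FALSE]
  if (nrow(gb) > 1L && any(gb$start[-1] < gb$end[-nrow(gb)]))
    stop("gene bodies overlap", call. = FALSE)
  n <- nchar(seq)
  stopifnot(all(gb$start >= 0L), all(gb$end <= n), all(gb$end > gb$start))

  rss_hits <- scan_rss(seq, params$spacer_class, params$rss)
  gaga_hits <- scan_gaga(seq, params = params$gaga)

  out <- list()
  plus <- gb[gb$strand == "+", , drop = FALSE]
  if (nrow(plus) > 0L)
    out <- c(out, list(.annotate_plus(plus, rss_hits, gaga_hits, params)))
  minus <- gb[gb$strand == "-", , drop = FALSE]
  if (nrow(minus) > 0L) {
    rcseq <- .revcomp(seq)
    rbodies <- data.frame(name = minus$name, start = n - minus$end,
                          end = n - minus$start)
    rr <- scan_rss(rcseq, params$spacer_class, params$rss)
    rg <- scan_gaga(rcseq, params = params$gaga)
    ann <- .annotate_plus(rbodies, rr, rg, params)
    nl <- nchar(params$rss$nonamer)
    hl <- nchar(params$rss$heptamer)
    remap <- ann
    remap$strand <- "-"
    remap$body_start <- n - ann$body_end
    remap$body_end <- n - ann$body_start
    remap$rss_heptamer_start <- n - ann$rss_heptamer_start - hl
    remap$rss_nonamer_start <- n - ann$rss_nonamer_start - nl
    ge <- n - ann$gaga_start
    gs <- n - ann$gaga_end
    remap$gaga_start <- gs
    remap$gaga_end <- ge
    out <- c(out, list(remap))
  }
  ann <- do.call(rbind, out)
  ann <- ann[order(ann$body_start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("segment_annotations", "data.frame")
  ann
}

#' Summarise GAGA-to-RSS spacing across annotated segments
#'
#' Aggregates per-segment GAGA-to-nonamer distances across one or more
#' annotated loci (e.g. Jk, JH, Ja of several species) into a tidy row table
#' and a summary: mean/min/max of the 5' distances, and counts of segments
#' with a 5' hit, a 3'-only hit, or no hit.
#'
#' @param annotations A `segment_annotations` data frame, or a named list of
#'   them (names become the `locus` column).
#' @return A list of class `spacing_report` with elements `rows` (locus,
#'   segment, distance_to_rss, tier) and `summary`.
#' @export
spacing_report <- function(annotations) {
  if (is.data.frame(annotations)) annotations <- list(locus = annotations)
  if (length(annotations) == 0L) stop("need at least one annotation set",
                                      call. = FALSE)
  if (is.null(names(annotations)))
    names(annotations) <- paste0("locus", seq_along(annotations))
  rows <- do.call(rbind, lapply(names(annotations), function(nm) {
    a <- annotations[[nm]]
    data.frame(locus = nm, segment = a$segment_name,
               distance_to_rss = a$distance_to_rss, tier = a$gaga_tier)
  }))
  d <- rows$distance_to_rss
  d5 <- d[!is.na(d) & d > 0]
  summary <- list(
    mean_distance = if (length(d5)) mean(d5) else NA_real_,
    min_distance = if (length(d5)) min(d5) else NA_real_,
    max_distance = if (length(d5)) max(d5) else NA_real_,
    n_5prime = length(d5),
    n_3prime_only = sum(!is.na(d) & d <= 0),
    n_no_hit = sum(is.na(d)))
  structure(list(rows = rows, summary = summary), class = "spacing_report")
}

#' @export
print.spacing_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "GAGA-to-nonamer spacing over %d segments: mean %.1f bp (range %s-%s bp)\n",
    nrow(x$rows), s$mean_distance,
    format(s$min_distance), format(s$max_distance)))
  cat(sprintf("  5' hits: %d | 3'-only: %d | none: %d\n",
              s$n_5prime, s$n_3prime_only, s$n_no_hit))
  invisible(x)
}

#' Find restriction sites introduced for genotyping
#'
#' Locates XhoI (`CTCGAG`) or HinfI (`GANTC`, N degenerate) recognition
#' sites, used to screen CRISPR-edited alleles (e.g. the `GAGAG` to `CTCGA`
#' edit that creates an XhoI site). Both recognition sequences are
#' palindromic up to the degenerate base, so a plus-strand scan with IUPAC
#' `N` matching finds every site.
#'
#' @param seq Uppercase nucleotide string.
#' @param enzyme `"XhoI"` or `"HinfI"` (case-insensitive).
#' @return Integer vector of 0-based match start positions on the plus strand.
#' @examples
#' find_restriction_sites("AACTCGAGTT", "XhoI")
#' @export
find_restriction_sites <- function(seq, enzyme = c("XhoI", "HinfI")) {
  .check_dna(seq)
  pats <- c(xhoi = "CTCGAG", hinfi = "GANTC")
  key <- tolower(enzyme[1])
  if (!key %in% names(pats))
    stop("unknown enzyme '", enzyme[1], "'; supported: XhoI, HinfI",
         call. = FALSE)
  pat <- pats[[key]]
  if (nchar(seq) < nchar(pat)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                fixed = FALSE)
  sort(BiocGenerics::start(m) - 1L)
}
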