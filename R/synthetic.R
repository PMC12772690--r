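# Synthetic data generators: toy J loci with planted RSS/GAGA units, ATAC
# fragment sets drawn from dyad/accessible-window mixtures, and Vk-Jk clone
# repertoires with uniform junction trimming. All generators are
# deterministic given their seed and return the planted ground truth.

#' Specify a synthetic J-like locus
#'
#' @param name Locus name.
#' @param length Sequence length in bp.
#' @param segments Data frame with one row per gene segment: `name`,
#'   `start`, `end` (gene body, 0-based half-open), `has_rss` (logical),
#'   `rss_spacer` (bp, typically 23), `gaga_distance` (bp from the GAGA
#'   motif 3' end to the nonamer 5' start; `NA` for no motif) and
#'   `gaga_pattern` (motif text, typically `"GAGAG"`).
#' @param background_gc Background GC fraction in `[0, 1]` (default 0.42,
#'   mouse genome-wide).
#' @param seed Integer seed; the whole construction is deterministic given it.
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(name, length, segments, background_gc = 0.42,
                       seed = 1L) {
  stopifnot(is.character(name), length > 0L,
            background_gc >= 0, background_gc <= 1,
            all(c("name", "start", "end", "has_rss", "rss_spacer",
                  "gaga_distance", "gaga_pattern") %in% names(segments)))
  seg <- segments[order(segments$start), , drop = FALSE]
  if (any(seg$start < 0L) || any(seg$end > length) || any(seg$end <= seg$start))
    stop("segment intervals must be within [0, length) and non-empty",
         call. = FALSE)
  if (nrow(seg) > 1L && any(seg$start[-1] < seg$end[-nrow(seg)]))
    stop("segment intervals overlap", call. = FALSE)
  bad <- !is.na(seg$gaga_distance) & seg$gaga_distance <= 0
  if (any(bad)) stop("gaga_distance must be > 0 when present", call. = FALSE)
  structure(list(name = name, length = as.integer(length), segments = seg,
                 background_gc = background_gc, seed = as.integer(seed)),
            class = "locus_spec")
}

#' A ready-made Jk-like locus specification
#'
#' Five gene segments emulating the murine Jk cluster: four functional
#' segments each carrying a 23-bp-spacer RSS and a `GAGAG` motif 80 bp
#' 5' of the nonamer, and one central pseudogene (the Jk3 analogue) with
#' neither element.
#'
#' @param seed Integer seed.
#' @param gaga_distance Spacing planted at functional segments (default 80 bp).
#' @return A `locus_spec`.
#' @export
jk_demo_spec <- function(seed = 1L, gaga_distance = 80L) {
  segments <- data.frame(
    name = c("Jk1", "Jk2", "Jk3", "Jk4", "Jk5"),
    start = c(800L, 1800L, 2800L, 3800L, 4800L),
    end = c(840L, 1840L, 2840L, 3840L, 4840L),
    has_rss = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    rss_spacer = 23L,
    gaga_distance = c(gaga_distance, gaga_distance, NA, gaga_distance,
                      gaga_distance),
    gaga_pattern = c("GAGAG", "GAGAG", NA, "GAGAG", "GAGAG"))
  locus_spec("Jk_demo", 6000L, segments, background_gc = 0.42, seed = seed)
}

# 0-based half-open planted-motif coordinates for one segment row.
.plant_coords <- function(seg, rss_gap, hl = 7L, nl = 9L) {
  out <- list(heptamer = NULL, nonamer = NULL, gaga = NULL)
  if (seg$has_rss) {
    ns <- seg$start - rss_gap - nl
    hs <- ns - seg$rss_spacer - hl
    out$nonamer <- c(ns, ns + nl)
    out$heptamer <- c(hs, hs + hl)
    if (!is.na(seg$gaga_distance)) {
      ge <- ns - seg$gaga_distance
      gs <- ge - nchar(seg$gaga_pattern)
      out$gaga <- c(gs, ge)
    }
  }
  out
}

# Positions (0-based) covered by accidental exact pentamers (GAGAG/CTCTC on
# the plus strand) or by non-planted RSS hits, restricted to resampleable
# (non-protected) positions.
.bad_positions <- function(seq, protected, planted_rss, spacer_classes,
                           rssp) {
  n <- nchar(seq)
  bad <- logical(n)
  for (pat in c("GAGAG", "CTCTC")) {
    st <- .fixed_starts(seq, pat)
    for (s in st) {
      iv <- s:(s + nchar(pat) - 1L)
      # a pentamer exactly coinciding with a protected (planted) footprint
      # is the planted motif itself; anything else is accidental
      if (!all(protected[iv + 1L])) bad[iv + 1L] <- TRUE
    }
  }
  for (cls in spacer_classes) {
    hits <- scan_rss(seq, cls, rssp)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      key <- paste(h$strand, h$heptamer_start, h$nonamer_start)
      if (key %in% planted_rss) next
      lo <- min(h$heptamer_start, h$nonamer_start)
      hi <- max(h$heptamer_start + 7L, h$nonamer_start + 9L) - 1L
      bad[(lo:hi) + 1L] <- TRUE
    }
  }
  which(bad & !protected)
}

#' Build a synthetic locus with planted RSS and GAGA motifs
#'
#' Draws an i.i.d. background at the configured GC content, plants for each
#' RSS-bearing segment an exact-consensus heptamer, a random spacer of the
#' configured length, and an exact nonamer ending `rss_gap` bp before the
#' gene body, plus (when configured) the GAGA pattern with its 3' end
#' `gaga_distance` bp 5' of the nonamer start. Accidental exact `GAGAG`
#' pentamers (either strand) and accidental near-consensus RSS hits in the
#' background are removed by rejection-resampling, so the planted motifs are
#' the only ones present and downstream scanners can be tested against an
#' exact oracle-by-construction.
#'
#' @param spec A [locus_spec()].
#' @param rss_gap Gap in bp between the nonamer 3' end and the gene-body
#'   start (default 2).
#' @param max_iter Maximum resampling sweeps before giving up (default 60).
#' @return A list of class `locus`: `name`, `sequence` (character),
#'   `annotations` (planted truth: per-segment gene body, RSS and GAGA
#'   coordinates, `gaga_distance`, `functional`), and `seed`.
#' @export
build_locus <- function(spec, rss_gap = 2L, max_iter = 60L) {
  stopifnot(inherits(spec, "locus_spec"))
  seg <- spec$segments
  n <- spec$length
  coords <- lapply(seq_len(nrow(seg)), function(i)
    .plant_coords(seg[i, ], rss_gap))

  # collision checks: planted footprints within bounds, not overlapping any
  # gene body or any other planted footprint
  occupied <- .merge_intervals(seg$start, seg$end)
  iv_all <- list()
  for (i in seq_along(coords)) {
    for (iv in coords[[i]]) {
      if (is.null(iv)) next
      if (iv[1] < 0L || iv[2] > n)
        stop("motif placement collision: planted motif for segment '",
             seg$name[i], "' falls outside the locus", call. = FALSE)
      for (j in seq_len(nrow(occupied)))
        if (iv[1] < occupied[j, 2] && occupied[j, 1] < iv[2])
          stop("motif placement collision: planted motif for segment '",
               seg$name[i], "' overlaps a gene body", call. = FALSE)
      for (known in iv_all)
        if (iv[1] < known[2] && known[1] < iv[2])
          stop("motif placement collision between planted motifs",
               call. = FALSE)
      iv_all <- c(iv_all, list(iv))
    }
  }

  rssp <- rss_params()
  spacer_classes <- sort(unique(c(12L, 23L, seg$rss_spacer[seg$has_rss])))

  seq_str <- .with_seed(spec$seed, {
    chars <- .random_bases(n, spec$background_gc)
    protected <- logical(n)
    planted_rss <- character(0)
    for (i in seq_len(nrow(seg))) {
      cc <- coords[[i]]
      if (!is.null(cc$heptamer)) {
        chars[(cc$heptamer[1] + 1L):cc$heptamer[2]] <-
          strsplit(rssp$heptamer, "")[[1]]
        chars[(cc$nonamer[1] + 1L):cc$nonamer[2]] <-
          strsplit(rssp$nonamer, "")[[1]]
        protected[(cc$heptamer[1] + 1L):cc$heptamer[2]] <- TRUE
        protected[(cc$nonamer[1] + 1L):cc$nonamer[2]] <- TRUE
        planted_rss <- c(planted_rss,
                         paste("+", cc$heptamer[1], cc$nonamer[1]))
      }
      if (!is.null(cc$gaga)) {
        chars[(cc$gaga[1] + 1L):cc$gaga[2]] <-
          strsplit(seg$gaga_pattern[i], "")[[1]]
        protected[(cc$gaga[1] + 1L):cc$gaga[2]] <- TRUE
      }
    }
    s <- paste(chars, collapse = "")
    for (iter in seq_len(max_iter)) {
      bad <- .bad_positions(s, protected, planted_rss, spacer_classes, rssp)
      if (length(bad) == 0L) break
      if (iter == max_iter)
        stop("could not clean accidental motifs after ", max_iter,
             " resampling sweeps", call. = FALSE)
      chars[bad] <- .random_bases(length(bad), spec$background_gc)
      s <- paste(chars, collapse = "")
    }
    s
  })

  ann <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    cc <- coords[[i]]
    data.frame(
      segment_name = seg$name[i], body_start = seg$start[i],
      body_end = seg$end[i],
      heptamer_start = if (is.null(cc$heptamer)) NA_integer_ else cc$heptamer[1],
      nonamer_start = if (is.null(cc$nonamer)) NA_integer_ else cc$nonamer[1],
      spacer_len = if (seg$has_rss[i]) seg$rss_spacer[i] else NA_integer_,
      gaga_start = if (is.null(cc$gaga)) NA_integer_ else cc$gaga[1],
      gaga_end = if (is.null(cc$gaga)) NA_integer_ else cc$gaga[2],
      gaga_distance = seg$gaga_distance[i],
      functional = seg$has_rss[i] && !is.na(seg$gaga_distance[i]))
  }))
  structure(list(name = spec$name, sequence = seq_str, annotations = ann,
                 seed = spec$seed),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("Synthetic locus '%s': %d bp, %d segments (%d functional), seed %d\n",
              x$name, nchar(x$sequence), nrow(x$annotations),
              sum(x$annotations$functional), x$seed))
  invisible(x)
}

#' Configure an ATAC fragment simulation
#'
#' Fragments come from a mixture of nucleosome-sized inserts whose midpoints
#' are Gaussian around planted dyads, and sub-nucleosomal inserts with
#' midpoints uniform over accessible windows — emulating the large- vs
#' short-insert read-pair classes of ATAC-seq libraries.
#'
#' @param dyads Data frame `position`, `fuzziness_sd`, `fragment_count`
#'   (may have zero rows).
#' @param accessible_windows Data frame `start`, `end`, `fragment_count`.
#' @param nuc_insert_mean,nuc_insert_sd Nucleosomal insert size (bp),
#'   defaults 200 and 15.
#' @param subnuc_insert_mean,subnuc_insert_sd Sub-nucleosomal insert size
#'   (bp), defaults 60 and 5.
#' @param seed Integer seed.
#' @return A list of class `atac_sim_config`.
#' @export
atac_sim_config <- function(dyads = NULL, accessible_windows = NULL,
                            nuc_insert_mean = 200, nuc_insert_sd = 15,
                            subnuc_insert_mean = 60, subnuc_insert_sd = 5,
                            seed = 1L) {
  if (is.null(dyads))
    dyads <- data.frame(position = numeric(0), fuzziness_sd = numeric(0),
                        fragment_count = integer(0))
  if (is.null(accessible_windows))
    accessible_windows <- data.frame(start = numeric(0), end = numeric(0),
                                     fragment_count = integer(0))
  stopifnot(all(c("position", "fuzziness_sd", "fragment_count") %in%
                  names(dyads)),
            all(c("start", "end", "fragment_count") %in%
                  names(accessible_windows)),
            all(dyads$fragment_count >= 0),
            all(accessible_windows$fragment_count >= 0),
            nuc_insert_mean > 0, subnuc_insert_mean > 0,
            subnuc_insert_mean < nuc_insert_mean)
  structure(list(dyads = dyads, accessible_windows = accessible_windows,
                 nuc_insert_mean = nuc_insert_mean,
                 nuc_insert_sd = nuc_insert_sd,
                 subnuc_insert_mean = subnuc_insert_mean,
                 subnuc_insert_sd = subnuc_insert_sd,
                 seed = as.integer(seed)),
            class = "atac_sim_config")
}

# Normal truncated to >= lower by resampling.
.rtrunc_norm <- function(n, mean, sd, lower = 1) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    idx <- which(x < lower)
    if (length(idx) == 0L) return(x)
    x[idx] <- stats::rnorm(length(idx), mean, sd)
  }
  pmax(x, lower)
}

#' Simulate paired-end ATAC fragments
#'
#' For each dyad, draws `fragment_count` fragments with midpoints
#' `Normal(position, fuzziness_sd)` and nucleosomal insert sizes; for each
#' accessible window, fragments with uniform midpoints and sub-nucleosomal
#' insert sizes. Inserts are truncated to >= 1 bp by resampling; fragments
#' are clipped to `[0, region_length)` and dropped (counted) if nothing
#' remains.
#'
#' @param cfg An [atac_sim_config()].
#' @param region_length Region length in bp (> 0).
#' @param chrom Chromosome label for the output (default `"sim"`).
#' @return A [fragment_set()]; attribute `n_rejected` counts fragments lost
#'   to clipping, attribute `seed` records the seed.
#' @export
simulate_fragments <- function(cfg, region_length, chrom = "sim") {
  stopifnot(inherits(cfg, "atac_sim_config"))
  if (region_length <= 0) stop("region_length must be > 0", call. = FALSE)
  .with_seed(cfg$seed, {
    mids <- numeric(0); ins <- numeric(0)
    d <- cfg$dyads
    for (i in seq_len(nrow(d))) {
      k <- d$fragment_count[i]
      if (k == 0) next
      mids <- c(mids, stats::rnorm(k, d$position[i], d$fuzziness_sd[i]))
      ins <- c(ins, .rtrunc_norm(k, cfg$nuc_insert_mean, cfg$nuc_insert_sd))
    }
    w <- cfg$accessible_windows
    for (i in seq_len(nrow(w))) {
      k <- w$fragment_count[i]
      if (k == 0) next
      mids <- c(mids, stats::runif(k, w$start[i], w$end[i]))
      ins <- c(ins, .rtrunc_norm(k, cfg$subnuc_insert_mean,
                                 cfg$subnuc_insert_sd))
    }
    ins <- round(ins)
    start <- round(mids - ins / 2)
    end <- start + ins
    start <- pmax(start, 0)
    end <- pmin(end, region_length)
    keep <- end - start >= 1
    fs <- fragment_set(chrom = chrom, start = start[keep], end = end[keep])
    attr(fs, "n_rejected") <- sum(!keep)
    attr(fs, "seed") <- cfg$seed
    fs
  })
}

#' Configure a Vk-Jk clone simulation
#'
#' @param usage_probs Named numeric vector of per-Jk usage probabilities
#'   (must sum to 1).
#' @param n_clones Number of clones (> 0).
#' @param junction_offset_max Maximum junction trimming in nt; each clone's
#'   Jk is trimmed by an offset uniform on `0..junction_offset_max`
#'   (default 14, so offsets are equidistributed mod 3).
#' @param seed Integer seed.
#' @return A list of class `clone_sim_config`.
#' @export
clone_sim_config <- function(usage_probs, n_clones,
                             junction_offset_max = 14L, seed = 1L) {
  stopifnot(is.numeric(usage_probs), !is.null(names(usage_probs)),
            all(usage_probs >= 0), n_clones > 0, junction_offset_max >= 0)
  if (abs(sum(usage_probs) - 1) > 1e-9)
    stop("usage_probs must sum to 1", call. = FALSE)
  structure(list(usage_probs = usage_probs, n_clones = as.integer(n_clones),
                 junction_offset_max = as.integer(junction_offset_max),
                 seed = as.integer(seed)),
            class = "clone_sim_config")
}

#' Simulate Vk-Jk cDNA clones with uniform junction trimming
#'
#' Each clone is the Vk prefix followed by the chosen Jk reference with a
#' uniformly drawn number of 5' nucleotides trimmed — a stochastic
#' recombination model with no selection, under which one third of clones
#' are expected in frame. Ground-truth labels record the Jk identity, the
#' trimming offset and the resulting frame (the clone reading frame starts
#' at position 0; the junction is in frame when the first retained Jk base
#' lands on its reference codon phase).
#'
#' @param cfg A [clone_sim_config()].
#' @param jk_refs List of [jk_reference()] objects covering all names in
#'   `usage_probs`.
#' @param vk_ref Vk prefix: a single nucleotide string (or a list with a
#'   `sequence` element).
#' @return A list of class `clone_set`: `sequences` (named character vector)
#'   and `truth` (data frame `clone_id`, `jk`, `offset`, `junction_pos`,
#'   `in_frame`).
#' @export
simulate_clones <- function(cfg, jk_refs, vk_ref) {
  stopifnot(inherits(cfg, "clone_sim_config"))
  if (length(jk_refs) == 0L) stop("empty Jk reference set", call. = FALSE)
  vk <- if (is.list(vk_ref)) vk_ref$sequence else vk_ref
  if (is.null(vk) || nchar(vk) == 0L) stop("empty Vk reference", call. = FALSE)
  ref_names <- vapply(jk_refs, function(r) r$name, character(1))
  if (!all(names(cfg$usage_probs) %in% ref_names))
    stop("usage_probs names missing from jk_refs", call. = FALSE)
  names(jk_refs) <- ref_names
  lv <- nchar(vk)
  .with_seed(cfg$seed, {
    jk_pick <- sample(names(cfg$usage_probs), cfg$n_clones, replace = TRUE,
                      prob = cfg$usage_probs)
    offsets <- sample.int(cfg$junction_offset_max + 1L, cfg$n_clones,
                          replace = TRUE) - 1L
    ids <- sprintf("clone_%04d", seq_len(cfg$n_clones))
    seqs <- character(cfg$n_clones)
    in_frame <- logical(cfg$n_clones)
    for (i in seq_len(cfg$n_clones)) {
      ref <- jk_refs[[jk_pick[i]]]
      seqs[i] <- paste0(vk, substring(ref$sequence, offsets[i] + 1L))
      in_frame[i] <- (lv %% 3L) == ((ref$frame_phase + offsets[i]) %% 3L)
    }
    names(seqs) <- ids
    structure(list(
      sequences = seqs,
      truth = data.frame(clone_id = ids, jk = jk_pick, offset = offsets,
                         junction_pos = lv, in_frame = in_frame),
      seed = cfg$seed), class = "clone_set")
  })
}

#' Built-in demonstration Vk/Jk references
#'
#' A synthetic Vk prefix and five synthetic Jk references (the third marked
#' non-functional, mirroring Jk3). Sequences are mutually divergent (local
#' identity well below the 0.8 assignment threshold between different Jk),
#' contain no stop codon in any reading frame (no `TA`/`TG` dinucleotides),
#' and the Vk length is a multiple of 3 with `frame_phase = 0` references,
#' so an untrimmed junction is in frame.
#'
#' @param jk_length Length of each Jk reference (default 39 nt).
#' @param vk_length Length of the Vk prefix (default 45 nt; multiple of 3).
#' @param seed Seed for the deterministic construction (default 42).
#' @return List with elements `vk` (character) and `jks` (list of
#'   [jk_reference()]).
#' @export
demo_references <- function(jk_length = 39L, vk_length = 45L, seed = 42L) {
  stopifnot(jk_length >= 15L, vk_length %% 3L == 0L, vk_length >= 21L)
  # After a T only pyrimidines may follow: rules out TAA/TAG/TGA everywhere,
  # in every frame and across junctions (the Vk also ends in CC).
  gen <- function(len) {
    prev <- "C"
    out <- character(len)
    for (i in seq_len(len)) {
      pool <- if (prev == "T") c("C", "T") else c("A", "C", "G", "T")
      out[i] <- sample(pool, 1L)
      prev <- out[i]
    }
    paste(out, collapse = "")
  }
  .with_seed(seed, {
    vk <- paste0(gen(vk_length - 2L), "CC")
    repeat {
      seqs <- vapply(1:5, function(i) gen(jk_length), character(1))
      div_ok <- TRUE
      for (i in 1:4) for (j in (i + 1):5) {
        a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
        if (mean(a == b) > 0.5) div_ok <- FALSE
      }
      if (div_ok) break
    }
    jks <- lapply(1:5, function(i)
      jk_reference(paste0("Jk", i), seqs[i], frame_phase = 0L,
                   functional = i != 3L))
    list(vk = vk, jks = jks)
  })
}
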