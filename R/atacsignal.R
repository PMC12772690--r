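# Fragment-size partitioning, nucleosome-occupancy and accessibility signal
# tracks, housekeeping-normalised region quantification and dyad calling.

#' Construct a fragment set
#'
#' @param chrom Chromosome labels (recycled).
#' @param start,end 0-based half-open fragment coordinates (`end > start`).
#' @return A data frame of class `fragment_set` with columns `chrom`,
#'   `start`, `end`, `insert` (= end - start).
#' @export
fragment_set <- function(chrom = "sim", start = integer(0),
                         end = integer(0)) {
  stopifnot(length(start) == length(end))
  if (any(end <= start)) stop("fragments must satisfy end > start",
                              call. = FALSE)
  fs <- data.frame(chrom = rep_len(as.character(chrom), length(start)),
                   start = as.numeric(start), end = as.numeric(end))
  fs$insert <- fs$end - fs$start
  class(fs) <- c("fragment_set", "data.frame")
  fs
}

#' Track construction parameters
#'
#' Insert-size cutoffs follow NucleoATAC-style conventions: sub-nucleosomal
#' fragments are shorter than `subnuc_max` (open chromatin), nucleosomal
#' fragments span `nuc_min`..`nuc_max` (nucleosome-protected). The Tn5
#' transposase duplicates 9 bp at each insertion; the conventional +4/-5
#' end shift centres cut sites on the insertion point.
#'
#' @param subnuc_max Sub-nucleosomal upper bound, exclusive (default 100 bp).
#' @param nuc_min,nuc_max Nucleosomal bounds, inclusive (defaults 180, 620).
#' @param kernel_sd Gaussian kernel bandwidth for occupancy smoothing
#'   (default 20 bp, roughly half a linker width).
#' @param tn5_shift Apply the +4/-5 Tn5 end correction (default `TRUE`).
#' @return A list of class `track_config`.
#' @export
track_config <- function(subnuc_max = 100L, nuc_min = 180L, nuc_max = 620L,
                         kernel_sd = 20, tn5_shift = TRUE) {
  if (!(subnuc_max < nuc_min))
    stop("subnuc_max must be < nuc_min", call. = FALSE)
  stopifnot(nuc_min <= nuc_max, kernel_sd > 0)
  structure(list(subnuc_max = subnuc_max, nuc_min = nuc_min,
                 nuc_max = nuc_max, kernel_sd = kernel_sd,
                 tn5_shift = isTRUE(tn5_shift)),
            class = "track_config")
}

#' Partition fragments by insert size
#'
#' @param fs A [fragment_set()].
#' @param cfg A [track_config()].
#' @return List with elements `subnuc` (insert < `subnuc_max`), `nuc`
#'   (`nuc_min` <= insert <= `nuc_max`) — both fragment sets — and
#'   `discarded`, the count of fragments in neither class.
#' @export
partition_fragments <- function(fs, cfg = track_config()) {
  stopifnot(inherits(fs, "fragment_set"), inherits(cfg, "track_config"))
  is_sub <- fs$insert < cfg$subnuc_max
  is_nuc <- fs$insert >= cfg$nuc_min & fs$insert <= cfg$nuc_max
  sub <- fs[is_sub, , drop = FALSE]
  nuc <- fs[is_nuc, , drop = FALSE]
  class(sub) <- class(nuc) <- c("fragment_set", "data.frame")
  list(subnuc = sub, nuc = nuc, discarded = sum(!is_sub & !is_nuc))
}

# Tn5-shifted fragment ends (0-based half-open); degenerate shifted
# fragments are clamped to 1 bp.
.shifted_ends <- function(fs, cfg) {
  if (cfg$tn5_shift) {
    s <- fs$start + 4; e <- fs$end - 5
  } else {
    s <- fs$start; e <- fs$end
  }
  e <- pmax(e, s + 1)
  list(start = s, end = e)
}

# Gaussian kernel density of integer positions over [start, end), evaluated
# per base. Positions within 4 sd outside the region still contribute.
.kernel_density <- function(pos, start, end, sd) {
  len <- end - start
  vals <- numeric(len)
  if (length(pos) == 0L) return(vals)
  r <- as.integer(ceiling(4 * sd))
  padded <- len + 2L * r
  off <- floor(pos) - (start - r)           # 0-based index into padded grid
  keep <- off >= 0 & off < padded
  if (!any(keep)) return(vals)
  counts <- tabulate(off[keep] + 1L, nbins = padded)
  kern <- stats::dnorm(seq(-r, r), 0, sd)
  full <- stats::convolve(counts, rev(kern), type = "open")
  # full[k] = sum_i counts[i] * kern[k - i + 1]; density at padded index p
  # is full[p + r], so unpadded bases (p = r+1 .. r+len) sit at 2r + 1..len.
  full[2L * r + seq_len(len)]
}

.new_track <- function(chrom, start, end, values, kind, cfg, library_size,
                       n_signal = NA_integer_, n_background = NA_integer_) {
  structure(list(chrom = chrom, start = start, end = end, values = values,
                 kind = kind, config = cfg, library_size = library_size,
                 n_signal = n_signal, n_background = n_background),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("%s track %s:%d-%d (%d bp), library %d fragments\n",
              x$kind, x$chrom, x$start, x$end, x$end - x$start,
              x$library_size))
  invisible(x)
}

#' Nucleosome-occupancy track from fragment-size classes
#'
#' The occupancy signal is the difference between two per-million-normalised
#' kernel densities: the smoothed density of Tn5-shifted midpoints of
#' nucleosome-sized fragments (signal) minus the same construction over
#' sub-nucleosomal fragments (background). Each density is scaled per
#' million fragments of its own class, so the difference is scale-balanced
#' and invariant to library depth; values may be negative where short-insert
#' background exceeds nucleosomal signal.
#'
#' @param fs A [fragment_set()] (the full library; partitioning happens
#'   internally).
#' @param region `c(start, end)`, 0-based half-open.
#' @param cfg A [track_config()].
#' @return A `signal_track` of kind `"occupancy"`.
#' @export
occupancy_track <- function(fs, region, cfg = track_config()) {
  stopifnot(inherits(fs, "fragment_set"), length(region) == 2L,
            region[2] > region[1])
  parts <- partition_fragments(fs, cfg)
  n_nuc <- nrow(parts$nuc); n_sub <- nrow(parts$subnuc)
  if (n_nuc == 0L && n_sub == 0L)
    stop("no fragments in either insert-size class; occupancy undefined",
         call. = FALSE)
  start <- region[1]; end <- region[2]
  dens <- function(part, n) {
    if (n == 0L) return(numeric(end - start))
    se <- .shifted_ends(part, cfg)
    mids <- floor((se$start + se$end) / 2)
    .kernel_density(mids, start, end, cfg$kernel_sd) * 1e6 / n
  }
  if (n_nuc == 0L) warning("no nucleosomal fragments; signal density is 0")
  if (n_sub == 0L) warning("no sub-nucleosomal fragments; background density is 0")
  vals <- dens(parts$nuc, n_nuc) - dens(parts$subnuc, n_sub)
  .new_track(fs$chrom[1] %||% "sim", start, end, vals, "occupancy", cfg,
             nrow(fs), n_signal = n_nuc, n_background = n_sub)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Chromatin-accessibility track from sub-nucleosomal cut sites
#'
#' Counts Tn5 cut sites — both shifted fragment ends (`start + 4` and
#' `end - 5` with the shift; `start` and `end - 1` without) — of
#' sub-nucleosomal fragments per base, scaled to tags per million total
#' library fragments. A full-fragment coverage mode is available for
#' comparison.
#'
#' @param fs A [fragment_set()] (full library).
#' @param region `c(start, end)`, 0-based half-open.
#' @param cfg A [track_config()].
#' @param library_size Scaling denominator; defaults to the number of
#'   fragments in `fs`.
#' @param mode `"cutsites"` (default) or `"coverage"`.
#' @return A `signal_track` of kind `"accessibility"` (values >= 0).
#' @export
accessibility_track <- function(fs, region, cfg = track_config(),
                                library_size = NULL,
                                mode = c("cutsites", "coverage")) {
  stopifnot(inherits(fs, "fragment_set"), length(region) == 2L,
            region[2] > region[1])
  mode <- match.arg(mode)
  if (is.null(library_size)) library_size <- nrow(fs)
  if (library_size <= 0) stop("library_size must be positive", call. = FALSE)
  start <- region[1]; end <- region[2]
  len <- end - start
  parts <- partition_fragments(fs, cfg)
  sub <- parts$subnuc
  counts <- numeric(len)
  if (nrow(sub) > 0L) {
    if (mode == "cutsites") {
      cuts <- if (cfg$tn5_shift) c(sub$start + 4, sub$end - 5)
              else c(sub$start, sub$end - 1)
      idx <- cuts - start
      idx <- idx[idx >= 0 & idx < len]
      if (length(idx)) counts <- tabulate(idx + 1L, nbins = len)
    } else {
      se <- .shifted_ends(sub, cfg)
      for (i in seq_len(nrow(sub))) {
        lo <- max(se$start[i], start); hi <- min(se$end[i], end)
        if (hi > lo) {
          ii <- (lo - start + 1L):(hi - start)
          counts[ii] <- counts[ii] + 1
        }
      }
    }
  }
  .new_track(fs$chrom[1] %||% "sim", start, end, counts * 1e6 / library_size,
             "accessibility", cfg, library_size,
             n_signal = nrow(sub))
}

#' Average a signal track over regions, normalised to a housekeeping region
#'
#' Computes the arithmetic per-base mean of the track over each region and
#' divides it by the mean over a housekeeping region (e.g. Gapdh), the
#' standard between-sample normalisation for region-level accessibility or
#' occupancy comparisons.
#'
#' @param track A `signal_track`.
#' @param regions Data frame with `name`, `start`, `end` (0-based half-open,
#'   within the track extent, non-empty).
#' @param housekeeping One-row data frame (or `c(start, end)`) giving the
#'   housekeeping region.
#' @return Data frame of class `region_quant`: `region_name`, `start`,
#'   `end`, `mean_signal`, `normalized`. If the housekeeping mean is <= 0,
#'   `normalized` is `NA` with a warning and raw means are still returned.
#' @export
quantify_regions <- function(track, regions, housekeeping) {
  stopifnot(inherits(track, "signal_track"),
            all(c("name", "start", "end") %in% names(regions)))
  if (is.numeric(housekeeping))
    housekeeping <- data.frame(name = "housekeeping",
                               start = housekeeping[1], end = housekeeping[2])
  region_mean <- function(s, e) {
    if (e <= s) stop("region of length 0", call. = FALSE)
    if (s < track$start || e > track$end)
      stop("region outside track extent", call. = FALSE)
    mean(track$values[(s - track$start + 1L):(e - track$start)])
  }
  hk_mean <- region_mean(housekeeping$start[1], housekeeping$end[1])
  means <- mapply(region_mean, regions$start, regions$end)
  if (hk_mean <= 0) {
    warning("housekeeping mean signal <= 0; normalized values are NA")
    norm <- rep(NA_real_, length(means))
  } else {
    norm <- means / hk_mean
  }
  out <- data.frame(region_name = regions$name, start = regions$start,
                    end = regions$end, mean_signal = means,
                    normalized = norm)
  class(out) <- c("region_quant", "data.frame")
  out
}

#' Call the 5' nucleosome dyad upstream of an anchor
#'
#' Scans the occupancy track over the `flank` bp immediately 5' of `anchor`
#' (e.g. the RSS nonamer start) for its maximum. A call is emitted only if
#' the peak exceeds `threshold` (default 0: nucleosomal signal must exceed
#' the short-insert background); ties go to the position nearest the anchor.
#'
#' @param track An occupancy `signal_track`.
#' @param anchor 0-based anchor position.
#' @param flank 5' window size in bp (default 250).
#' @param threshold Minimum peak occupancy (default 0).
#' @return A list of class `nucleosome_call` (`dyad`, `score`,
#'   `flank_window`), or `NULL` when no peak clears the threshold.
#' @export
call_nucleosomes <- function(track, anchor, flank = 250L, threshold = 0) {
  stopifnot(inherits(track, "signal_track"))
  lo <- anchor - flank; hi <- anchor
  if (lo < track$start || hi > track$end)
    stop("flank window outside track extent", call. = FALSE)
  if (hi <= lo) stop("empty flank window", call. = FALSE)
  idx <- (lo - track$start + 1L):(hi - track$start)
  v <- track$values[idx]
  m <- max(v)
  if (m <= threshold) return(NULL)
  pos <- lo + which(v == m) - 1L
  structure(list(dyad = max(pos), score = m, flank_window = c(lo, hi)),
            class = "nucleosome_call")
}

#' @export
print.nucleosome_call <- function(x, ...) {
  cat(sprintf("nucleosome dyad at %d (occupancy %.3f) in window [%d, %d)\n",
              x$dyad, x$score, x$flank_window[1], x$flank_window[2]))
  invisible(x)
}
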