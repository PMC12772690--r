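# Vk-Jk clone classification: Jk assignment by local alignment, reading
# frame and productivity calls, usage tables and group comparison.

#' Construct a Jk reference
#'
#' @param name Segment name.
#' @param sequence Reference nucleotide sequence (>= 15 nt).
#' @param frame_phase Codon phase (0, 1 or 2) of reference position 0,
#'   supplied rather than inferred so that frame calls are config-auditable.
#' @param functional Whether the segment is functional.
#' @return A list of class `jk_reference`.
#' @export
jk_reference <- function(name, sequence, frame_phase = 0L,
                         functional = TRUE) {
  .check_dna(sequence, "sequence")
  if (nchar(sequence) < 15L)
    stop("reference sequence must be >= 15 nt", call. = FALSE)
  if (!frame_phase %in% 0:2) stop("frame_phase must be 0, 1 or 2",
                                  call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 frame_phase = as.integer(frame_phase),
                 functional = isTRUE(functional)),
            class = "jk_reference")
}

#' Alignment and assignment parameters
#'
#' @param match,mismatch,gap_open,gap_extend Local-alignment scoring
#'   (defaults +1/-1/-2/-1, expressed as positive penalties for gaps).
#' @param min_identity Minimum alignment identity for an assignment
#'   (default 0.8).
#' @param min_aln_len Minimum aligned length in nt (default 15).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 2,
                         gap_extend = 1, min_identity = 0.8,
                         min_aln_len = 15L) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 min_aln_len = as.integer(min_aln_len)),
            class = "align_params")
}

#' Assign a clone to a Jk reference by local alignment
#'
#' Aligns every reference locally against the clone (Smith-Waterman via
#' `Biostrings::pairwiseAlignment`); the best-scoring reference wins if the
#' alignment identity is at least `min_identity` over at least `min_aln_len`
#' aligned nucleotides. A score tie between distinct references yields
#' `"ambiguous"`; failing the thresholds yields `"unassigned"`.
#'
#' @param clone Clone nucleotide sequence (>= 20 nt).
#' @param refs List of [jk_reference()] objects.
#' @param params An [align_params()] object.
#' @return List: `assigned_jk` (name, `"ambiguous"` or `"unassigned"`),
#'   `score`, `identity`, `junction_pos` (0-based clone coordinate aligned
#'   to the reference's 5'-most aligned base), `ref_aln_start` (0-based
#'   position of that base in the reference) and `jk_end_in_clone`
#'   (0-based exclusive end of the aligned Jk region in the clone).
#' @export
assign_jk <- function(clone, refs, params = align_params()) {
  if (length(refs) == 0L) stop("empty reference set", call. = FALSE)
  .check_dna(clone, "clone")
  if (nchar(clone) < 20L) stop("clone must be >= 20 nt", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  scores <- numeric(length(refs))
  alns <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(refs[[i]]$sequence),
      subject = Biostrings::DNAString(clone),
      type = "local", substitutionMatrix = submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    scores[i] <- Biostrings::score(aln)
    alns[[i]] <- aln
  }
  best <- which.max(scores)
  aln <- alns[[best]]
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  aln_len <- Biostrings::nchar(aln)
  res <- list(
    assigned_jk = refs[[best]]$name,
    score = scores[best], identity = identity,
    junction_pos = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
    ref_aln_start = BiocGenerics::start(Biostrings::pattern(aln)) - 1L,
    ref_aln_end = BiocGenerics::end(Biostrings::pattern(aln)),
    jk_end_in_clone = BiocGenerics::end(Biostrings::subject(aln)))
  tied <- sum(abs(scores - scores[best]) < 1e-9)
  if (identity < params$min_identity || aln_len < params$min_aln_len) {
    res$assigned_jk <- "unassigned"
  } else if (tied > 1L) {
    res$assigned_jk <- "ambiguous"
  }
  res
}

#' Call reading frame and productivity for an assigned clone
#'
#' The clone reading frame starts at position 0 (the Vk prefix is assumed in
#' frame). The junction is in frame when the aligned Jk bases sit on their
#' reference codon phase. The check is anchored at the 3' end of the aligned
#' Jk region — `jk_end_in_clone mod 3 == (frame_phase + ref_aln_end) mod 3` —
#' rather than at the junction itself: for a gapless alignment the two are
#' equivalent (`junction_pos mod 3 == (frame_phase + ref_aln_start) mod 3`),
#' but the 5' alignment edge is ambiguous when the V tail resembles the
#' trimmed J prefix, whereas the J phase running into the downstream constant
#' region — which is what productivity is about — is fixed by the 3' end.
#' A stop codon (TAA/TAG/TGA) anywhere in frame from the clone start through
#' the end of the aligned Jk region vetoes productivity:
#' productive = in frame and no stop.
#'
#' @param assignment Result of [assign_jk()] (must be assigned to a named
#'   reference).
#' @param ref The matching [jk_reference()].
#' @param clone_seq The clone sequence.
#' @return List: `in_frame`, `has_stop`, `productive`.
#' @export
call_frame <- function(assignment, ref, clone_seq) {
  if (assignment$assigned_jk %in% c("unassigned", "ambiguous"))
    stop("frame call undefined for ", assignment$assigned_jk, " clone",
         call. = FALSE)
  in_frame <- (assignment$jk_end_in_clone %% 3L) ==
    ((ref$frame_phase + assignment$ref_aln_end) %% 3L)
  stops <- c("TAA", "TAG", "TGA")
  has_stop <- FALSE
  starts <- seq.int(0L, assignment$jk_end_in_clone - 3L, by = 3L)
  if (length(starts) > 0L) {
    codons <- substring(clone_seq, starts + 1L, starts + 3L)
    has_stop <- any(codons %in% stops)
  }
  list(in_frame = in_frame, has_stop = has_stop,
       productive = in_frame && !has_stop)
}

#' Classify a set of clones
#'
#' Runs [assign_jk()] and, for assigned clones, [call_frame()] on every
#' clone.
#'
#' @param clones Named character vector of clone sequences (or a `clone_set`
#'   from [simulate_clones()]).
#' @param refs List of [jk_reference()] objects.
#' @param params An [align_params()] object.
#' @return Data frame of class `clone_records`: `clone_id`, `assigned_jk`,
#'   `score`, `identity`, `junction_pos`, `in_frame`, `has_stop`,
#'   `productive` (frame fields `NA` for ambiguous/unassigned clones).
#' @export
classify_clones <- function(clones, refs, params = align_params()) {
  if (inherits(clones, "clone_set")) clones <- clones$sequences
  stopifnot(length(clones) > 0L)
  if (is.null(names(clones)))
    names(clones) <- sprintf("clone_%04d", seq_along(clones))
  by_name <- stats::setNames(refs, vapply(refs, `[[`, character(1), "name"))
  rows <- lapply(names(clones), function(id) {
    a <- assign_jk(clones[[id]], refs, params)
    fr <- list(in_frame = NA, has_stop = NA, productive = NA)
    if (!a$assigned_jk %in% c("unassigned", "ambiguous"))
      fr <- call_frame(a, by_name[[a$assigned_jk]], clones[[id]])
    data.frame(clone_id = id, assigned_jk = a$assigned_jk, score = a$score,
               identity = a$identity, junction_pos = a$junction_pos,
               in_frame = fr$in_frame, has_stop = fr$has_stop,
               productive = fr$productive)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clone_records", "data.frame")
  out
}

#' Build a usage table from per-Jk counts
#'
#' @param counts Named numeric vector of per-Jk clone counts.
#' @param group_name Label for the sample/group.
#' @return A list of class `usage_table`: `group_name`, `counts`, `total`,
#'   `frequencies` (counts / total).
#' @examples
#' usage_table(c(Jk3 = 27, other = 331), "Jk3_GAGA_RSS_small_preB")
#' @export
usage_table <- function(counts, group_name = "group") {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("no counts", call. = FALSE)
  structure(list(group_name = group_name, counts = counts, total = total,
                 frequencies = counts / total),
            class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("Jk usage for '%s' (n = %d):\n", x$group_name, x$total))
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %5d  (%.2f%%)\n", nm, x$counts[[nm]],
                100 * x$frequencies[[nm]]))
  invisible(x)
}

#' Per-Jk usage frequencies from classified clones
#'
#' Counts assigned clones per Jk; ambiguous and unassigned clones are
#' tallied separately and excluded from the frequency denominator by
#' default (frequencies are over uniquely assigned sequences), matching the
#' convention of analysing unique assignable sequences.
#'
#' @param clone_table A `clone_records` data frame from [classify_clones()].
#' @param group_name Label for the group.
#' @param include_unassigned If `TRUE`, ambiguous/unassigned classes enter
#'   the denominator as their own categories.
#' @return A [usage_table()] with attributes `n_ambiguous`, `n_unassigned`.
#' @export
usage_frequencies <- function(clone_table, group_name = "group",
                              include_unassigned = FALSE) {
  stopifnot(is.data.frame(clone_table), "assigned_jk" %in% names(clone_table))
  special <- clone_table$assigned_jk %in% c("ambiguous", "unassigned")
  use <- if (include_unassigned) clone_table$assigned_jk
         else clone_table$assigned_jk[!special]
  if (length(use) == 0L) stop("no assigned clones", call. = FALSE)
  counts <- table(use)
  ut <- usage_table(stats::setNames(as.numeric(counts), names(counts)),
                    group_name)
  attr(ut, "n_ambiguous") <- sum(clone_table$assigned_jk == "ambiguous")
  attr(ut, "n_unassigned") <- sum(clone_table$assigned_jk == "unassigned")
  ut
}

#' Compare per-mouse Jk usage between two genotypes
#'
#' Two-sample unpaired t-test on per-mouse frequencies of one Jk segment
#' (equal-variance by default, Welch optional). Inputs may be lists of
#' [usage_table()] objects (one per mouse) plus the Jk name, or plain
#' numeric frequency vectors.
#'
#' When both groups have zero within-group variance: equal means return
#' `t = 0, p = 1`; unequal means make the equal-variance statistic
#' undefined, and the function stops with guidance to use `welch = TRUE`
#' with a small `var_floor`.
#'
#' @param group1,group2 Numeric vectors of per-mouse frequencies, or lists
#'   of `usage_table`s.
#' @param jk Jk name to extract when usage tables are supplied.
#' @param welch Use Welch's unequal-variance test.
#' @param var_floor Variance floor applied in Welch mode (default 0).
#' @return List: `mean_diff` (group1 - group2), `t`, `p`, `df`, `method`.
#' @export
compare_usage <- function(group1, group2, jk = NULL, welch = FALSE,
                          var_floor = 0) {
  get_freqs <- function(g) {
    if (is.numeric(g)) return(g)
    if (is.null(jk)) stop("jk name required with usage tables", call. = FALSE)
    vapply(g, function(u) {
      f <- u$frequencies[[jk]]
      if (is.null(f)) 0 else f
    }, numeric(1))
  }
  x <- get_freqs(group1); y <- get_freqs(group2)
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 mice per genotype", call. = FALSE)
  md <- mean(x) - mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (!welch && vx == 0 && vy == 0) {
    if (md == 0)
      return(list(mean_diff = 0, t = 0, p = 1,
                  df = length(x) + length(y) - 2, method = "equal-variance"))
    stop("zero within-group variance with unequal means: equal-variance t ",
         "is undefined; rerun with welch = TRUE and a small var_floor",
         call. = FALSE)
  }
  if (welch && var_floor > 0) {
    vx <- max(vx, var_floor); vy <- max(vy, var_floor)
    se <- sqrt(vx / length(x) + vy / length(y))
    tt <- md / se
    df <- (vx / length(x) + vy / length(y))^2 /
      ((vx / length(x))^2 / (length(x) - 1) +
         (vy / length(y))^2 / (length(y) - 1))
    return(list(mean_diff = md, t = tt,
                p = 2 * stats::pt(-abs(tt), df), df = df,
                method = "welch (variance floor)"))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(mean_diff = md, t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       method = if (welch) "welch" else "equal-variance")
}
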