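# Delta-delta-Ct qPCR quantification and small statistical helpers.

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of the test transcript in the experimental (KO/mutant) group
#' relative to the control (WT) group, each normalised to a housekeeping
#' gene (B2m in the original assay):
#' `2^-((ko_test - ko_housekeeping) - (wt_test - wt_housekeeping))`.
#' All arguments are Ct values in cycles and may be vectors (recycled).
#'
#' @param ko_test,ko_housekeeping Ct values in the experimental group.
#' @param wt_test,wt_housekeeping Ct values in the control group.
#' @return Positive fold change(s); 1 means no change, 0.5 means the KO
#'   delta-Ct is one cycle larger (half the expression).
#' @examples
#' ddct_fold_change(24, 20, 26, 22)    # equal deltas -> 1
#' ddct_fold_change(25, 20, 26, 22)    # one extra cycle -> 0.5
#' @export
ddct_fold_change <- function(ko_test, ko_housekeeping, wt_test,
                             wt_housekeeping) {
  vals <- c(ko_test, ko_housekeeping, wt_test, wt_housekeeping)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("Ct values must be finite positive cycle counts", call. = FALSE)
  2^-((ko_test - ko_housekeeping) - (wt_test - wt_housekeeping))
}

#' Delta-delta-Ct from a long-format Ct table
#'
#' Averages replicate Ct values (e.g. qPCR triplicates) per group and gene
#' before applying [ddct_fold_change()].
#'
#' @param ct Data frame with columns `group`, `gene`, `ct`.
#' @param test_gene Gene of interest.
#' @param housekeeping Housekeeping gene (default `"B2m"`).
#' @param wt_group,ko_group Group labels.
#' @return A single fold change.
#' @export
ddct_from_table <- function(ct, test_gene, housekeeping = "B2m",
                            wt_group = "WT", ko_group = "KO") {
  stopifnot(all(c("group", "gene", "ct") %in% names(ct)))
  pick <- function(grp, gene) {
    v <- ct$ct[ct$group == grp & ct$gene == gene]
    if (length(v) == 0L)
      stop("no Ct values for group '", grp, "', gene '", gene, "'",
           call. = FALSE)
    mean(v)
  }
  ddct_fold_change(pick(ko_group, test_gene), pick(ko_group, housekeeping),
                   pick(wt_group, test_gene), pick(wt_group, housekeeping))
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector with at least two values.
#' @return Named numeric vector `c(mean, sem)` with
#'   `sem = sd(values) / sqrt(n)` (sample sd, n - 1 denominator).
#' @examples
#' mean_sem(c(1, 2, 3))
#' @export
mean_sem <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values for a standard error", call. = FALSE)
  c(mean = mean(values),
    sem = stats::sd(values) / sqrt(length(values)))
}
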