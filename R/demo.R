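# End-to-end demonstration: two synthetic ATAC conditions reproducing the
# direction of the GAGA-dependent chromatin phenotype.

#' Simulate the GAGA-present vs GAGA-mutant chromatin contrast
#'
#' Builds two synthetic ATAC fragment libraries over a toy J segment and
#' quantifies the two signals the biology turns on:
#' * **GAGA-present ("WT")**: a positioned 5' nucleosome (planted dyad 100 bp
#'   upstream of the RSS nonamer) plus an accessible window over the RSS.
#' * **GAGA-mutant**: no positioned dyad (nucleosomal fragments scattered
#'   uniformly) and no RSS-proximal accessible window.
#'
#' Both conditions share a constitutively accessible housekeeping window
#' (the Gapdh analogue) used for normalisation, identical library
#' composition sizes, and a uniform sub-nucleosomal background. The
#' expectation is directional: mutant RSS accessibility below WT and mutant
#' 5'-nucleosome occupancy below WT.
#'
#' @param seed Integer seed.
#' @param n_dyad_fragments Nucleosomal fragments at the planted dyad
#'   (default 2000).
#' @param n_window_fragments Sub-nucleosomal fragments per accessible window
#'   (default 2000).
#' @return List with elements `wt` and `mutant` (each: `accessibility`
#'   [region_quant], `occupancy_5p` mean occupancy over the 5' flank,
#'   `nucleosome_call`), plus `region_layout`.
#' @export
demo_gaga_contrast <- function(seed = 1L, n_dyad_fragments = 2000L,
                               n_window_fragments = 2000L) {
  region_len <- 2000L
  nonamer_start <- 1000L          # RSS nonamer 5' start (anchor)
  rss <- c(961L, 1009L)           # heptamer..nonamer footprint
  body <- c(1011L, 1051L)
  dyad_true <- nonamer_start - 100L
  flank <- c(nonamer_start - 250L, nonamer_start)
  hk <- c(200L, 280L)             # housekeeping accessible window

  sim <- function(cond_seed, with_dyad, with_rss_window) {
    dy <- if (with_dyad)
      data.frame(position = dyad_true, fuzziness_sd = 10,
                 fragment_count = n_dyad_fragments)
    else
      data.frame(position = region_len / 2, fuzziness_sd = region_len / 4,
                 fragment_count = n_dyad_fragments)
    win <- data.frame(start = hk[1], end = hk[2],
                      fragment_count = n_window_fragments)
    if (with_rss_window)
      win <- rbind(win, data.frame(start = rss[1] - 20, end = body[2],
                                   fragment_count = n_window_fragments))
    # uniform sub-nucleosomal background in both conditions
    win <- rbind(win, data.frame(start = 0, end = region_len,
                                 fragment_count = n_window_fragments))
    cfg <- atac_sim_config(dyads = dy, accessible_windows = win,
                           seed = cond_seed)
    simulate_fragments(cfg, region_len)
  }

  quantify <- function(fs) {
    tcfg <- track_config()
    acc <- accessibility_track(fs, c(0L, region_len), tcfg)
    occ <- occupancy_track(fs, c(0L, region_len), tcfg)
    regions <- data.frame(name = c("RSS", "gene_body"),
                          start = c(rss[1], body[1]),
                          end = c(rss[2], body[2]))
    rq <- quantify_regions(acc, regions, c(hk[1], hk[2]))
    occ5 <- mean(occ$values[(flank[1] + 1L):flank[2]])
    list(accessibility = rq, occupancy_5p = occ5,
         nucleosome_call = call_nucleosomes(occ, nonamer_start, flank = 250L))
  }

  wt_fs <- sim(seed, with_dyad = TRUE, with_rss_window = TRUE)
  mu_fs <- sim(seed + 1L, with_dyad = FALSE, with_rss_window = FALSE)
  list(wt = quantify(wt_fs), mutant = quantify(mu_fs),
       region_layout = list(region_len = region_len, rss = rss, body = body,
                            dyad = dyad_true, flank = flank,
                            housekeeping = hk))
}
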