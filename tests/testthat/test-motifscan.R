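test_that("scan_rss finds a planted exact-consensus RSS and nothing in poly-A", {
  set.seed(11)
  spacer <- rand_dna(23)
  seq <- paste0(strrep("A", 100), "CACAGTG", spacer, "ACAAAAACC",
                strrep("C", 50))
  hits <- scan_rss(seq, 23)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$heptamer_start == 100 & plus$spacer_len == 23))
  best <- plus[plus$heptamer_start == 100 & plus$spacer_len == 23, ]
  expect_equal(best$nonamer_start, 130)
  expect_equal(best$heptamer_mismatches, 0)
  expect_equal(best$nonamer_mismatches, 0)

  expect_equal(nrow(scan_rss(strrep("A", 500), 23)), 0)
  expect_error(scan_rss("ACGTX"), "non-nucleotide")
})

test_that("scan_rss matches the exhaustive brute-force oracle on decoy-bearing sequences", {
  n_nonempty <- 0
  for (s in 1:12) {
    set.seed(s)
    for (cls in c(12L, 23L)) {
      seq <- seq_with_rss_decoys(3000, spacer_class = cls)
      got <- scan_rss(seq, cls)
      want <- bf_scan_rss(seq, cls)
      if (nrow(want) > 0) n_nonempty <- n_nonempty + 1
      expect_same_hits(got, want,
                       c("heptamer_start", "nonamer_start", "spacer_len",
                         "strand", "heptamer_mismatches",
                         "nonamer_mismatches"))
    }
  }
  expect_gt(n_nonempty, 10)  # the comparison is not vacuous
  # one long case
  set.seed(99)
  seq <- seq_with_rss_decoys(10000, n_implants = 15)
  expect_same_hits(scan_rss(seq, 23), bf_scan_rss(seq, 23),
                   c("heptamer_start", "nonamer_start", "spacer_len",
                     "strand"))
})

test_that("scan_rss obeys strand reflection", {
  set.seed(21)
  seq <- seq_with_rss_decoys(4000, n_implants = 8)
  n <- nchar(seq)
  fwd <- scan_rss(seq, 23)
  expect_gt(nrow(fwd), 0)
  rev <- scan_rss(bf_revcomp(seq), 23)
  # reflect the reverse-complement hit set back
  refl <- rev
  refl$heptamer_start <- n - rev$heptamer_start - 7
  refl$nonamer_start <- n - rev$nonamer_start - 9
  refl$strand <- ifelse(rev$strand == "+", "-", "+")
  o <- order(pmin(refl$heptamer_start, refl$nonamer_start), refl$strand)
  expect_same_hits(refl[o, ], fwd,
                   c("heptamer_start", "nonamer_start", "spacer_len",
                     "strand"))
})

test_that("scan_gaga finds pentamers, merges overlaps and matches the oracle", {
  hits <- scan_gaga("CCCGAGAGCCC")
  pent <- hits[hits$tier == "pentamer", ]
  expect_equal(nrow(pent), 1)
  expect_equal(pent$start, 3)
  expect_equal(pent$end, 8)
  expect_equal(pent$strand, "+")

  # GAGAGAG holds two overlapping pentamer matches -> one merged hit
  hits <- scan_gaga("TTGAGAGAGTT")
  pent <- hits[hits$tier == "pentamer" & hits$strand == "+", ]
  expect_equal(nrow(pent), 1)
  expect_equal(c(pent$start, pent$end), c(2, 9))

  expect_equal(nrow(scan_gaga(strrep("C", 200),
                              params = gaga_params(tiers = "pentamer"))), 0)

  for (s in 1:12) {
    set.seed(100 + s)
    seq <- rand_dna_ga(5000)
    got <- scan_gaga(seq, params = gaga_params(tiers = "pentamer"))
    want <- bf_scan_gaga_pentamer(seq)
    expect_gt(nrow(want), 0)
    expect_same_hits(got, want, c("start", "end", "strand"))
  }
})

test_that("scan_gaga obeys strand reflection", {
  set.seed(55)
  seq <- rand_dna_ga(3000)
  n <- nchar(seq)
  fwd <- scan_gaga(seq, params = gaga_params(tiers = "pentamer"))
  rev <- scan_gaga(bf_revcomp(seq), params = gaga_params(tiers = "pentamer"))
  refl <- data.frame(start = n - rev$end, end = n - rev$start,
                     strand = ifelse(rev$strand == "+", "-", "+"))
  refl <- refl[order(refl$start, refl$end, refl$strand), ]
  expect_same_hits(refl, fwd[order(fwd$start, fwd$end, fwd$strand),
                             c("start", "end", "strand")],
                   c("start", "end", "strand"))
})

test_that("scan_gaga run tier requires length and GA-dinucleotide purity", {
  # pure alternation qualifies; homopolymer A run does not
  hits <- scan_gaga("CCGAGAGAGACC", params = gaga_params(tiers = "run"))
  run <- hits[hits$tier == "run" & hits$strand == "+", ]
  expect_equal(nrow(run), 1)
  expect_equal(run$run_length, 8)
  expect_equal(c(run$start, run$end), c(2, 10))
  expect_equal(nrow(scan_gaga("CCAAAAAAACC",
                              params = gaga_params(tiers = "run"))), 0)
  # minimal GAG tier only when requested
  expect_false("gag" %in% scan_gaga("CCGAGCC")$tier)
  g <- scan_gaga("CCGAGCC", params = gaga_params(include_gag = TRUE))
  expect_true("gag" %in% g$tier)
})

test_that("scan_gaga respects a search window", {
  seq <- paste0("GAGAG", strrep("C", 50), "GAGAG", strrep("C", 50))
  hits <- scan_gaga(seq, window = c(40, 70),
                    params = gaga_params(tiers = "pentamer"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 55)  # full-sequence coordinates
})

test_that("annotate_segments recovers planted truth on synthetic loci", {
  for (s in 1:20) {
    loc <- build_locus(jk_demo_spec(seed = s))
    truth <- loc$annotations
    ann <- annotate_segments(loc$sequence, data.frame(
      name = truth$segment_name, start = truth$body_start,
      end = truth$body_end))
    expect_equal(ann$functional_call, truth$functional)
    expect_equal(sum(ann$functional_call), 4)
    expect_equal(ann$rss_nonamer_start, truth$nonamer_start)
    fun <- truth$functional
    expect_equal(ann$distance_to_rss[fun], truth$gaga_distance[fun])
    expect_true(all(ann$distance_to_rss[fun] == 80))
  }
})

test_that("an RSS without a 5' GAGA motif does not make a functional call", {
  set.seed(5)
  spacer <- rand_dna(23, gc = 0.5)
  # RSS planted, body right after; no GAGAG anywhere (C/T-free of GA runs)
  seq <- paste0(strrep("C", 1200), "CACAGTG", spacer, "ACAAAAACC", "CC",
                strrep("CT", 20), strrep("C", 100))
  body_start <- 1200 + 7 + 23 + 9 + 2
  ann <- annotate_segments(seq, data.frame(name = "seg", start = body_start,
                                           end = body_start + 40))
  expect_false(is.na(ann$rss_nonamer_start))
  expect_true(is.na(ann$gaga_start) || ann$distance_to_rss <= 0)
  expect_false(ann$functional_call)
})

test_that("a 3'-only GAGA motif is recorded with negative distance; ja_mode accepts it", {
  set.seed(6)
  spacer <- rand_dna(23, gc = 0.5)
  rss <- paste0("CACAGTG", spacer, "ACAAAAACC")
  # GAGAG only downstream of the gene body
  seq <- paste0(strrep("C", 1100), rss, "CC", strrep("C", 40),
                strrep("C", 95), "GAGAG", strrep("C", 200))
  body_start <- 1100 + 39 + 2
  ann <- annotate_segments(seq, data.frame(name = "seg", start = body_start,
                                           end = body_start + 40))
  expect_false(ann$functional_call)
  expect_true(!is.na(ann$distance_to_rss) && ann$distance_to_rss < 0)
  ann_ja <- annotate_segments(seq,
                              data.frame(name = "seg", start = body_start,
                                         end = body_start + 40),
                              params = annotate_params(ja_mode = TRUE))
  expect_true(ann_ja$functional_call)
})

test_that("annotation of a minus-strand segment mirrors the plus-strand call", {
  loc <- build_locus(jk_demo_spec(seed = 3))
  truth <- loc$annotations
  n <- nchar(loc$sequence)
  rcseq <- bf_revcomp(loc$sequence)
  bodies_rc <- data.frame(name = truth$segment_name,
                          start = n - truth$body_end,
                          end = n - truth$body_start, strand = "-")
  ann <- annotate_segments(rcseq, bodies_rc)
  ann <- ann[match(truth$segment_name, ann$segment_name), ]
  expect_equal(ann$functional_call, truth$functional)
  fun <- truth$functional
  expect_equal(ann$distance_to_rss[fun], truth$gaga_distance[fun])
})

test_that("spacing_report summarises distances and hit categories", {
  mk <- function(seg, d) data.frame(
    segment_name = seg, body_start = 0, body_end = 1, strand = "+",
    rss_heptamer_start = NA, rss_nonamer_start = NA, rss_spacer_len = NA,
    gaga_start = NA, gaga_end = NA, gaga_tier = "pentamer",
    gaga_run_length = NA, distance_to_rss = d, functional_call = TRUE)
  rep1 <- spacing_report(mk(paste0("Jk", 1:4), c(80, 80, 80, 80)))
  expect_equal(rep1$summary$mean_distance, 80)
  expect_equal(rep1$summary$min_distance, 80)
  expect_equal(rep1$summary$max_distance, 80)

  rep2 <- spacing_report(mk(c("JH1", "JH2"), c(273, 361)))
  expect_equal(rep2$summary$mean_distance, 317)
  expect_equal(c(rep2$summary$min_distance, rep2$summary$max_distance),
               c(273, 361))

  rep3 <- spacing_report(mk(c("a", "b", "c"), c(100, NA, -40)))
  expect_equal(rep3$summary$n_5prime, 1)
  expect_equal(rep3$summary$n_3prime_only, 1)
  expect_equal(rep3$summary$n_no_hit, 1)
})

test_that("find_restriction_sites handles XhoI and degenerate HinfI", {
  expect_equal(find_restriction_sites("AACTCGAGTT", "XhoI"), 2)
  expect_equal(find_restriction_sites("GACTC", "HinfI"), 0)
  expect_equal(find_restriction_sites("GAGTC", "HinfI"), 0)
  expect_equal(find_restriction_sites("TTGANTCTT", "XhoI"), integer(0))
  expect_error(find_restriction_sites("ACGT", "EcoRI"), "unknown enzyme")

  # the GAGAG -> CTCGA edit followed by G creates an XhoI site
  wt <- paste0("TTTT", "GAGAG", "GTTTT")
  mut <- paste0("TTTT", "CTCGA", "GTTTT")
  expect_equal(length(find_restriction_sites(wt, "XhoI")), 0)
  expect_equal(find_restriction_sites(mut, "XhoI"), 4)
})
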