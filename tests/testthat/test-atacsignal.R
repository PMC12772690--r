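test_that("partition_fragments applies the insert-size thresholds", {
  fs <- fragment_set("chr", start = c(0, 0, 0), end = c(60, 200, 130))
  p <- partition_fragments(fs, track_config())
  expect_equal(nrow(p$subnuc), 1)
  expect_equal(nrow(p$nuc), 1)
  expect_equal(p$discarded, 1)

  pe <- partition_fragments(fragment_set("chr"), track_config())
  expect_equal(nrow(pe$subnuc) + nrow(pe$nuc) + pe$discarded, 0)
})

test_that("partition of simulated fragments matches simulator truth", {
  cfg <- atac_sim_config(
    dyads = data.frame(position = 2000, fuzziness_sd = 20,
                       fragment_count = 5000),
    accessible_windows = data.frame(start = 500, end = 3500,
                                    fragment_count = 5000),
    nuc_insert_mean = 200, nuc_insert_sd = 15,
    subnuc_insert_mean = 60, subnuc_insert_sd = 5, seed = 4)
  fs <- simulate_fragments(cfg, 4000)
  p <- partition_fragments(fs, track_config())
  # expected class sizes from the Normal insert model, binomial 4-SE bands:
  # P(N(60,5) < 100) ~ 1 (sub-nucleosomal tail above 100 is ~1e-15);
  # P(180 <= N(200,15) <= 620) leaves a ~9% left tail in the discard bin
  p_nuc <- pnorm(620.5, 200, 15) - pnorm(179.5, 200, 15)
  expect_lt(abs(nrow(p$subnuc) - 5000), 5)
  expect_lt(abs(nrow(p$nuc) - 5000 * p_nuc),
            4 * sqrt(5000 * p_nuc * (1 - p_nuc)))
  expect_equal(nrow(p$subnuc) + nrow(p$nuc) + p$discarded, nrow(fs))
})

test_that("occupancy peak matches the closed-form kernel sum", {
  # 1000 nucleosomal fragments, all with midpoint 500, no Tn5 shift
  fs <- fragment_set("chr", start = rep(400, 1000), end = rep(600, 1000))
  cfg <- track_config(tn5_shift = FALSE)
  expect_warning(tr <- occupancy_track(fs, c(300, 700), cfg),
                 "sub-nucleosomal")
  # per-million scaling: 1000 fragments -> x1000; all mass at 500.
  # the kernel is truncated at 4 sd, so compare within that support and
  # require (numerical) zero outside it
  expected <- 1e6 * dnorm(300:699, mean = 500, sd = cfg$kernel_sd)
  within <- abs(300:699 - 500) <= 4 * cfg$kernel_sd
  expect_lt(max(abs(tr$values[within] - expected[within])), 1e-6)
  expect_lt(max(abs(tr$values[!within])), 1e-6)
  expect_equal(which.max(tr$values) - 1 + 300, 500)
  # symmetric Gaussian decay
  expect_equal(tr$values[(500 - 300) + 1 + 30], tr$values[(500 - 300) + 1 - 30],
               tolerance = 1e-6)
})

test_that("occupancy tracks are invariant to library depth scaling", {
  set.seed(8)
  nuc_start <- sample(100:800, 300, replace = TRUE)
  sub_start <- sample(100:800, 500, replace = TRUE)
  fs1 <- fragment_set("chr", c(nuc_start, sub_start),
                      c(nuc_start + 200, sub_start + 60))
  k <- 3
  fs3 <- fragment_set("chr", rep(c(nuc_start, sub_start), k),
                      rep(c(nuc_start + 200, sub_start + 60), k))
  t1 <- occupancy_track(fs1, c(0, 1200))
  t3 <- occupancy_track(fs3, c(0, 1200))
  expect_equal(t1$values, t3$values, tolerance = 1e-9)

  a1 <- accessibility_track(fs1, c(0, 1200))
  a3 <- accessibility_track(fs3, c(0, 1200))
  expect_equal(a1$values, a3$values, tolerance = 1e-9)
})

test_that("identical positional distributions cancel in the occupancy difference", {
  region_mean <- replicate(60, {
    start <- sample(200:1800, 2000, replace = TRUE)
    fs <- fragment_set("chr",
                       c(start[1:1000], start[1001:2000]),
                       c(start[1:1000] + 200, start[1001:2000] + 60))
    tr <- occupancy_track(fs, c(500, 1500))
    mean(tr$values)
  })
  se <- sd(region_mean) / sqrt(length(region_mean))
  expect_lt(abs(mean(region_mean)), 3 * se + 1e-12)
})

test_that("accessibility counts shifted cut sites at tags per million", {
  fs <- fragment_set("chr", start = 100, end = 160)
  tr <- accessibility_track(fs, c(0, 300), track_config(),
                            library_size = 1e6)
  expect_equal(tr$values[104 + 1], 1.0)
  expect_equal(tr$values[155 + 1], 1.0)
  expect_equal(sum(tr$values), 2.0)

  # unshifted mode counts the raw ends
  tr0 <- accessibility_track(fs, c(0, 300), track_config(tn5_shift = FALSE),
                             library_size = 1e6)
  expect_equal(which(tr0$values > 0) - 1, c(100, 159))

  # no sub-nucleosomal fragments -> zero track
  fsn <- fragment_set("chr", 100, 300)
  trn <- accessibility_track(fsn, c(0, 400))
  expect_true(all(trn$values == 0))
})

test_that("uniform sub-nucleosomal coverage flattens as n grows", {
  cv <- function(n, seed) {
    cfg <- atac_sim_config(
      accessible_windows = data.frame(start = 0, end = 2000,
                                      fragment_count = n),
      seed = seed)
    fs <- simulate_fragments(cfg, 2000)
    tr <- accessibility_track(fs, c(500, 1500))
    sd(tr$values) / mean(tr$values)
  }
  expect_lt(cv(200000, 5), cv(2000, 5))
})

test_that("adding sub-nucleosomal fragments never decreases region accessibility", {
  set.seed(12)
  start <- sample(0:900, 200, replace = TRUE)
  fs <- fragment_set("chr", start, start + 60)
  tr <- accessibility_track(fs, c(0, 1000), library_size = 500)
  base_mean <- mean(tr$values[(400 + 1):600])
  fs2 <- fragment_set("chr", c(start, 450), c(start + 60, 510))
  tr2 <- accessibility_track(fs2, c(0, 1000), library_size = 500)
  expect_gte(mean(tr2$values[(400 + 1):600]), base_mean)
})

test_that("quantify_regions equals the per-base averaging oracle", {
  set.seed(13)
  vals <- rnorm(400, mean = 5)  # positive housekeeping mean
  tr <- structure(list(chrom = "chr", start = 100, end = 500, values = vals,
                       kind = "occupancy", config = track_config(),
                       library_size = 1L, n_signal = 1L, n_background = 1L),
                  class = "signal_track")
  regions <- data.frame(name = c("a", "b", "c"),
                        start = c(100, 250, 480), end = c(120, 400, 500))
  rq <- quantify_regions(tr, regions, c(150, 200))
  for (i in 1:3) {
    want <- mean(vals[(regions$start[i] - 100 + 1):(regions$end[i] - 100)])
    expect_equal(rq$mean_signal[i], want)
    expect_equal(rq$normalized[i], want / mean(vals[51:100]))
  }
})

test_that("quantify_regions normalizes a constant track to exactly 1", {
  tr <- structure(list(chrom = "c", start = 0, end = 100,
                       values = rep(2.5, 100), kind = "accessibility",
                       config = track_config(), library_size = 1L,
                       n_signal = 1L, n_background = NA_integer_),
                  class = "signal_track")
  rq <- quantify_regions(tr, data.frame(name = c("x", "y"),
                                        start = c(0, 60), end = c(10, 100)),
                         c(20, 40))
  expect_equal(rq$normalized, c(1, 1))
  expect_equal(rq$mean_signal, c(2.5, 2.5))

  # worked arithmetic: track {1,2,3,4}, housekeeping mean 2
  tr4 <- tr; tr4$values <- rep(c(1, 2, 3, 4, 2), each = 20)
  rq4 <- quantify_regions(tr4, data.frame(name = "r", start = 0, end = 80),
                          c(80, 100))
  expect_equal(rq4$mean_signal, 2.5)
  expect_equal(rq4$normalized, 1.25)

  expect_error(quantify_regions(tr, data.frame(name = "z", start = 5,
                                               end = 5), c(20, 40)),
               "length 0")
  expect_error(quantify_regions(tr, data.frame(name = "z", start = 90,
                                               end = 120), c(20, 40)),
               "outside")
  zero <- tr; zero$values <- rep(0, 100)
  expect_warning(rqz <- quantify_regions(zero,
                                         data.frame(name = "x", start = 0,
                                                    end = 10), c(20, 40)),
                 "housekeeping")
  expect_true(is.na(rqz$normalized))
  expect_equal(rqz$mean_signal, 0)
})

test_that("call_nucleosomes recovers a planted dyad and applies the tie rule", {
  cfg <- atac_sim_config(
    dyads = data.frame(position = 900, fuzziness_sd = 5,
                       fragment_count = 1000),
    accessible_windows = data.frame(start = 0, end = 2000,
                                    fragment_count = 1000),
    seed = 6)
  fs <- simulate_fragments(cfg, 2000)
  tr <- occupancy_track(fs, c(0, 2000))
  call <- call_nucleosomes(tr, anchor = 1000, flank = 250)
  expect_false(is.null(call))
  expect_lte(abs(call$dyad - 900), 10)

  # uniform zero occupancy -> no call
  flat <- structure(list(chrom = "c", start = 0, end = 500,
                         values = rep(0, 500), kind = "occupancy",
                         config = track_config(), library_size = 1L,
                         n_signal = 1L, n_background = 1L),
                    class = "signal_track")
  expect_null(call_nucleosomes(flat, anchor = 400, flank = 200))

  # two equal peaks -> the one nearer the anchor wins
  two <- flat
  two$values[c(101, 301)] <- 5   # positions 100 and 300
  call2 <- call_nucleosomes(two, anchor = 400, flank = 390)
  expect_equal(call2$dyad, 300)

  expect_error(call_nucleosomes(flat, anchor = 100, flank = 250), "outside")
})

test_that("dyad recovery holds within 10 bp in at least 90% of seeded runs", {
  hits <- vapply(1:50, function(s) {
    cfg <- atac_sim_config(
      dyads = data.frame(position = 900, fuzziness_sd = 10,
                         fragment_count = 1000),
      accessible_windows = data.frame(start = 0, end = 2000,
                                      fragment_count = 500),
      seed = s)
    fs <- simulate_fragments(cfg, 2000)
    tr <- occupancy_track(fs, c(0, 2000))
    call <- call_nucleosomes(tr, anchor = 1000, flank = 250)
    !is.null(call) && abs(call$dyad - 900) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("occupancy errors when both insert classes are empty", {
  fs <- fragment_set("chr", 0, 150)  # insert 150: neither class
  expect_error(occupancy_track(fs, c(0, 300)), "either insert-size class")
})
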