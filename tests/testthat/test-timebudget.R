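avail_q <- c(crepuscular = 0.25, diurnal = 0.5, nocturnal = 0.25)

test_that("selection ratios follow use over availability", {
  # counts proportional to availability: all ratios 1
  sr <- selection_ratios(c(crepuscular = 25, diurnal = 50, nocturnal = 25),
                         avail_q)
  expect_equal(sr$ratio, c(1, 1, 1))

  sr2 <- selection_ratios(c(crepuscular = 10, diurnal = 0, nocturnal = 0),
                          avail_q)
  expect_equal(sr2$ratio, c(4, 0, 0))

  # round trip: n_i = w_i * pi_i * N
  expect_equal(sr2$ratio * sr2$availability * sum(sr2$n), as.numeric(sr2$n))

  expect_error(
    selection_ratios(c(crepuscular = 1, diurnal = 1, nocturnal = 1),
                     c(crepuscular = 0, diurnal = 0.5, nocturnal = 0.5)),
    "availability"
  )
})

test_that("the chi-squared random-use test matches hand arithmetic", {
  ch <- chisq_random_use(c(crepuscular = 10, diurnal = 0, nocturnal = 0),
                         avail_q)
  expect_equal(ch$chi2, 30) # 22.5 + 5 + 2.5
  expect_equal(ch$df, 2)

  # zero deviation: statistic 0, p = 1
  ch0 <- chisq_random_use(c(crepuscular = 25, diurnal = 50, nocturnal = 25),
                          avail_q)
  expect_equal(ch0$chi2, 0)
  expect_equal(ch0$p_value, 1)

  # invariant to period relabelling with permuted availability
  cnt <- c(crepuscular = 12, diurnal = 40, nocturnal = 23)
  perm <- c(crepuscular = 40, diurnal = 23, nocturnal = 12)
  pa <- c(crepuscular = 0.5, diurnal = 0.25, nocturnal = 0.25)
  expect_equal(chisq_random_use(cnt, avail_q)$chi2,
               chisq_random_use(perm, pa)$chi2)
})

test_that("selection on published-style counts reproduces the printed ratios", {
  # masked-palm-civet-like warm-season record: counts (32, 5, 99) against
  # availability ~(0.125, 0.541, 0.335) give ratios ~(1.88, 0.07, 2.17)
  # and chi2 ~139.6
  avail <- c(crepuscular = 0.1252, diurnal = 0.5411, nocturnal = 0.3337)
  counts <- c(crepuscular = 32, diurnal = 5, nocturnal = 99)
  sr <- selection_ratios(counts, avail)
  expect_equal(sr$ratio, c(1.88, 0.07, 2.17), tolerance = 0.01)
  ch <- chisq_random_use(counts, avail)
  expect_equal(ch$chi2, 139.57, tolerance = 0.02)
  expect_lt(ch$p_value, 0.001)
})

test_that("randomization p-values are directional, add-one corrected and stable", {
  counts <- c(crepuscular = 150, diurnal = 40, nocturnal = 10)
  pa <- c(crepuscular = 0.1, diurnal = 0.5, nocturnal = 0.4)
  rt <- randomization_test(counts, pa, n_reps = 2000, seed = 1)
  # extreme excess: smallest attainable p
  expect_equal(rt$p_value[1], 1 / 2001)
  expect_equal(rt$direction[1], "more than expected")
  expect_equal(rt$direction[3], "less than expected")
  expect_true(all(rt$p_value > 0))

  # reproducible under a fixed seed
  rt2 <- randomization_test(counts, pa, n_reps = 2000, seed = 1)
  expect_equal(rt, rt2)

  # converges with more replicates on a moderate case
  cnt <- c(crepuscular = 30, diurnal = 95, nocturnal = 75)
  p_small <- randomization_test(cnt, avail_q, n_reps = 2000, seed = 3)$p_value
  p_big <- randomization_test(cnt, avail_q, n_reps = 100000, seed = 4)$p_value
  expect_true(all(abs(p_small - p_big) < 0.01 + 3 * sqrt(p_big * (1 - p_big) / 2000)))
})

test_that("randomization tails match the exact binomial at small N", {
  # with a negligible third period the per-period null is Binomial(N, pi_i)
  pa <- c(crepuscular = 0.45, diurnal = 0.45, nocturnal = 0.10)
  counts <- c(crepuscular = 14, diurnal = 5, nocturnal = 1)
  n_reps <- 20000
  rt <- randomization_test(counts, pa, n_reps = n_reps, seed = 5)
  exact_upper <- pbinom(13, 20, 0.45, lower.tail = FALSE) # P(X >= 14)
  mc_se <- sqrt(exact_upper * (1 - exact_upper) / n_reps)
  expect_equal(rt$p_value[1], exact_upper, tolerance = (3 * mc_se + 1e-4) / exact_upper)
  exact_lower <- pbinom(5, 20, 0.45) # P(X <= 5)
  mc_se2 <- sqrt(exact_lower * (1 - exact_lower) / n_reps)
  expect_equal(rt$p_value[2], exact_lower, tolerance = (3 * mc_se2 + 1e-4) / exact_lower)
})

test_that("diel_selection assembles per-species-season rows", {
  set.seed(41)
  dep <- toy_deployment(start = "2014-05-01 00:00:00",
                        end = "2014-07-01 00:00:00")
  # nocturnal species: events between 22:00 and 04:00
  hrs <- c(runif(30, 22, 24), runif(20, 0, 4), runif(5, 10, 14))
  days <- sample(0:59, 55, TRUE)
  ph <- toy_photos(format(clock("2014-05-01 00:00:00") + days * 86400 +
                            hrs * 3600), species = "night_cat")
  ev <- annotate_events(independent_events(ph), dep)
  sel <- diel_selection(ev, dep, min_n = 10, n_reps = 500, seed = 9)
  expect_equal(nrow(sel), 3)
  expect_equal(as.character(sel$period), c("crepuscular", "diurnal", "nocturnal"))
  noct <- sel[sel$period == "nocturnal", ]
  expect_gt(noct$ratio, 1)
  expect_equal(noct$direction, "more than expected")
  expect_equal(sum(sel$use), 1)
  # availability columns sum to 1 within the table
  expect_equal(sum(sel$availability), 1, tolerance = 1e-9)
})
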