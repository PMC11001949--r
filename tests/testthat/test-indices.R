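# Frozen worked examples: a dish of 20 seeds with germination events on
# days 26, 30, 30 and 35 of a 60-day trial, plus the degenerate cases.

test_that("each index reproduces its hand-computed value", {
  s <- make_schedule(c(26, 30, 30, 35))
  expect_equal(final_germination_percentage(s), 20)
  expect_equal(mean_germination_time(s), 121 / 4)
  expect_equal(mean_germination_rate(s), 4 / 121)
  expect_equal(germination_span(s), c(fdg = 26, ldg = 35))
  expect_equal(median_germination_time(s), 29)
  disp <- germination_time_dispersion(s)
  expect_equal(disp[["s_t2"]], 163 / 12, tolerance = 1e-12)
  expect_equal(disp[["cvt"]], 100 * sqrt(163 / 12) / 30.25,
               tolerance = 1e-12)
  expect_equal(coefficient_of_velocity(s), 400 / 121)
  expect_equal(germination_rate_index(s), 5 / 26 + 10 / 30 + 5 / 35)
  expect_equal(germination_index(s), 35 + 2 * 31 + 26)

  all_idx <- germination_indices(s)
  expect_equal(all_idx$cvt, 12.18, tolerance = 1e-3)
  expect_equal(all_idx$gri, 0.6685, tolerance = 1e-4)
})

test_that("degenerate schedules follow the stated rules", {
  none <- germination_schedule(rep(0L, 60), 20)
  expect_equal(final_germination_percentage(none), 0)
  expect_true(is.na(mean_germination_time(none)))
  expect_true(is.na(mean_germination_rate(none)))
  expect_true(all(is.na(germination_span(none))))
  expect_true(is.na(median_germination_time(none)))
  expect_true(all(is.na(germination_time_dispersion(none))))
  expect_true(is.na(coefficient_of_velocity(none)))
  expect_equal(germination_rate_index(none), 0)
  expect_equal(germination_index(none), 0)

  day1 <- make_schedule(rep(1, 20))
  expect_equal(mean_germination_time(day1), 1)
  expect_equal(mean_germination_rate(day1), 1)
  expect_equal(coefficient_of_velocity(day1), 100)
  expect_equal(germination_rate_index(day1), 100)
  expect_equal(germination_index(day1), 1200)

  one_day <- make_schedule(rep(17, 5))
  expect_equal(median_germination_time(one_day), 17)
  expect_equal(germination_time_dispersion(one_day)[["cvt"]], 0)

  single <- make_schedule(40)
  expect_equal(germination_span(single), c(fdg = 40, ldg = 40))
  expect_equal(median_germination_time(single), 40)
  expect_true(is.na(germination_time_dispersion(single)[["cvt"]]))

  last_day <- make_schedule(60)
  expect_equal(germination_index(last_day), 1)
})

test_that("T50 interpolates the printed formula on both bracket shapes", {
  # N = 10 germinated, cumulative 5 at day 10 and 10 at day 20:
  # 10 + (5.5 - 5) * 10 / 5 = 11
  s <- make_schedule(c(rep(10, 5), rep(20, 5)))
  expect_equal(median_germination_time(s), 11)
  # exact hit of (N+1)/2: N = 3, cumulative 2 at day 8
  s2 <- make_schedule(c(5, 8, 12), total_seeds = 5, duration_days = 20)
  expect_equal(median_germination_time(s2), 8)
  # first event day already past the half-count
  s3 <- make_schedule(c(rep(10, 6), rep(20, 4)))
  expect_equal(median_germination_time(s3), 10)
})

test_that("indices agree with the per-event oracle on random schedules", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    k <- sample(5:60, 1)
    g <- sample(0:n, 1)
    days <- if (g) sample(k, g, replace = TRUE) else integer(0)
    s <- make_schedule(days, total_seeds = n, duration_days = k)
    got <- germination_indices(s)
    want <- oracle_indices(days, n, k)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12,
                   info = sprintf("%s on n=%d k=%d days=%s", f, n, k,
                                  paste(days, collapse = ",")))
    }
  }
})

test_that("reciprocity, monotonicity and scale invariance hold", {
  set.seed(99)
  for (rep in 1:100) {
    g <- sample(1:20, 1)
    days <- sample(60, g, replace = TRUE)
    s <- make_schedule(days, total_seeds = 20 + g)
    expect_lt(abs(mean_germination_rate(s) * mean_germination_time(s) - 1),
              1e-12)
    expect_lt(abs(coefficient_of_velocity(s) -
                    100 * mean_germination_rate(s)), 1e-9)
    expect_lte(germination_index(s), s$duration_days * s$total_seeds)

    # extra germination event never decreases FGP, GRI, GI
    extra <- make_schedule(c(days, sample(60, 1)), total_seeds = 20 + g)
    expect_gte(final_germination_percentage(extra),
               final_germination_percentage(s))
    expect_gte(germination_rate_index(extra), germination_rate_index(s))
    expect_gte(germination_index(extra), germination_index(s))

    # doubling every count and N: ratio-form indices unchanged, GI doubles.
    # T50 and CVt are only asymptotically scale-free: their printed
    # formulas carry the small-sample corrections (N+1)/2 and sum(n)-1.
    dbl <- germination_schedule(2L * s$daily_counts, 2L * s$total_seeds,
                                s$duration_days)
    for (f in c("final_germination_percentage", "mean_germination_time",
                "mean_germination_rate", "coefficient_of_velocity")) {
      expect_equal(get(f)(dbl), get(f)(s), tolerance = 1e-12)
    }
    expect_equal(germination_index(dbl), 2 * germination_index(s))

    # T50 within the germination span
    span <- germination_span(s)
    t50 <- median_germination_time(s)
    expect_gte(t50, span[["fdg"]])
    expect_lte(t50, span[["ldg"]])
  }
})

test_that("GRI cumulative reading is available behind the flag", {
  s <- make_schedule(c(26, 30, 30, 35))
  cum_pct <- cumsum(100 * s$daily_counts / 20)
  expect_equal(germination_rate_index(s, cumulative = TRUE),
               sum(cum_pct / 1:60))
  expect_gt(germination_rate_index(s, cumulative = TRUE),
            germination_rate_index(s))
})

test_that("cut-test summary yields percentages over tested seeds", {
  ct <- summarize_cut_test(1, 16, 3)
  expect_equal(ct$percent, c(5, 80, 15))
  expect_equal(sum(ct$percent), 100)
  expect_equal(summarize_cut_test(20, 0, 0)$percent, c(100, 0, 0))
  expect_error(summarize_cut_test(0, 0, 0), "at least one")
  expect_error(summarize_cut_test(-1, 2, 3), "non-negative")
})

test_that("treatment summaries exclude undefined indices from means", {
  idx <- germination_index_table(list(
    make_schedule(c(20, 30), dish_id = "a", treatment_id = "t1"),
    make_schedule(integer(0), dish_id = "b", treatment_id = "t1")
  ))
  sm <- summarize_treatments(idx)
  mgt_row <- sm[sm$index == "mgt", ]
  expect_equal(mgt_row$mean, 25)   # the empty dish does not drag this to NA
  expect_equal(mgt_row$n_defined, 1L)
  fgp_row <- sm[sm$index == "fgp", ]
  expect_equal(fgp_row$mean, 5)    # but contributes a true 0 to capacity
  expect_equal(fgp_row$n_defined, 2L)
})
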