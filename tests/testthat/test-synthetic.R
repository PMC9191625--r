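test_that("the default cohort reproduces the study's group structure", {
  cohort <- simulate_cohort(cohort_spec(), seed = 1)
  expect_identical(nrow(cohort), 72L)
  expect_equal(as.integer(table(cohort$group)[c("MMSE<24", "MMSE24-27",
                                                "MMSE>=28", "YOUNG")]),
               c(17L, 16L, 17L, 22L))
  low <- cohort$mmse[cohort$group == "MMSE<24"]
  expect_true(all(low >= 17 & low <= 23))
  mid <- cohort$mmse[cohort$group == "MMSE24-27"]
  expect_true(all(mid >= 24 & mid <= 27))
  expect_true(all(is.na(cohort$mmse[cohort$group == "YOUNG"])))
})

test_that("large-cohort group ages concentrate at the specified means", {
  spec <- cohort_spec(n_low = 250, n_mid = 250, n_high = 250, n_young = 250)
  cohort <- simulate_cohort(spec, seed = 2)
  mu <- tapply(cohort$age, cohort$group, mean)
  expect_lt(abs(mu[["MMSE<24"]] - 79.26), 1.5)
  expect_lt(abs(mu[["MMSE24-27"]] - 75.42), 1.5)
  expect_lt(abs(mu[["MMSE>=28"]] - 74.77), 1.5)
  expect_lt(abs(mu[["YOUNG"]] - 24.09), 0.5)
})

test_that("recordings are deterministic per seed", {
  lib <- test_library()
  sc <- generate_schedule(3)
  p <- data.frame(participant_id = "Y1", age = 24, sex = "F",
                  mmse = NA_integer_, group = "YOUNG")
  r1 <- simulate_recording(p, effect_params(), sc, lib, seed = 5)
  r2 <- simulate_recording(p, effect_params(), sc, lib, seed = 5)
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_recording(p, effect_params(), sc, lib, seed = 6)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("Theta power increases with load for the young profile only", {
  lib <- test_library()
  sc <- generate_schedule(11)
  ef <- effect_params()
  young <- data.frame(participant_id = "Y1", age = 24, sex = "F",
                      mmse = NA_integer_, group = "YOUNG")
  senior <- data.frame(participant_id = "S1", age = 78, sex = "M",
                       mmse = 21L, group = "MMSE<24")
  ymeans <- smeans <- matrix(0, 4, 3, dimnames = list(NULL,
                                                      c("RS", "D1", "D2")))
  for (i in 1:4) {
    ry <- simulate_recording(young, ef, sc, lib, seed = 40 + i)
    bp <- band_power_series(ry)
    lv <- task_level_at(sc, bp$t_s)
    ymeans[i, ] <- tapply(bp$Theta, lv, mean)[c("RS", "D1", "D2")]
    rs <- simulate_recording(senior, ef, sc, lib, seed = 140 + i)
    bps <- band_power_series(rs)
    smeans[i, ] <- tapply(bps$Theta, task_level_at(sc, bps$t_s),
                          mean)[c("RS", "D1", "D2")]
  }
  ym <- colMeans(ymeans)
  expect_lt(ym["RS"], ym["D1"])
  expect_lt(ym["D1"], ym["D2"])
  sm <- colMeans(smeans)
  expect_lt(abs(sm["D2"] - sm["RS"]), 0.5)
})

test_that("click behavior carries the planted RT-MMSE correlation", {
  sc <- generate_schedule(42)
  ef <- effect_params()
  set.seed(1)
  mm <- sample(17:30, 200, replace = TRUE)
  stats <- vapply(seq_along(mm), function(i) {
    p <- data.frame(participant_id = "S", age = 75, sex = "M",
                    mmse = mm[i], group = "MMSE<24")
    bs <- score_responses(sc, simulate_clicks(p, ef, sc, seed = 5000 + i))
    c(bs$mean_rt_all, bs$accuracy_d1, bs$accuracy_d2)
  }, numeric(3))
  r <- cor(stats[1, ], mm)
  expect_lt(abs(r - ef$rt_mmse_r), 0.1)
  expect_true(all(stats[1, ] > 0))
  # hit probability is monotone in MMSE
  hi <- mean(stats[2:3, mm >= 28])
  lo <- mean(stats[2:3, mm <= 20])
  expect_gte(hi, lo)
})

test_that("clicks are deterministic and within response range", {
  sc <- generate_schedule(12)
  p <- data.frame(participant_id = "S", age = 75, sex = "M", mmse = 25L,
                  group = "MMSE24-27")
  c1 <- simulate_clicks(p, effect_params(), sc, seed = 2)
  c2 <- simulate_clicks(p, effect_params(), sc, seed = 2)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_true(all(c1$onset_s > 0))
})

test_that("hierarchical seeds stay within 32-bit integer range", {
  for (tag in c("cohort", "rec_Y001", "bcaRTsavg", "sched_M016"))
    for (master in c(1, 2, 1000, 2^28)) {
      s <- derive_seed(master, tag)
      expect_true(is.integer(s) && s >= 0 && s < 2^31)
    }
})
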