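test_that("schedule invariants hold across seeds", {
  for (seed in 1:60) {
    sc <- generate_schedule(seed)
    blocks <- attr(sc, "blocks")
    cfg <- attr(sc, "config")
    d1 <- blocks[blocks$level == "D1", ]
    expect_identical(nrow(d1), 3L)
    expect_true(all(d1$dur == 90))
    total <- attr(sc, "total_s")
    expect_gte(total, 1020)   # 18 +/- 1 min
    expect_lte(total, 1140)
    mel <- sc[sc$kind == "melody", ]
    expect_true(all(mel$duration_s[mel$task_level == "D1"] == 3))
    expect_true(all(mel$duration_s[mel$task_level == "D2"] == 1.5))
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      m <- mel[mel$onset_s >= b$start & mel$onset_s < b$start + b$dur, ]
      gaps <- diff(m$onset_s) - m$duration_s[-nrow(m)]
      if (b$level == "D1") {
        expect_true(nrow(m) %in% 5:6)
        expect_true(all(m$is_target))
        expect_true(all(gaps >= 10 - 1e-9 & gaps <= 18 + 1e-9))
      } else {
        expect_true(nrow(m) %in% 6:8)
        expect_true(sum(m$is_target) %in% 2:3)
        expect_true(all(gaps >= 8 - 1e-9 & gaps <= 14 + 1e-9))
        expect_true(all(m$instrument[m$is_target] == b$instrument))
        expect_true(all(m$instrument[!m$is_target] != b$instrument))
      }
    }
  }
})

test_that("the resting block precedes the task blocks and schedules are
          deterministic", {
  sc1 <- generate_schedule(99)
  sc2 <- generate_schedule(99)
  expect_identical(as.data.frame(sc1), as.data.frame(sc2))
  expect_identical(sc1$task_level[1], "RS")
  expect_identical(task_level_at(sc1, c(0, 60, 119.9))[1:3],
                   rep("RS", 3))
  expect_identical(task_level_at(sc1, 121), "D1")
})

test_that("infeasible battery configurations are rejected", {
  cfg <- battery_config()
  cfg$d1_instances <- c(30, 30)      # 30 melodies cannot fit in 90 s
  expect_error(generate_schedule(1, cfg), "infeasible")
})

test_that("click scoring implements the hit/false-alarm rules", {
  sc <- generate_schedule(7)
  targets <- sc[sc$kind == "melody" & sc$is_target, ]
  t1 <- targets$onset_s[1]
  mk_clicks <- function(times) event_list(data.frame(
    onset_s = times, duration_s = rep(0, length(times)),
    kind = rep("click", length(times)),
    instrument = rep("none", length(times)),
    is_target = rep(FALSE, length(times)),
    task_level = rep("RS", length(times))))

  bs <- score_responses(sc, mk_clicks(t1 + 1.2))
  expect_equal(bs$hits$rt[1], 1.2)
  expect_equal(bs$accuracy_d1, 1 / sum(targets$task_level == "D1"))

  # a second click on the same target is ignored, not a false alarm
  bs2 <- score_responses(sc, mk_clicks(c(t1 + 1.0, t1 + 1.5)))
  expect_equal(bs2$hits$rt[1], 1.0)
  expect_identical(bs2$false_alarms, 0L)

  # a click in silence is a false alarm and excluded from RTs
  far <- targets$onset_s[1] - 5
  bs3 <- score_responses(sc, mk_clicks(far))
  expect_identical(bs3$false_alarms, 1L)
  expect_true(is.na(bs3$mean_rt_all))

  # no clicks: zero accuracy, undefined RT
  bs4 <- score_responses(sc, mk_clicks(numeric(0)))
  expect_equal(bs4$accuracy_d1, 0)
  expect_equal(bs4$accuracy_d2, 0)
  expect_true(is.na(bs4$mean_rt_d1))

  # scoring is invariant to click order
  times <- targets$onset_s[1:5] + 0.8
  expect_identical(score_responses(sc, mk_clicks(times))$hits,
                   score_responses(sc, mk_clicks(rev(times)))$hits)
})

test_that("scoring requires targets", {
  sc <- generate_schedule(7)
  no_targets <- event_list(as.data.frame(sc)[sc$kind != "melody", ])
  attr(no_targets, "blocks") <- attr(sc, "blocks")
  clicks <- event_list(data.frame(onset_s = 1, duration_s = 0,
                                  kind = "click", instrument = "none",
                                  is_target = FALSE, task_level = "RS"))
  expect_error(score_responses(no_targets, clicks), "without targets")
})
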