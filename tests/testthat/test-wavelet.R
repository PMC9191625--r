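test_that("windowing produces the spectrogram-style 75%-overlap grid", {
  rec <- noise_recording(20)
  ws <- segment_windows(rec, 2048, 500)
  expect_length(ws$starts, (10000 - 2048) %/% 500 + 1)   # 16
  expect_equal(ws$starts[1:3], c(0, 500, 1000))
  expect_length(segment_windows(recording(rnorm(2048), 500))$starts, 1)
  expect_error(segment_windows(recording(rnorm(2047), 500)),
               "shorter than window")
})

test_that("quadrature filters are orthonormal and satisfy Parseval at every
          level", {
  for (nm in c("haar", "db4")) {
    filt <- filter_pair(nm)
    expect_equal(sum(filt$h^2), 1, tolerance = 1e-12)
    expect_equal(sum(filt$g^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(filt$h * filt$g)), 1e-12)
    for (rep in 1:10) {
      x <- rnorm(256)
      tr <- wp_full_tree(x, filt, 5)
      for (L in 0:5)
        expect_equal(sum(tr$coef[L + 1, ]^2), sum(x^2), tolerance = 1e-10)
    }
  }
})

test_that("Haar analysis matches hand computations", {
  # differences of a constant vanish on every high-pass branch
  tr <- wp_full_tree(rep(3, 32), filter_pair("haar"), 3)
  for (L in 1:3) for (f in 1:(2^L - 1))
    expect_equal(sum(tree_node(tr, L, f)^2), 0)
  # the alternating frame is pure difference content
  tr2 <- wp_full_tree(rep(c(1, -1), 8), filter_pair("haar"), 1)
  expect_equal(sum(tree_node(tr2, 1, 0)^2), 0)
  expect_equal(sum(tree_node(tr2, 1, 1)^2), 16)
})

test_that("round trips reconstruct perfectly from full depth and from a
          best basis", {
  filt <- filter_pair("db4")
  for (rep in 1:25) {
    x <- rnorm(512)
    tr <- wp_full_tree(x, filt, 6)
    expect_lt(max(abs(reconstruct_window(tr) - x)), 1e-9 * max(abs(x)))
    bb <- select_best_basis(tr)
    expect_lt(max(abs(reconstruct_window(tr, bb) - x)), 1e-9 * max(abs(x)))
  }
  tr0 <- wp_full_tree(rnorm(64), filt, 3)
  tr0$coef[] <- 0
  expect_equal(reconstruct_window(tr0), numeric(64))
  expect_error(reconstruct_window(tr0, data.frame(level = 1, f = 0)),
               "incomplete cover")
})

test_that("best-basis selection is a disjoint cover attaining the
          exhaustive minimum", {
  filt <- filter_pair("haar")
  for (rep in 1:30) {
    x <- rnorm(16)
    tr <- wp_full_tree(x, filt, 3)
    for (cost in c("shannon_entropy", "log_energy")) {
      bb <- select_best_basis(tr, cost)
      expect_equal(sum(1 / 2^bb$level), 1)
      all_covers <- enumerate_prunings(tr, cost)
      expect_equal(attr(bb, "cost"), min(vapply(all_covers, `[[`, 0, "cost")),
                   tolerance = 1e-10)
    }
  }
})

test_that("a frame equal to one packet atom selects that atom's node", {
  filt <- filter_pair("db4")
  w <- wp_atom(64, filt, 2, 1)
  tr <- wp_full_tree(w, filt, 3)
  bb <- select_best_basis(tr)
  hit <- bb$level == 2 & bb$f == 1
  expect_true(any(hit))
  expect_gt(sum(tree_node(tr, 2, 1)^2), 0.99 * sum(w^2))
})

test_that("hard thresholding zeroes sub-threshold coefficients and keeps
          planted ones", {
  x <- rep(0.1, 100)
  out <- prune_denoise(x, "fixed", tau = 0.5)
  expect_equal(as.numeric(out), numeric(100))
  expect_equal(as.numeric(prune_denoise(x, "fixed", tau = 0)), x)

  set.seed(4)
  noise <- rnorm(1024, sd = 1)
  tau_univ <- (median(abs(noise)) / 0.6745) * sqrt(2 * log(1024))
  y <- noise
  y[100] <- 10 * tau_univ
  kept <- prune_denoise(y, "universal")
  expect_equal(kept[100], y[100])
  expect_lt(mean(kept[-100] != 0), 0.05)
  expect_error(prune_denoise(numeric(0)), "empty")
})

test_that("pruned energy is non-increasing in tau and accounted for by the
          reconstruction error", {
  filt <- filter_pair("db4")
  x <- rnorm(256)
  tr <- wp_full_tree(x, filt, 4)
  taus <- c(0, 0.5, 1, 2, 4)
  e <- vapply(taus, function(tau) {
    pr <- prune_denoise(tr, "fixed", tau)
    sum(pr$coef[5, ]^2)
  }, 0)
  expect_true(all(diff(e) <= 0))
  # Parseval bookkeeping at the deepest level
  pr <- prune_denoise(tr, "fixed", 1)
  basis <- data.frame(level = 4, f = 0:15)
  xhat <- reconstruct_window(pr, basis)
  removed <- sum(tr$coef[5, ]^2) - sum(pr$coef[5, ]^2)
  expect_equal(sum((x - xhat)^2), removed, tolerance = 1e-8)
})

test_that("the frozen library has 121 atoms and is deterministic", {
  lib <- test_library()
  expect_identical(nrow(lib$atoms), 121L)
  corpus <- simulate_baseline_corpus(n_rec = 2, minutes = 1, seed = 11)
  a <- build_baf_library(corpus, seed = 3, max_windows_per_rec = 40,
                         min_minutes = 1)
  b <- build_baf_library(corpus, seed = 3, max_windows_per_rec = 40,
                         min_minutes = 1)
  expect_identical(a$atoms, b$atoms)
  expect_error(build_baf_library(corpus[1], seed = 1, min_minutes = 10),
               "too short")
})

test_that("a pure 6-Hz corpus concentrates top-ranked atoms near 6 Hz", {
  fs <- 500
  recs <- lapply(1:2, function(i) withr::with_seed(20 + i, {
    t <- (0:(90 * fs - 1)) / fs
    recording(20 * sin(2 * pi * 6 * t + runif(1)) + rnorm(length(t)), fs)
  }))
  lib <- build_baf_library(recs, seed = 2, max_windows_per_rec = 40,
                           min_minutes = 2)
  expect_lt(abs(lib$atoms$peak_hz[1] - 6), 1.5)
})

test_that("BAF extraction has the contracted shape and responds to planted
          content", {
  lib <- test_library()
  rec <- noise_recording(10, seed = 9)
  baf <- extract_bafs(rec, lib)
  expect_identical(ncol(baf), 121L)
  expect_identical(nrow(baf), length(segment_windows(rec, lib$n_win,
                                                     lib$hop)$starts))
  z <- extract_bafs(recording(rep(0, 5000), 500), lib, "fixed", 0)
  expect_equal(max(abs(z)), 0)
  # a recording made of one library atom, extracted on atom-aligned
  # windows, lights up exactly that atom's column
  k <- which.min(abs(lib$atoms$peak_hz - 30))
  w <- wp_atom(lib$n_win, lib$filter, lib$atoms$level[k], lib$atoms$f[k])
  rec2 <- recording(rep(w, 4) * 100, 500)
  lib_aligned <- lib
  lib_aligned$hop <- lib$n_win
  baf2 <- extract_bafs(rec2, lib_aligned, "fixed", 0)
  cm <- colMeans(baf2)
  # the planted node attains the maximum (ancestor nodes, whose blocks
  # contain the same coefficient, legitimately tie with it)
  expect_equal(unname(cm[k]), max(cm), tolerance = 1e-9)
  expect_gt(unname(cm[k]), 10 * median(cm))
})

test_that("high-frequency EMG bursts are flagged, clean EEG is not", {
  lib <- test_library()
  fs <- 500
  rec <- simulate_baseline_corpus(1, 1, seed = 31)[[1]]
  baf <- extract_bafs(rec, lib)
  expect_identical(sum(flag_artifacts(baf, lib)), 0L)

  x <- rec$samples
  burst <- withr::with_seed(5, rnorm(fs)) * 10 * sd(x)
  t_hz <- seq_len(fs)
  burst <- burst * sin(2 * pi * 100 * t_hz / fs)   # shift toward 100 Hz
  i0 <- 20 * fs
  x[i0 + seq_len(fs)] <- x[i0 + seq_len(fs)] + burst
  baf2 <- extract_bafs(recording(x, fs), lib)
  flags <- flag_artifacts(baf2, lib)
  t_s <- attr(baf2, "t_s")
  overlap <- t_s > 20 - 2 & t_s < 21 + 2
  expect_gt(sum(flags[overlap]), 0)
  z <- extract_bafs(recording(rep(0, 5000), fs), lib, "fixed", 0)
  expect_identical(sum(flag_artifacts(z, lib)), 0L)
})

test_that("extraction is deterministic given identical input", {
  lib <- test_library()
  rec <- noise_recording(8, seed = 2)
  expect_identical(extract_bafs(rec, lib), extract_bafs(rec, lib))
})
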