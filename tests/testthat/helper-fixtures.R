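# Shared fixtures and independent oracles. Heavy objects are built once per
# session and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small frozen BAF library built from a 3-minute baseline corpus
test_library <- function() {
  if (is.null(.fixtures$lib)) {
    corpus <- simulate_baseline_corpus(n_rec = 3, minutes = 1, seed = 7)
    .fixtures$lib <- build_baf_library(corpus, seed = 7,
                                       max_windows_per_rec = 60,
                                       min_minutes = 2)
  }
  .fixtures$lib
}

# white-noise recording of a given duration
noise_recording <- function(seconds, fs = 500, sd = 10, seed = 1) {
  withr::with_seed(seed, recording(rnorm(seconds * fs, sd = sd), fs))
}

# brute-force best-basis oracle: enumerate every admissible pruning of a
# depth-D tree and return the minimal total cost (independent of the DP)
enumerate_prunings <- function(tree, cost) {
  norm2 <- sum(tree$coef[1, ]^2)
  if (norm2 == 0) norm2 <- 1
  blk_cost <- function(level, f) {
    block <- tree_node(tree, level, f)
    if (cost == "shannon_entropy") {
      p <- block^2 / norm2
      p <- p[p > 0]
      -sum(p * log(p))
    } else sum(log(pmax(block^2, 1e-300)))
  }
  covers <- function(level, f) {
    # list of admissible covers of the subtree rooted at (level, f), each a
    # data.frame of nodes with its total cost
    own <- list(list(nodes = data.frame(level = level, f = f),
                     cost = blk_cost(level, f)))
    if (level == tree$depth) return(own)
    left <- covers(level + 1, 2 * f)
    right <- covers(level + 1, 2 * f + 1)
    combos <- list()
    for (a in left) for (b in right)
      combos[[length(combos) + 1]] <- list(
        nodes = rbind(a$nodes, b$nodes), cost = a$cost + b$cost)
    c(own, combos)
  }
  covers(0, 0)
}

# literal transcription of the z-test for two overlapping dependent
# correlations (Fisher-transformed, shared variable), kept independent of
# the package implementation
meng_oracle <- function(r_xy, r_xz, r_yz, n) {
  z1 <- atanh(r_xy)
  z2 <- atanh(r_xz)
  r2 <- (r_xy^2 + r_xz^2) / 2
  f <- min((1 - r_yz) / (2 * (1 - r2)), 1)
  h <- (1 - f * r2) / (1 - r2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_yz) * h))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# parametric "scaled replicate" of the study's effect structure at the
# per-window level: young-only task effect, per-participant random
# intercepts and task slopes
simulate_lmm_dataset <- function(n_per_group = 6, reps = 10, b_task = 0,
                                 young_only_task = 0, slope_sd = 0.5,
                                 int_sd = 1, sigma = 2, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    pid <- 0
    for (g in 0:3) for (i in seq_len(n_per_group)) {
      pid <- pid + 1
      u <- rnorm(1, 0, int_sd)
      s <- rnorm(1, 0, slope_sd)
      for (task in 0:2) {
        mu <- 10 + 0.5 * g + b_task * task +
          young_only_task * task * (g == 3) + u + s * task
        rows[[length(rows) + 1]] <- data.frame(
          participant = sprintf("P%03d", pid), group = g, task = task,
          value = mu + rnorm(reps, 0, sigma))
      }
    }
    do.call(rbind, rows)
  })
}

# exact vectors with a prescribed correlation: y = r*x + sqrt(1-r^2)*e with
# x, e orthonormal in the sample sense
make_corr_pair <- function(r, n, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n); e <- rnorm(n)
    x <- as.numeric(scale(x))
    e <- residuals(lm(e ~ x))
    e <- as.numeric(scale(e))
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  })
}
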