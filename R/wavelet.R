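#' Quadrature-mirror filter pairs
#'
#' Returns the low-pass taps `h` (the averaging operator) and the high-pass
#' taps `g` (the differencing operator), with `g` derived from `h` by the
#' alternating-sign reversal `g[k] = (-1)^k h[L-1-k]`, so the induced
#' convolution-decimation transform is orthonormal.
#'
#' @param name `"haar"` or `"db4"` (4-tap Daubechies, the default mother
#'   wavelet of the pipeline).
#' @return An object of class `filter_pair` with elements `h`, `g`, `name`.
#' @export
filter_pair <- function(name = c("db4", "haar")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = rep(1 / sqrt(2), 2),
    db4  = c((1 + sqrt(3)), (3 + sqrt(3)), (3 - sqrt(3)),
             (1 - sqrt(3))) / (4 * sqrt(2)))
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  structure(list(h = h, g = g, name = name), class = "filter_pair")
}

check_filter <- function(filt) {
  if (!inherits(filt, "filter_pair")) stop("not a filter_pair")
  ok <- abs(sum(filt$h^2) - 1) < 1e-10 &&
    abs(sum(filt$h * filt$g)) < 1e-10
  if (!ok) stop("non-orthonormal filter")
  invisible(filt)
}

#' Segment a recording into fixed-length analysis windows
#'
#' Windows start at samples `0, hop, 2*hop, ...` with no padding: a window is
#' emitted only if it fits entirely in the recording. The defaults (2048
#' samples at 500 Hz advanced by 500 samples) give the spectrogram-style 75%
#' overlap of the per-second feature cadence.
#'
#' @param rec An `eeg_recording`.
#' @param n_win Window length in samples (power of 2).
#' @param hop Hop in samples.
#' @return A `window_set`: list with 0-based `starts`, `t_center_s`, `n_win`,
#'   `hop`, `fs`.
#' @export
segment_windows <- function(rec, n_win = 2048, hop = 500) {
  L <- length(rec$samples)
  if (hop < 1) stop("hop must be >= 1")
  if (L < n_win) stop("recording shorter than window")
  n <- (L - n_win) %/% hop + 1
  starts <- (seq_len(n) - 1L) * as.integer(hop)
  structure(list(starts = starts,
                 t_center_s = (starts + n_win / 2) / rec$fs,
                 n_win = as.integer(n_win), hop = as.integer(hop),
                 fs = rec$fs),
            class = "window_set")
}

#' Extract one window's samples
#' @param rec An `eeg_recording`.
#' @param ws A `window_set` from [segment_windows()].
#' @param i Window index (1-based).
#' @return Numeric vector of length `ws$n_win`.
#' @export
window_frame <- function(rec, ws, i) {
  rec$samples[ws$starts[i] + seq_len(ws$n_win)]
}

#' Full wavelet-packet tree of one frame
#'
#' Recursive convolution-decimation with the circular boundary convention:
#' node (L, f) has children (L+1, 2f) through `h` and (L+1, 2f+1) through
#' `g`. For orthonormal filters every level carries the frame's energy
#' exactly (Parseval).
#'
#' @param x Numeric frame whose length is a power of 2.
#' @param filt A `filter_pair`.
#' @param depth Tree depth, at most `log2(length(x))`.
#' @return A `wp_tree`: list with `coef` ((depth+1) x n matrix of level-wise
#'   coefficients), `depth`, `n`, `filter`.
#' @export
wp_full_tree <- function(x, filt, depth) {
  check_filter(filt)
  n <- length(x)
  if (bitwAnd(n, n - 1L) != 0L) stop("frame length must be a power of 2")
  if (depth > log2(n)) stop("depth too large for frame length")
  if (!all(is.finite(x))) stop("non-finite samples")
  structure(list(coef = cpp_wp_tree(as.numeric(x), filt$h, filt$g,
                                    as.integer(depth)),
                 depth = as.integer(depth), n = n, filter = filt),
            class = "wp_tree")
}

#' Coefficient block of one tree node
#' @param tree A `wp_tree`.
#' @param level Level index (0 = root).
#' @param f Frequency (node) index at that level, `0 .. 2^level - 1`.
#' @return Numeric vector of length `n / 2^level`.
#' @export
tree_node <- function(tree, level, f) {
  m <- tree$n / 2^level
  tree$coef[level + 1L, f * m + seq_len(m)]
}

node_cost <- function(block, cost, norm2) {
  if (cost == "shannon_entropy") {
    p <- block^2 / norm2
    p <- p[p > 0]
    -sum(p * log(p))
  } else {                         # log_energy
    c2 <- block^2
    sum(log(pmax(c2, 1e-300)))
  }
}

#' Best-basis selection (bottom-up dynamic program)
#'
#' Chooses, among all prunings of the packet tree, the orthonormal node cover
#' minimizing an additive information cost. Coefficients are normalized by
#' the frame energy once so the Shannon entropy cost is additive across
#' nodes.
#'
#' @param tree A `wp_tree`.
#' @param cost `"shannon_entropy"` (default) or `"log_energy"`.
#' @return Data frame with columns `level`, `f` forming a disjoint cover of
#'   the frequency axis; attribute `"cost"` holds the attained cost.
#' @export
select_best_basis <- function(tree, cost = c("shannon_entropy",
                                             "log_energy")) {
  cost <- match.arg(cost)
  D <- tree$depth
  norm2 <- sum(tree$coef[1L, ]^2)
  if (norm2 == 0) norm2 <- 1
  # best[[L]][f+1]: minimal cost of covering node (L, f); keep[[L]][f+1]: TRUE
  # if the node itself is kept rather than split.
  best <- vector("list", D + 1L)
  keep <- vector("list", D + 1L)
  for (L in D:0) {
    nf <- 2^L
    best[[L + 1L]] <- numeric(nf)
    keep[[L + 1L]] <- logical(nf)
    for (f in 0:(nf - 1L)) {
      own <- node_cost(tree_node(tree, L, f), cost, norm2)
      if (L == D) {
        best[[L + 1L]][f + 1L] <- own
        keep[[L + 1L]][f + 1L] <- TRUE
      } else {
        ch <- best[[L + 2L]][2 * f + 1L] + best[[L + 2L]][2 * f + 2L]
        if (own <= ch) {
          best[[L + 1L]][f + 1L] <- own
          keep[[L + 1L]][f + 1L] <- TRUE
        } else {
          best[[L + 1L]][f + 1L] <- ch
        }
      }
    }
  }
  sel_level <- integer(0); sel_f <- integer(0)
  expand <- function(L, f) {
    if (keep[[L + 1L]][f + 1L]) {
      sel_level <<- c(sel_level, L); sel_f <<- c(sel_f, f)
    } else {
      expand(L + 1L, 2L * f)
      expand(L + 1L, 2L * f + 1L)
    }
  }
  expand(0L, 0L)
  out <- data.frame(level = sel_level, f = sel_f)
  attr(out, "cost") <- best[[1L]][1L]
  out
}

#' Hard-threshold denoising of wavelet-packet coefficients
#'
#' Coefficients with `|c| < tau` are zeroed. Under the `"universal"` rule
#' `tau = sigma_hat * sqrt(2 log n)` with `sigma_hat = median(|d|)/0.6745`
#' estimated from the finest-scale high-pass block (node (1, 1) for a
#' `wp_tree`; the vector itself for plain numeric input).
#'
#' @param coeffs A `wp_tree` or numeric vector of coefficients.
#' @param threshold_rule `"universal"` or `"fixed"`.
#' @param tau Threshold used when `threshold_rule = "fixed"`.
#' @return Object of the same shape with sub-threshold coefficients zeroed
#'   and attribute `"tau"`.
#' @export
prune_denoise <- function(coeffs, threshold_rule = c("universal", "fixed"),
                          tau = 0) {
  threshold_rule <- match.arg(threshold_rule)
  if (inherits(coeffs, "wp_tree")) {
    if (threshold_rule == "universal") {
      d1 <- tree_node(coeffs, 1L, 1L)
      sigma <- stats::median(abs(d1)) / 0.6745
      tau <- sigma * sqrt(2 * log(coeffs$n))
    }
    out <- coeffs
    ck <- out$coef
    ck[-1L, ][abs(ck[-1L, ]) < tau] <- 0   # root row left as the raw frame
    out$coef <- ck
    attr(out, "tau") <- tau
    return(out)
  }
  x <- as.numeric(coeffs)
  if (length(x) == 0L) stop("empty coefficient set")
  if (!all(is.finite(x))) stop("coefficients must be finite")
  if (threshold_rule == "universal") {
    sigma <- stats::median(abs(x)) / 0.6745
    tau <- sigma * sqrt(2 * log(length(x)))
  }
  x[abs(x) < tau] <- 0
  attr(x, "tau") <- tau
  x
}

# Synthesize the length-n signal whose packet coefficients are `block` in
# node (level, f) and zero elsewhere (cover completed with zero siblings).
node_to_signal <- function(block, level, f, filt) {
  x <- block
  for (L in level:1) {
    zero <- numeric(length(x))
    x <- if (f %% 2 == 0) cpp_wp_merge(x, zero, filt$h, filt$g)
         else cpp_wp_merge(zero, x, filt$h, filt$g)
    f <- f %/% 2
  }
  x
}

#' Synthesize a single wavelet-packet atom waveform
#' @param n Frame length (power of 2).
#' @param filt A `filter_pair`.
#' @param level,f Node coordinates.
#' @param p Translation index within the node (default: center).
#' @return Unit-norm numeric vector of length `n`.
#' @export
wp_atom <- function(n, filt, level, f, p = NULL) {
  m <- n / 2^level
  if (is.null(p)) p <- m %/% 2
  block <- numeric(m)
  block[p + 1L] <- 1
  w <- node_to_signal(block, level, f, filt)
  w / sqrt(sum(w^2))
}

#' Reconstruct a frame from tree coefficients
#'
#' Inverse convolution-decimation. With `basis = NULL` the full deepest level
#' is inverted; otherwise `basis` must be a disjoint cover (as returned by
#' [select_best_basis()]).
#'
#' @param tree A `wp_tree` (possibly pruned).
#' @param basis Optional data frame with columns `level`, `f`.
#' @return Numeric vector of length `tree$n`.
#' @export
reconstruct_window <- function(tree, basis = NULL) {
  filt <- tree$filter
  if (is.null(basis)) {
    basis <- data.frame(level = tree$depth,
                        f = 0:(2^tree$depth - 1L))
  }
  cover <- sum(1 / 2^basis$level)
  if (abs(cover - 1) > 1e-12) stop("incomplete cover")
  rec <- function(L, f) {
    hit <- which(basis$level == L & basis$f == f)
    if (length(hit)) return(tree_node(tree, L, f))
    a <- rec(L + 1L, 2L * f)
    d <- rec(L + 1L, 2L * f + 1L)
    cpp_wp_merge(a, d, filt$h, filt$g)
  }
  rec(0L, 0L)
}

all_nodes <- function(depth) {
  do.call(rbind, lapply(1:depth, function(L)
    data.frame(level = L, f = 0:(2^L - 1L))))
}

# FFT peak frequency of a node's atom waveform (metadata for band reasoning)
node_peak_hz <- function(n, filt, level, f, fs) {
  w <- wp_atom(n, filt, level, f)
  sp <- Mod(stats::fft(w))[1:(n / 2 + 1)]
  (which.max(sp) - 1) * fs / n
}

#' Build the fixed BAF library from a corpus of recordings
#'
#' Per-window best bases over the corpus are pooled; every candidate node is
#' scored by (selection frequency) x (mean retained energy after
#' hard-threshold denoising), and the `n_atoms` top-scoring nodes - ties
#' broken by lower level, then lower frequency index - are frozen as the
#' library. Atoms are node-level aggregates: a per-window activation is the
#' retained energy summed over all translations within the node, which makes
#' the 1-s cadence translation-invariant inside the window.
#'
#' @param corpus List of `eeg_recording` objects (total duration at least
#'   `min_minutes`).
#' @param seed Integer seed recorded in the library metadata (the build is
#'   deterministic given corpus and configuration).
#' @param n_atoms Library size (121).
#' @param filt A `filter_pair`.
#' @param n_win,hop Windowing parameters.
#' @param depth Tree depth (7 admits 254 candidate nodes).
#' @param cost Best-basis cost function.
#' @param max_windows_per_rec Cap on windows scanned per recording.
#' @param min_minutes Minimum corpus duration in minutes.
#' @return A `baf_library`: data frame `atoms` (level, f, peak_hz, score) plus
#'   configuration metadata.
#' @export
build_baf_library <- function(corpus, seed = 1L, n_atoms = 121L,
                              filt = filter_pair("db4"), n_win = 2048L,
                              hop = 500L, depth = 7L,
                              cost = "shannon_entropy",
                              max_windows_per_rec = 400L,
                              min_minutes = 10) {
  if (inherits(corpus, "eeg_recording")) corpus <- list(corpus)
  total_min <- sum(vapply(corpus, duration_s, 0)) / 60
  if (total_min < min_minutes)
    stop(sprintf("corpus too short: %.1f min < %g min", total_min,
                 min_minutes))
  nodes <- all_nodes(depth)
  sel_count <- numeric(nrow(nodes))
  energy_sum <- numeric(nrow(nodes))
  n_windows <- 0L
  key <- paste0(nodes$level, ":", nodes$f)
  for (rec in corpus) {
    ws <- segment_windows(rec, n_win, hop)
    idx <- seq_along(ws$starts)
    if (length(idx) > max_windows_per_rec) {
      stride <- ceiling(length(idx) / max_windows_per_rec)
      idx <- idx[seq(1L, length(idx), by = stride)]
    }
    en <- cpp_extract_bafs(rec$samples, ws$starts[idx], as.integer(n_win),
                           filt$h, filt$g, as.integer(depth),
                           as.integer(nodes$level), as.integer(nodes$f),
                           1L, 0)
    energy_sum <- energy_sum + colSums(en)
    for (i in idx) {
      tr <- wp_full_tree(window_frame(rec, ws, i), filt, depth)
      bb <- select_best_basis(tr, cost)
      hit <- match(paste0(bb$level, ":", bb$f), key)
      sel_count[hit] <- sel_count[hit] + 1
    }
    n_windows <- n_windows + length(idx)
  }
  score <- (sel_count / n_windows) * (energy_sum / n_windows)
  if (sum(score > 0) < n_atoms)
    stop("corpus too short to populate ", n_atoms, " distinct nodes")
  ord <- order(-score, nodes$level, nodes$f)
  keep <- ord[seq_len(n_atoms)]
  atoms <- nodes[keep, , drop = FALSE]
  atoms$score <- score[keep]
  atoms$peak_hz <- vapply(seq_len(nrow(atoms)), function(i)
    node_peak_hz(n_win, filt, atoms$level[i], atoms$f[i], corpus[[1]]$fs),
    0)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, filter = filt, n_win = as.integer(n_win),
                 hop = as.integer(hop), depth = as.integer(depth),
                 fs = corpus[[1]]$fs, cost = cost, seed = as.integer(seed)),
            class = "baf_library")
}

#' @export
print.baf_library <- function(x, ...) {
  cat(sprintf("<baf_library> %d atoms, %s filter, depth %d, n_win %d @ %g Hz\n",
              nrow(x$atoms), x$filter$name, x$depth, x$n_win, x$fs))
  invisible(x)
}

#' Per-second BAF activations of a recording
#'
#' For each analysis window the packet tree is built, hard-threshold denoised
#' (universal rule by default), and each library node's activation recorded
#' as the energy (sum of squared retained coefficients) of its block.
#'
#' @param rec An `eeg_recording`.
#' @param lib A `baf_library`.
#' @param threshold_rule `"universal"`, `"fixed"`, or `"none"`.
#' @param tau Threshold when `threshold_rule = "fixed"`.
#' @param log_scale If `TRUE`, activations are reported as
#'   `10 log10(energy + 1)` (so an empty node reads 0 dB), stabilizing the
#'   heavy-tailed energy distribution for the linear feature layer.
#' @return A `baf_matrix`: numeric matrix (windows x atoms) with column names
#'   `atom_001..`, attribute `t_s` (window centers) and `lib` metadata.
#' @export
extract_bafs <- function(rec, lib, threshold_rule = "universal", tau = 0,
                         log_scale = FALSE) {
  if (abs(rec$fs - lib$fs) > 1e-9) stop("library/recording rate mismatch")
  ws <- segment_windows(rec, lib$n_win, lib$hop)
  mode <- match(threshold_rule, c("none", "universal", "fixed")) - 1L
  if (is.na(mode)) stop("unknown threshold rule")
  m <- cpp_extract_bafs(rec$samples, ws$starts, lib$n_win, lib$filter$h,
                        lib$filter$g, lib$depth,
                        as.integer(lib$atoms$level),
                        as.integer(lib$atoms$f), mode, tau)
  if (log_scale) m <- 10 * log10(pmax(m, 0) + 1)
  colnames(m) <- sprintf("atom_%03d", seq_len(nrow(lib$atoms)))
  attr(m, "t_s") <- ws$t_center_s
  attr(m, "peak_hz") <- lib$atoms$peak_hz
  class(m) <- c("baf_matrix", class(m))
  m
}

#' Flag windows contaminated by high-frequency (muscle) artifacts
#'
#' Strong EMG has higher amplitude than EEG mainly above the EEG range, so it
#' is directly observable in the high-frequency atoms: a window is flagged
#' when the summed activation of atoms with spectral peak above
#' `hf_cutoff_hz` exceeds `k` MADs above the recording median.
#'
#' @param baf A `baf_matrix`.
#' @param lib The `baf_library` used to extract it.
#' @param k Robust threshold multiplier (default 8).
#' @param hf_cutoff_hz Atoms peaking above this frequency count as
#'   high-frequency (default 45 Hz).
#' @return Logical vector, one flag per window.
#' @export
flag_artifacts <- function(baf, lib, k = 8, hf_cutoff_hz = 45) {
  if (nrow(baf) == 0L) stop("empty BAF matrix")
  hf <- which(lib$atoms$peak_hz > hf_cutoff_hz)
  if (!length(hf)) return(rep(FALSE, nrow(baf)))
  s <- rowSums(baf[, hf, drop = FALSE])
  med <- stats::median(s)
  scale <- stats::mad(s)
  if (scale == 0) return(rep(FALSE, nrow(baf)))
  s > med + k * scale
}
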