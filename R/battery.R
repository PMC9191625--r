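# Auditory detection battery: timeline generation and behavioral scoring.

#' Default battery configuration
#'
#' Resting state 120 s; detection level 1: three 90-s trials (one per
#' instrument), 3-s melodies, 5-6 instances, 10-18 s silence in between;
#' detection level 2: 1.5-s melodies, 6-8 per trial, 8-14 s silence, 2-3
#' target instances, with trials appended until the whole battery reaches
#' 18 +/- 1 min.
#'
#' @return Named list of battery parameters.
#' @export
battery_config <- function() {
  list(rs_duration = 120,
       d1_trials = 3, d1_trial_len = 90, d1_melody = 3,
       d1_gap = c(10, 18), d1_instances = c(5, 6),
       d2_melody = 1.5, d2_gap = c(8, 14), d2_melodies = c(6, 8),
       d2_targets = c(2, 3),
       lead_in = 5, lead_out = 5,
       total_range = c(1020, 1140),
       instruments = c("violin", "trumpet", "flute"))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# melody onsets inside one trial: lead-in, then inter-melody gaps drawn
# uniformly from `gap`; rejection keeps the trial inside `limit` seconds.
draw_trial_onsets <- function(n_choices, melody, gap, lead_in, limit) {
  for (try in 1:200) {
    n <- if (length(n_choices) > 1) sample(n_choices, 1) else n_choices
    gaps <- stats::runif(n - 1, gap[1], gap[2])
    span <- lead_in + n * melody + sum(gaps)
    if (is.null(limit) || span <= limit) {
      onsets <- lead_in + cumsum(c(0, gaps + melody))
      return(list(onsets = onsets, span = span))
    }
  }
  stop("infeasible config: melodies do not fit in the trial")
}

#' Generate the auditory battery timeline
#'
#' Deterministic given `seed`. The resting-state block precedes the two
#' detection levels; all schedule invariants of [battery_config()] hold by
#' construction.
#'
#' @param seed Integer seed.
#' @param config Battery configuration (default [battery_config()]).
#' @return A `battery_schedule`: an [event_list()] with melody, instruction
#'   and block-start events; attribute `"blocks"` summarizes the trials.
#' @export
generate_schedule <- function(seed = 1L, config = battery_config()) {
  cfg <- config
  if (cfg$d1_melody + cfg$d1_gap[1] <= 0 ||
      cfg$lead_in + min(cfg$d1_instances) * cfg$d1_melody +
        (min(cfg$d1_instances) - 1) * cfg$d1_gap[1] > cfg$d1_trial_len)
    stop("infeasible config")
  with_seed(seed, {
    ev <- list()
    blocks <- list()
    add <- function(onset, dur, kind, instr, target, level)
      ev[[length(ev) + 1L]] <<- data.frame(
        onset_s = onset, duration_s = dur, kind = kind, instrument = instr,
        is_target = target, task_level = level)
    add(0, cfg$rs_duration, "block_start", "none", FALSE, "RS")
    t0 <- cfg$rs_duration
    # --- detection level 1: one instrument per 90-s trial, all targets
    for (i in seq_len(cfg$d1_trials)) {
      instr <- cfg$instruments[(i - 1) %% 3 + 1]
      add(t0, cfg$d1_trial_len, "block_start", instr, FALSE, "D1")
      add(t0, 2, "instruction", instr, FALSE, "D1")
      tr <- draw_trial_onsets(cfg$d1_instances, cfg$d1_melody, cfg$d1_gap,
                              cfg$lead_in, cfg$d1_trial_len)
      for (on in tr$onsets)
        add(t0 + on, cfg$d1_melody, "melody", instr, TRUE, "D1")
      blocks[[length(blocks) + 1L]] <- data.frame(
        level = "D1", start = t0, dur = cfg$d1_trial_len, instrument = instr)
      t0 <- t0 + cfg$d1_trial_len
    }
    # --- detection level 2: mixed instruments, click only for the target
    repeat {
      if (t0 >= cfg$total_range[1]) break
      instr <- cfg$instruments[(length(blocks) - cfg$d1_trials) %% 3 + 1]
      tr <- draw_trial_onsets(seq(cfg$d2_melodies[1], cfg$d2_melodies[2]),
                              cfg$d2_melody, cfg$d2_gap, cfg$lead_in, NULL)
      n <- length(tr$onsets)
      ntar <- sample(seq(cfg$d2_targets[1], cfg$d2_targets[2]), 1)
      tpos <- sort(sample(n, ntar))
      others <- setdiff(cfg$instruments, instr)
      dur <- tr$span + cfg$lead_out
      add(t0, dur, "block_start", instr, FALSE, "D2")
      add(t0, 2, "instruction", instr, FALSE, "D2")
      for (j in seq_len(n)) {
        tgt <- j %in% tpos
        add(t0 + tr$onsets[j], cfg$d2_melody, "melody",
            if (tgt) instr else sample(others, 1), tgt, "D2")
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        level = "D2", start = t0, dur = dur, instrument = instr)
      t0 <- t0 + dur
    }
    out <- event_list(do.call(rbind, ev))
    attr(out, "blocks") <- do.call(rbind, blocks)
    attr(out, "total_s") <- t0
    attr(out, "config") <- cfg
    class(out) <- c("battery_schedule", class(out))
    out
  })
}

#' Task level as a function of time
#' @param sched A `battery_schedule`.
#' @param t_s Times in seconds.
#' @return Character vector (`"RS"`, `"D1"`, `"D2"`, or `NA` past the end).
#' @export
task_level_at <- function(sched, t_s) {
  blocks <- attr(sched, "blocks")
  cfg <- attr(sched, "config")
  lv <- rep(NA_character_, length(t_s))
  lv[t_s >= 0 & t_s < cfg$rs_duration] <- "RS"
  for (i in seq_len(nrow(blocks))) {
    sel <- t_s >= blocks$start[i] & t_s < blocks$start[i] + blocks$dur[i]
    lv[sel] <- blocks$level[i]
  }
  lv
}

#' Score clicks against the battery schedule
#'
#' A click is a hit if it falls in `(onset, onset + response_window]` of a
#' target melody (window = melody duration + 2 s by default); only the first
#' click per target counts, later ones are ignored. Clicks matching no target
#' are false alarms. Accuracy is hits/targets and mean RT is over hits only,
#' per level.
#'
#' @param sched A `battery_schedule`.
#' @param clicks An `event_list` of click events.
#' @param extra_window Seconds added to the melody duration (default 2).
#' @return List of class `behavioral_summary`: `mean_rt_d1`, `mean_rt_d2`,
#'   `mean_rt_all`, `accuracy_d1`, `accuracy_d2`, `false_alarms`, and the
#'   per-hit table `hits`.
#' @export
score_responses <- function(sched, clicks, extra_window = 2) {
  targets <- sched[sched$kind == "melody" & sched$is_target, , drop = FALSE]
  if (nrow(targets) == 0L) stop("schedule without targets")
  ct <- sort(clicks$onset_s[clicks$kind == "click"])
  used <- logical(length(ct))
  hit <- data.frame(onset = targets$onset_s, level = targets$task_level,
                    rt = NA_real_)
  for (i in seq_len(nrow(targets))) {
    lo <- targets$onset_s[i]
    hi <- lo + targets$duration_s[i] + extra_window
    j <- which(!used & ct > lo & ct <= hi)
    if (length(j)) {
      j <- j[1]
      used[j] <- TRUE
      hit$rt[i] <- ct[j] - lo
      # later clicks on the same target are ignored, not false alarms
      dup <- which(!used & ct > lo & ct <= hi)
      used[dup] <- TRUE
    }
  }
  fa <- sum(!used)
  lvl_stats <- function(lv) {
    sub <- hit[hit$level == lv, , drop = FALSE]
    rts <- sub$rt[!is.na(sub$rt)]
    list(acc = if (nrow(sub)) length(rts) / nrow(sub) else NA_real_,
         rt = if (length(rts)) mean(rts) else NA_real_)
  }
  d1 <- lvl_stats("D1"); d2 <- lvl_stats("D2")
  all_rt <- hit$rt[!is.na(hit$rt)]
  structure(list(mean_rt_d1 = d1$rt, mean_rt_d2 = d2$rt,
                 mean_rt_all = if (length(all_rt)) mean(all_rt) else NA_real_,
                 accuracy_d1 = d1$acc, accuracy_d2 = d2$acc,
                 false_alarms = fa, hits = hit),
            class = "behavioral_summary")
}
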