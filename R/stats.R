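# Correlation, bootstrap, and mixed-model machinery of the analysis.

#' Pearson correlation with Fisher-z confidence interval
#'
#' Standard product-moment correlation; the CI comes from the Fisher
#' transform `atanh(r) +/- z_{a/2} / sqrt(n - 3)` and the p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors.
#' @param alpha Two-sided level (default 0.05).
#' @return List of class `corr_result`: `r`, `n`, `ci_lo`, `ci_hi`, `p`,
#'   `method`.
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("n < 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zc <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 3))
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(r = r, n = n, ci_lo = ci[1], ci_hi = ci[2], p = p,
                 method = "pearson"), class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("r = %.4f (n = %d, %s), 95%% CI (%.4f, %.4f), p = %.4g\n",
              x$r, x$n, x$method, x$ci_lo, x$ci_hi, x$p))
  invisible(x)
}

#' Age-partialled Pearson correlation
#'
#' Correlation of the residuals of least-squares fits of `x` on `age` and
#' `y` on `age`; the Fisher CI uses the `sqrt(n - 4)` denominator (one
#' covariate) and the p-value `t = r sqrt((n - 3)/(1 - r^2))`.
#'
#' @param x,y,age Numeric vectors.
#' @param alpha Two-sided level.
#' @return A `corr_result` with method `"partial_age"`.
#' @export
partial_corr_age <- function(x, y, age, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y) & is.finite(age)
  x <- x[ok]; y <- y[ok]; age <- age[ok]
  n <- length(x)
  if (n < 5) stop("n < 5")
  rx <- stats::lm.fit(cbind(1, age), x)$residuals
  ry <- stats::lm.fit(cbind(1, age), y)$residuals
  if (stats::sd(rx) < 1e-12 * stats::sd(x) || stats::sd(ry) < 1e-12 *
        stats::sd(y))
    stop("zero residual variance")
  r <- stats::cor(rx, ry)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zc <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 4))
  tt <- r * sqrt((n - 3) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  structure(list(r = r, n = n, ci_lo = ci[1], ci_hi = ci[2], p = p,
                 method = "partial_age"), class = "corr_result")
}

#' Compare two dependent, overlapping correlations
#'
#' Meng-Rosenthal-Rubin z-test for `r_xy` vs `r_xz` sharing the variable
#' `x`, with `r_yz` supplying the dependence correction. The CI of the
#' difference uses the paired-z construction on the Fisher scale.
#'
#' @param r_xy,r_xz The two correlations being compared (shared variable x).
#' @param r_yz Correlation between the non-shared variables.
#' @param n Sample size.
#' @param alpha Two-sided level.
#' @return List of class `corr_comparison`: `delta_r`, `z`, `p`, `ci_lo`,
#'   `ci_hi`.
#' @export
compare_dependent_corrs <- function(r_xy, r_xz, r_yz, n, alpha = 0.05) {
  rs <- c(r_xy, r_xz, r_yz)
  if (any(abs(rs[1:2]) >= 1)) stop("correlation at bound")
  R <- matrix(c(1, r_xy, r_xz, r_xy, 1, r_yz, r_xz, r_yz, 1), 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("non-PSD correlation triple")
  z1 <- atanh(r_xy); z2 <- atanh(r_xz)
  r2bar <- (r_xy^2 + r_xz^2) / 2
  f <- min((1 - r_yz) / (2 * (1 - r2bar)), 1)
  h <- (1 - f * r2bar) / (1 - r2bar)
  se_z <- sqrt(2 * (1 - r_yz) * h / (n - 3))
  z <- (z1 - z2) / se_z
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - alpha / 2)
  ci <- sort(tanh((z1 - z2) + c(-1, 1) * zc * se_z))
  structure(list(delta_r = r_xy - r_xz, z = z, p = p, ci_lo = ci[1],
                 ci_hi = ci[2]), class = "corr_comparison")
}

#' BCa bootstrap test of (partial minus unadjusted) correlation
#'
#' Statistic `theta = r_{xy.age} - r_{xy}`, case-resampled `k` times; the
#' interval applies the bias correction `z0 = Phi^-1(#{theta* < theta}/k)`
#' and the jackknife acceleration. The difference is deemed nonzero iff the
#' interval excludes 0. Deterministic per seed.
#'
#' @param x,y,age Numeric vectors.
#' @param k Number of bootstrap replicates (study default 1000).
#' @param seed Integer seed.
#' @param alpha Two-sided level.
#' @return List of class `corr_comparison` with elements `delta_r`, `ci_lo`,
#'   `ci_hi`, `p` (`NA`; the test is interval-based), `significant`,
#'   `z0`, `accel`.
#' @export
bca_bootstrap_partial_vs_unadjusted <- function(x, y, age, k = 1000,
                                                seed = 1L, alpha = 0.05) {
  n <- length(x)
  if (n < 10) stop("n < 10")
  stat <- function(idx) {
    xs <- x[idx]; ys <- y[idx]; as_ <- age[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0 || stats::sd(as_) == 0)
      return(NA_real_)
    partial_minus_plain(xs, ys, as_)
  }
  theta_hat <- stat(seq_len(n))
  boot_t <- with_seed(seed, {
    out <- numeric(k)
    for (b in seq_len(k)) {
      v <- NA_real_
      for (redraw in 1:10) {
        v <- stat(sample.int(n, n, replace = TRUE))
        if (is.finite(v)) break
      }
      if (!is.finite(v)) stop("resample degeneracy after 10 redraws")
      out[b] <- v
    }
    out
  })
  z0 <- stats::qnorm(pmin(pmax(mean(boot_t < theta_hat), 1 / (2 * k)),
                          1 - 1 / (2 * k)))
  jack <- vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)), 0)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  zc <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zc) / (1 - a * (z0 + zc)))
  ci <- stats::quantile(boot_t, adj, names = FALSE, type = 6)
  pct <- stats::quantile(boot_t, c(alpha / 2, 1 - alpha / 2),
                         names = FALSE, type = 6)
  structure(list(delta_r = theta_hat, ci_lo = ci[1], ci_hi = ci[2],
                 p = NA_real_, significant = ci[1] > 0 || ci[2] < 0,
                 z0 = z0, accel = a, k = k,
                 percentile_lo = pct[1], percentile_hi = pct[2]),
            class = "corr_comparison")
}

# partial (one covariate, via the correlation identity) minus plain r
partial_minus_plain <- function(x, y, z) {
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den < 1e-12) return(NA_real_)
  (rxy - rxz * ryz) / den - rxy
}

#' Welch two-sample t-test (raw or summary input)
#'
#' @param a,b Numeric vectors, or lists `list(mean=, sd=, n=)` for summary
#'   mode.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
welch_ttest <- function(a, b) {
  summ <- function(v) {
    if (is.list(v)) {
      if (v$n < 2) stop("n < 2")
      if (v$sd <= 0) stop("sd must be > 0")
      v
    } else {
      if (length(v) < 2) stop("n < 2")
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  A <- summ(a); B <- summ(b)
  va <- A$sd^2 / A$n; vb <- B$sd^2 / B$n
  t <- (A$mean - B$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (A$n - 1) + vb^2 / (B$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_diff = A$mean - B$mean)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, order-preserving, `>=` raw).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit the study's linear mixed model
#'
#' `value ~ group + task (+ group:task)` with group and task coded as linear
#' covariates (task RS = 0, D1 = 1, D2 = 2; group MMSE<24 = 0, MMSE24-27 =
#' 1, MMSE>=28 = 2, YOUNG = 3) and a per-participant random intercept or
#' correlated random intercept + task slope. Fits by maximum likelihood so
#' likelihood-ratio comparisons across fixed structures are valid;
#' fixed-effect t-tests use Satterthwaite degrees of freedom.
#'
#' @param data Data frame with columns `participant`, `value`, numeric
#'   `task` and (unless `group = FALSE`) numeric `group`.
#' @param formula `"additive"` or `"interaction"`.
#' @param random `"intercept"` or `"task_slope"`.
#' @param group Set `FALSE` for the per-group models (`value ~ task`).
#' @return Object of class `baf_lmm`: fixed-effect table, `logLik`, `AIC`,
#'   `BIC`, `npar`, `deviance`, `converged`, `singular`, and the underlying
#'   `lmerMod` in `$fit`.
#' @export
fit_lmm <- function(data, formula = c("additive", "interaction"),
                    random = c("intercept", "task_slope"), group = TRUE) {
  formula <- match.arg(formula)
  random <- match.arg(random)
  if (length(unique(data$participant)) < 2)
    stop("need at least 2 participants")
  if (length(unique(data$task)) < 2) stop("need at least 2 task levels")
  fe <- if (!group) "task"
        else if (formula == "additive") "group + task"
        else "group * task"
  re <- if (random == "intercept") "(1 | participant)"
        else "(task | participant)"
  fml <- stats::as.formula(paste("value ~", fe, "+", re))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = data, REML = FALSE)))
  cf <- as.data.frame(stats::coef(summary(fit)))
  names(cf) <- c("estimate", "se", "df", "t", "p")
  cf$term <- rownames(cf)
  rownames(cf) <- NULL
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(fixed = cf[, c("term", "estimate", "se", "df", "t", "p")],
                 logLik = ll, AIC = 2 * npar - 2 * ll,
                 BIC = log(nrow(data)) * npar - 2 * ll,
                 deviance = -2 * ll, npar = npar,
                 converged = conv,
                 singular = lme4::isSingular(fit),
                 formula = formula, random = random, fit = fit),
            class = "baf_lmm")
}

#' @export
print.baf_lmm <- function(x, ...) {
  cat(sprintf("<baf_lmm> %s fixed effects, %s random; logLik %.1f, AIC %.1f%s\n",
              x$formula, x$random, x$logLik, x$AIC,
              if (x$singular) " (singular)" else ""))
  print(x$fixed, digits = 4)
  invisible(x)
}

#' @export
summary.baf_lmm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Step-wise-step-up mixed-model selection
#'
#' Fits the ladder additive+intercept, interaction+intercept,
#' additive+slope, interaction+slope; the comparison table lists each step
#' against the previous row (chi-square on the deviance difference). The
#' interaction is accepted if it significantly improves fit at alpha; the
#' random task slope likewise; when the slope is retained, the interaction
#' decision is re-taken on the slope models.
#'
#' @param data Long data frame as for [fit_lmm()].
#' @param alpha LRT acceptance level (0.05).
#' @return List of class `baf_model_selection`: `chosen` (a `baf_lmm`),
#'   `table` (one row per ladder step), `interaction`, `slope`.
#' @export
select_model <- function(data, alpha = 0.05) {
  fits <- list(
    add_int = fit_lmm(data, "additive", "intercept"),
    int_int = fit_lmm(data, "interaction", "intercept"),
    add_slp = fit_lmm(data, "additive", "task_slope"),
    int_slp = fit_lmm(data, "interaction", "task_slope"))
  if (!all(vapply(fits, `[[`, TRUE, "converged")))
    warning("non-convergent step in the model ladder")
  dev <- vapply(fits, `[[`, 0, "deviance")
  chi <- c(NA, pmax(dev[-4] - dev[-1], 0))
  chi[3] <- NA   # rows 2 -> 3 are not nested; no test reported
  df <- c(NA, 1, NA, 1)
  pv <- ifelse(is.na(chi), NA, stats::pchisq(chi, df, lower.tail = FALSE))
  tab <- data.frame(
    interaction = c("Group + Task", "Group x Task", "Group + Task",
                    "Group x Task"),
    slope = c("1 | Participant", "1 | Participant", "Task | Participant",
              "Task | Participant"),
    npar = vapply(fits, `[[`, 0, "npar"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    deviance = dev, chisq = chi, df = df, p = pv)
  rownames(tab) <- NULL
  lrt <- function(small, big) {
    stats::pchisq(max(small$deviance - big$deviance, 0), 1,
                  lower.tail = FALSE)
  }
  slope_p <- lrt(fits$add_int, fits$add_slp)
  slope <- is.finite(slope_p) && slope_p < alpha
  inter_p <- if (slope) lrt(fits$add_slp, fits$int_slp)
             else lrt(fits$add_int, fits$int_int)
  inter <- is.finite(inter_p) && inter_p < alpha
  chosen <- fits[[paste0(if (inter) "int" else "add", "_",
                         if (slope) "slp" else "int")]]
  structure(list(chosen = chosen, table = tab, interaction = inter,
                 slope = slope, interaction_p = inter_p, slope_p = slope_p),
            class = "baf_model_selection")
}

#' @export
print.baf_model_selection <- function(x, ...) {
  cat(sprintf("<baf_model_selection> interaction: %s, task slope: %s\n",
              x$interaction, x$slope))
  print(x$table, digits = 6)
  invisible(x)
}

#' Pairwise post-hoc comparisons (Tukey or Bonferroni)
#'
#' All pairwise differences of group means. Tukey p-values come from the
#' studentized-range distribution with the one-way ANOVA residual variance;
#' Bonferroni p-values are `min(1, m * p_raw)` from pairwise Welch t-tests.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @param correction `"tukey"` or `"bonferroni"`.
#' @param alpha Level for the Tukey CIs.
#' @return Data frame of class `posthoc_table` with one row per contrast.
#' @export
posthoc_pairwise <- function(values, groups, correction = c("tukey",
                                                            "bonferroni"),
                             alpha = 0.05) {
  correction <- match.arg(correction)
  groups <- factor(groups)
  lev <- levels(groups)
  kg <- length(lev)
  if (kg < 2) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  N <- length(values)
  dfe <- N - kg
  mse <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2))) / dfe
  pairs <- utils::combn(kg, 2)
  m <- ncol(pairs)
  out <- data.frame(contrast = character(m), diff = numeric(m),
                    se = numeric(m), ci_lo = numeric(m), ci_hi = numeric(m),
                    p = numeric(m))
  for (i in seq_len(m)) {
    a <- pairs[2, i]; b <- pairs[1, i]   # later level minus earlier
    d <- ms[a] - ms[b]
    if (correction == "tukey") {
      se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
      q <- abs(d) / se
      p <- stats::ptukey(q, kg, dfe, lower.tail = FALSE)
      qc <- stats::qtukey(1 - alpha, kg, dfe)
      ci <- d + c(-1, 1) * qc * se
    } else {
      w <- welch_ttest(values[groups == lev[a]], values[groups == lev[b]])
      se <- abs(d / w$t)
      p <- min(1, m * w$p)
      ci <- d + c(-1, 1) * stats::qt(1 - alpha / 2, w$df) * se
    }
    out$contrast[i] <- paste(lev[a], "-", lev[b])
    out$diff[i] <- d; out$se[i] <- se
    out$ci_lo[i] <- ci[1]; out$ci_hi[i] <- ci[2]; out$p[i] <- p
  }
  attr(out, "correction") <- correction
  class(out) <- c("posthoc_table", "data.frame")
  out
}
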