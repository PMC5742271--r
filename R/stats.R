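#' Long-format table of real vs baseline profiles
#'
#' Stacks per-dyad real and baseline lag profiles into the long format
#' used by the mixed-effects layer: one recurrence-rate value per (dyad,
#' condition, lag level). Lag is coded as an unordered factor whose
#' reference level is the most negative lag (-4 s on the default grid),
#' and condition as a factor with reference `"baseline"`, so the model
#' intercept is the baseline condition at the reference lag.
#'
#' @param real,baseline lists of `lag_profile` objects on the same grid,
#'   one per dyad, in the same dyad order.
#' @param dyad_ids character vector of dyad identifiers.
#' @return data.frame of class `profile_long_table` with columns `dyad`
#'   (factor), `condition` (factor, ref `"baseline"`), `lag` (factor of
#'   lag seconds, ref = most negative), `lag_s` (numeric), `rr`.
#' @export
profile_long_table <- function(real, baseline, dyad_ids = NULL) {
  stopifnot(is.list(real), is.list(baseline),
            length(real) == length(baseline), length(real) >= 2)
  if (is.null(dyad_ids)) dyad_ids <- sprintf("dyad%02d", seq_along(real))
  grid <- real[[1]]$lag_frames
  fps <- attr(real[[1]], "fps")
  rows <- list()
  for (i in seq_along(real)) {
    for (cond in c("real", "baseline")) {
      p <- if (cond == "real") real[[i]] else baseline[[i]]
      if (!identical(p$lag_frames, grid)) {
        stop("profile grids differ across dyads/conditions")
      }
      rows[[length(rows) + 1]] <- data.frame(
        dyad = dyad_ids[i], condition = cond,
        lag_s = p$lag_ms / 1000, rr = p$rr)
    }
  }
  tab <- do.call(rbind, rows)
  tab$dyad <- factor(tab$dyad)
  tab$condition <- stats::relevel(factor(tab$condition), ref = "baseline")
  lv <- sort(unique(tab$lag_s))
  tab$lag <- factor(format_lag(tab$lag_s), levels = format_lag(lv))
  structure(tab, fps = fps, class = c("profile_long_table", "data.frame"))
}

format_lag <- function(s) sprintf("%+.2f", s)

#' Fit the null, additive, and full profile models
#'
#' Three nested linear mixed models of recurrence rate with a random
#' intercept per dyad, fitted by maximum likelihood (so likelihood-ratio
#' comparison is valid):
#'
#' * null: `rr ~ 1 + (1 | dyad)`
#' * additive: `rr ~ condition + lag + (1 | dyad)`
#' * full: `rr ~ condition * lag + (1 | dyad)`
#'
#' Lag enters as an unordered factor (each lag contrasted with the
#' reference, the most negative lag), so on the 51-level grid the full
#' model has 102 fixed-effect coefficients and 104 estimated parameters
#' including the two variance components.
#'
#' @param table a [profile_long_table()] with both conditions present and
#'   a complete (dyad x condition x lag) grid.
#' @return list with elements `null`, `additive`, `full`
#'   (`lmerTest`-fitted models) and `table`.
#' @export
fit_profile_models <- function(table) {
  stopifnot(inherits(table, "profile_long_table"))
  if (nlevels(table$dyad) < 2) stop("need at least 2 dyads")
  if (nlevels(table$condition) < 2) stop("both conditions must be present")
  cells <- table(table$condition, table$lag)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    stop("missing (condition, lag) cells: ",
         paste(rownames(cells)[miss[, 1]], colnames(cells)[miss[, 2]],
               sep = "@", collapse = ", "))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- function(fml) {
    suppressMessages(lmerTest::lmer(fml, data = table, REML = FALSE,
                                    control = ctrl))
  }
  list(null = fit(rr ~ 1 + (1 | dyad)),
       additive = fit(rr ~ condition + lag + (1 | dyad)),
       full = fit(rr ~ condition * lag + (1 | dyad)),
       table = table)
}

#' Likelihood-ratio comparison of two nested models
#'
#' chi2 = 2 (logLik_bigger - logLik_smaller), df = difference in the
#' number of estimated parameters, p from the chi-square distribution.
#' Also reports a Cramer's-V-style effect size
#' sqrt(chi2 / (N * df)) with N the number of observations.
#'
#' @param bigger,smaller ML-fitted nested models on the same data
#'   (`bigger` containing `smaller`).
#' @return list of class `model_comparison`: `chi2`, `df`, `p`,
#'   `effect_size_v`, `n_obs`, `models`.
#' @export
likelihood_ratio <- function(bigger, smaller) {
  llb <- stats::logLik(bigger)
  lls <- stats::logLik(smaller)
  df <- attr(llb, "df") - attr(lls, "df")
  nb <- stats::nobs(bigger)
  if (nb != stats::nobs(smaller)) stop("models were fitted to different data")
  if (df < 0) stop("'bigger' has fewer parameters than 'smaller'; models must be nested")
  chi2 <- max(0, 2 * (as.numeric(llb) - as.numeric(lls)))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p,
                 effect_size_v = if (df == 0) 0 else cramers_v(chi2, nb, df),
                 n_obs = nb,
                 models = c(deparse1(stats::formula(bigger)),
                            deparse1(stats::formula(smaller)))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT: chi2(%d) = %.2f, p = %.3g, V = %.3f  [%s vs %s]\n",
              x$df, x$chi2, x$p, x$effect_size_v, x$models[1], x$models[2]))
  invisible(x)
}

#' Significant window of the condition-by-lag interaction
#'
#' Extracts the interaction coefficients of the full model (one per
#' non-reference lag: real-vs-baseline contrast at that lag relative to
#' the reference lag), tests each with a t-test using Satterthwaite
#' degrees of freedom, and returns the contiguous lag range(s) where the
#' coefficients are significant at `alpha`. A per-lag paired effect size
#' d (mean over dyads of rr_real - rr_baseline at that lag, divided by
#' its SD) is reported alongside.
#'
#' @param fits result of [fit_profile_models()].
#' @param alpha significance level (default 0.05).
#' @return list with `per_lag` (data.frame `lag_s, estimate, se, t, df,
#'   p, d, significant`) and `windows` (data.frame `from_s, to_s,
#'   n_lags`; zero rows when nothing is significant).
#' @export
interaction_significance_window <- function(fits, alpha = 0.05) {
  stopifnot(is.list(fits), !is.null(fits$full))
  cf <- stats::coef(summary(fits$full))  # lmerTest: Satterthwaite df
  inter <- grepl("^conditionreal:lag", rownames(cf))
  if (!any(inter)) stop("full model has no condition-by-lag interaction terms")
  lag_lab <- sub("^conditionreal:lag", "", rownames(cf)[inter])
  lag_s <- as.numeric(lag_lab)
  tab <- fits$table
  d <- vapply(lag_lab, function(lv) {
    sub <- tab[tab$lag == lv, ]
    w <- stats::reshape(sub[, c("dyad", "condition", "rr")],
                        idvar = "dyad", timevar = "condition",
                        direction = "wide")
    diffs <- w$rr.real - w$rr.baseline
    if (stats::sd(diffs) == 0) 0 else mean(diffs) / stats::sd(diffs)
  }, numeric(1))
  per_lag <- data.frame(lag_s = lag_s,
                        estimate = cf[inter, "Estimate"],
                        se = cf[inter, "Std. Error"],
                        t = cf[inter, "t value"],
                        df = cf[inter, "df"],
                        p = cf[inter, "Pr(>|t|)"],
                        d = unname(d))
  per_lag <- per_lag[order(per_lag$lag_s), ]
  rownames(per_lag) <- NULL
  per_lag$significant <- per_lag$p < alpha
  runs <- rle(per_lag$significant)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sig <- which(runs$values)
  windows <- data.frame(from_s = per_lag$lag_s[starts[sig]],
                        to_s = per_lag$lag_s[ends[sig]],
                        n_lags = runs$lengths[sig])
  list(per_lag = per_lag, windows = windows)
}

#' Windowed t-tests of a profile against its baseline
#'
#' Divides the lag grid into `n_windows` equal windows (any remainder
#' goes to the last window) and runs one t-test per window comparing
#' real vs baseline recurrence, with Bonferroni correction: a window is
#' significant iff p < alpha / n_windows.
#'
#' Two pairing schemes are available. With a single dyad (`real` and
#' `baseline` are single profiles), rr values are paired by lag bin
#' within each window — the test for an individual recording, whose df
#' is (bins per window - 1). With a cohort (lists of profiles), each
#' dyad contributes one window-mean rr per condition and the test pairs
#' dyads, df = (n dyads - 1).
#'
#' @param real,baseline a `lag_profile` or a list of them (same grids).
#' @param n_windows number of windows (default 4).
#' @param alpha familywise significance level before correction
#'   (default 0.05).
#' @return data.frame, one row per window: `window, from_s, to_s, n, t,
#'   df, p, d, significant`; attribute `"alpha_corrected"` = alpha /
#'   n_windows.
#' @export
windowed_ttests <- function(real, baseline, n_windows = 4, alpha = 0.05) {
  if (inherits(real, "lag_profile")) real <- list(real)
  if (inherits(baseline, "lag_profile")) baseline <- list(baseline)
  stopifnot(length(real) == length(baseline), length(real) >= 1)
  grid <- real[[1]]$lag_ms / 1000
  nbins <- length(grid)
  if (n_windows < 1 || n_windows > nbins) {
    stop("n_windows must be between 1 and the number of lag bins (", nbins, ")")
  }
  size <- nbins %/% n_windows
  bounds <- c(seq(1, by = size, length.out = n_windows), nbins + 1)
  bounds[n_windows + 1] <- nbins + 1
  alpha_c <- alpha / n_windows
  by_dyad <- length(real) > 1
  rows <- lapply(seq_len(n_windows), function(w) {
    idx <- seq(bounds[w], bounds[w + 1] - 1)
    if (by_dyad) {
      rv <- vapply(real, function(p) mean(p$rr[idx]), numeric(1))
      bv <- vapply(baseline, function(p) mean(p$rr[idx]), numeric(1))
    } else {
      rv <- real[[1]]$rr[idx]
      bv <- baseline[[1]]$rr[idx]
    }
    diffs <- rv - bv
    if (stats::sd(diffs) == 0) {
      t <- if (all(diffs == 0)) 0 else NA_real_
      data.frame(window = w, from_s = grid[idx[1]], to_s = grid[idx[length(idx)]],
                 n = length(diffs), t = t, df = length(diffs) - 1L,
                 p = NA_real_, d = if (all(diffs == 0)) 0 else NA_real_,
                 significant = FALSE)
    } else {
      tt <- stats::t.test(rv, bv, paired = TRUE)
      data.frame(window = w, from_s = grid[idx[1]], to_s = grid[idx[length(idx)]],
                 n = length(diffs), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 d = mean(diffs) / stats::sd(diffs),
                 significant = tt$p.value < alpha_c)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_corrected") <- alpha_c
  out
}

#' Cramer's-V-style effect size for a likelihood-ratio chi-square
#'
#' Computed as sqrt(chi2 / (N * df)). This is one of several conventions
#' in use for converting a chi-square statistic to an effect size; it is
#' bounded by \[0, 1\] only when chi2 <= N * df.
#'
#' @param chi2 chi-square statistic.
#' @param n number of observations.
#' @param df degrees of freedom of the comparison.
#' @return numeric effect size.
#' @export
cramers_v <- function(chi2, n, df) {
  stopifnot(chi2 >= 0, n > 0, df >= 1)
  sqrt(chi2 / (n * df))
}

#' Cohen's d for paired differences
#'
#' d = mean(diff) / SD(diff). Undefined (NA, with attribute
#' `defined = FALSE`) when the differences have zero spread around a
#' nonzero mean; exactly 0 when all differences are zero.
#'
#' @param diffs numeric vector of paired differences.
#' @return numeric d.
#' @export
cohens_d_paired <- function(diffs) {
  stopifnot(length(diffs) >= 2)
  s <- stats::sd(diffs)
  if (s == 0) {
    structure(if (all(diffs == 0)) 0 else NA_real_, defined = all(diffs == 0))
  } else {
    structure(mean(diffs) / s, defined = TRUE)
  }
}
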