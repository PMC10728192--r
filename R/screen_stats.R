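#' Quadrant chemotaxis index
#'
#' CI = (animals on the odorant side - animals on the control side) / total
#' on both sides. Ranges from -1 (full repulsion) to +1 (full attraction).
#'
#' @param n_odor,n_control Non-negative counts.
#' @return CI in `[-1, 1]`; `NA` (with a warning) when both counts are zero.
#' @export
chemotaxis_index_quadrant <- function(n_odor, n_control) {
  stopifnot(n_odor >= 0, n_control >= 0)
  tot <- n_odor + n_control
  if (tot == 0) {
    warning("no animals on either side; CI undefined")
    return(NA_real_)
  }
  (n_odor - n_control) / tot
}

#' Distal-spot chemotaxis index
#'
#' CI = (animals in the odorant circle - animals in the control circle) /
#' total animals on the plate (animals outside both circles count in the
#' denominator).
#'
#' @param n_odor_circle,n_control_circle,n_total_on_plate Counts.
#' @return CI; `NA` when the plate is empty.
#' @export
chemotaxis_index_distal <- function(n_odor_circle, n_control_circle,
                                    n_total_on_plate) {
  stopifnot(n_odor_circle >= 0, n_control_circle >= 0, n_total_on_plate >= 0)
  if (n_total_on_plate == 0) return(NA_real_)
  if (n_odor_circle + n_control_circle > n_total_on_plate) {
    warning("circle counts exceed plate total; computing anyway")
  }
  (n_odor_circle - n_control_circle) / n_total_on_plate
}

#' Single-worm sector score
#'
#' The square plate is divided into six equal sectors A-F scored 3, 2, 1,
#' -1, -2, -3 (odor spot in A, control in F); the score is the sum over
#' sectors the animal visited.
#'
#' @param sectors_visited Character vector, subset of `c("A","B","C","D","E","F")`.
#' @return Integer score.
#' @export
single_worm_score <- function(sectors_visited) {
  vals <- c(A = 3L, B = 2L, C = 1L, D = -1L, E = -2L, F = -3L)
  if (length(sectors_visited) == 0L) return(0L)
  if (!all(sectors_visited %in% names(vals))) {
    stop("unknown sector label: ",
         paste(setdiff(sectors_visited, names(vals)), collapse = ", "))
  }
  sum(vals[unique(sectors_visited)])
}

#' Pathogen-lawn avoidance and occupancy
#'
#' Avoidance = animals off the pathogen lawn / total; occupancy is the
#' complement (animals on the lawn / total).
#'
#' @param n_off_lawn,n_total Counts, `n_off_lawn <= n_total`, `n_total > 0`.
#' @return Named numeric vector `c(avoidance, occupancy)`.
#' @export
lawn_indices <- function(n_off_lawn, n_total) {
  stopifnot(n_total > 0)
  if (n_off_lawn > n_total) stop("n_off_lawn exceeds n_total")
  av <- n_off_lawn / n_total
  c(avoidance = av, occupancy = 1 - av)
}

#' Relative change of a mutant index versus wild type
#'
#' (mutant - wild type) / wild type; used both for avoidance indices and
#' mean survival days.
#'
#' @param mutant_value,wt_value Numeric scalars.
#' @return Fraction; `NA` (with warning) when `wt_value` is 0.
#' @export
relative_change <- function(mutant_value, wt_value) {
  if (wt_value == 0) {
    warning("wild-type value is 0; relative change undefined")
    return(NA_real_)
  }
  (mutant_value - wt_value) / wt_value
}

#' Flag screen hits
#'
#' Two deterministic rules with strict comparisons (records exactly at a
#' threshold are never flagged): `ci_threshold` flags repellent-assay
#' records whose CI exceeds the threshold (default -0.5: animals that fail
#' to avoid); `quantile` flags extreme tails of `relative_change`.
#'
#' @param records Data frame of screen records.
#' @param rule A list: `list(type = "ci_threshold", threshold = -0.5,
#'   column = "ci")` or `list(type = "quantile", q = 0.05,
#'   tail = "low"|"high"|"both", column = "relative_change")`.
#' @return `records` restricted to flagged rows (with a `flagged` attribute
#'   giving the logical vector over the input).
#' @export
call_hits <- function(records, rule) {
  if (nrow(records) == 0L) {
    attr(records, "flagged") <- logical(0)
    return(records)
  }
  if (rule$type == "ci_threshold") {
    col <- if (is.null(rule$column)) "ci" else rule$column
    thr <- if (is.null(rule$threshold)) -0.5 else rule$threshold
    flag <- !is.na(records[[col]]) & records[[col]] > thr
  } else if (rule$type == "quantile") {
    col <- if (is.null(rule$column)) "relative_change" else rule$column
    q <- if (is.null(rule$q)) 0.05 else rule$q
    tail <- if (is.null(rule$tail)) "both" else rule$tail
    x <- records[[col]]
    lo <- quantile(x, q, na.rm = TRUE, names = FALSE)
    hi <- quantile(x, 1 - q, na.rm = TRUE, names = FALSE)
    flag <- switch(tail,
                   low = !is.na(x) & x < lo,
                   high = !is.na(x) & x > hi,
                   both = !is.na(x) & (x < lo | x > hi),
                   stop("unknown tail: ", tail))
  } else {
    stop("unknown hit rule: ", rule$type)
  }
  out <- records[flag, , drop = FALSE]
  attr(out, "flagged") <- flag
  out
}

#' Construct a time-series trace
#'
#' @param t Strictly increasing times (seconds).
#' @param y Finite values (speed or fluorescence), one per frame.
#' @param kind `"speed"` or `"fluorescence"`.
#' @param stimulus_windows List of `c(t_on, t_off)` pairs.
#' @return Object of class `trace`.
#' @export
trace <- function(t, y, kind = c("fluorescence", "speed"),
                  stimulus_windows = list()) {
  kind <- match.arg(kind)
  stopifnot(length(t) == length(y), all(diff(t) > 0), all(is.finite(y)))
  structure(list(t = t, y = y, kind = kind,
                 stimulus_windows = stimulus_windows),
            class = "trace")
}

#' Mean response over baseline and stimulus windows
#'
#' Means are taken over frames whose time falls in each half-open window
#' `[t0, t1)`; the response is their difference.
#'
#' @param trace A `trace`.
#' @param baseline_window,stimulus_window `c(t0, t1)` in seconds.
#' @return Named vector `c(baseline_mean, stimulus_mean, delta)`; `NA`s when
#'   a window contains no frames.
#' @export
interval_mean_response <- function(trace, baseline_window, stimulus_window) {
  wmean <- function(w) {
    sel <- trace$t >= w[1] & trace$t < w[2]
    if (!any(sel)) NA_real_ else mean(trace$y[sel])
  }
  b <- wmean(baseline_window)
  s <- wmean(stimulus_window)
  c(baseline_mean = b, stimulus_mean = s, delta = s - b)
}

#' Photobleaching correction of a fluorescence trace
#'
#' Fits an exponential decay `y = a * exp(-b * t)` by least squares on
#' log-transformed values over the pre- and post-stimulus windows only (by
#' default the first 30 s and the last 20 s of the recording, excluding the
#' response), with `b` constrained non-negative, and divides the trace by
#' the fitted curve. A perfectly bleach-free or bleach-only trace therefore
#' corrects to a constant 1.
#'
#' @param trace A fluorescence `trace` with positive values in the fit
#'   windows.
#' @param fit_windows List of two `c(t0, t1)` windows; `NULL` uses the first
#'   30 s and last 20 s of the recording.
#' @return Corrected `trace`; attributes `a`, `b` hold the fit and
#'   `fit_ok` is `FALSE` when the fit failed and the trace was returned
#'   uncorrected (with a warning).
#' @export
bleach_correct <- function(trace, fit_windows = NULL) {
  t0 <- trace$t[1]; t1 <- trace$t[length(trace$t)]
  if (is.null(fit_windows)) {
    fit_windows <- list(c(t0, t0 + 30), c(t1 - 20, t1 + 1e-9))
  }
  sel <- Reduce(`|`, lapply(fit_windows, function(w) {
    trace$t >= w[1] & trace$t < w[2]
  }))
  if (sum(sel) < 2L || any(trace$y[sel] <= 0)) {
    warning("bleach fit not possible; returning uncorrected trace")
    attr(trace, "fit_ok") <- FALSE
    return(trace)
  }
  fit <- lm(log(y) ~ t, data = data.frame(t = trace$t[sel], y = trace$y[sel]))
  b <- -coef(fit)[["t"]]
  if (!is.finite(b)) {
    warning("bleach fit failed; returning uncorrected trace")
    attr(trace, "fit_ok") <- FALSE
    return(trace)
  }
  if (b < 0) {  # no decay: fall back to a flat baseline
    b <- 0
    a <- exp(mean(log(trace$y[sel])))
  } else {
    a <- exp(coef(fit)[["(Intercept)"]])
  }
  if (!is.finite(a) || a <= 0) {
    warning("bleach fit failed; returning uncorrected trace")
    attr(trace, "fit_ok") <- FALSE
    return(trace)
  }
  corrected <- trace
  corrected$y <- trace$y / (a * exp(-b * trace$t))
  attr(corrected, "a") <- a
  attr(corrected, "b") <- b
  attr(corrected, "fit_ok") <- TRUE
  corrected
}

#' Fluorescence change relative to the pre-stimulus baseline
#'
#' F0 is the mean of the (bleach-corrected) trace over the 5 s before odor
#' onset; the output trace is `(y - F0) / F0`.
#'
#' @param trace A (corrected) fluorescence `trace`.
#' @param odor_onset_t Odor onset time in seconds; at least 5 s of
#'   pre-onset samples are required.
#' @return A `trace` of dF/F0 values; all-`NA` (with warning) when F0 is 0.
#' @export
delta_f_over_f0 <- function(trace, odor_onset_t) {
  if (trace$t[1] > odor_onset_t - 5) {
    stop("need at least 5 s of pre-onset samples")
  }
  sel <- trace$t >= odor_onset_t - 5 & trace$t < odor_onset_t
  f0 <- mean(trace$y[sel])
  out <- trace
  if (f0 == 0) {
    warning("F0 is 0; dF/F0 undefined")
    out$y <- rep(NA_real_, length(trace$y))
    return(out)
  }
  out$y <- (trace$y - f0) / f0
  out
}

#' Correlation of response profiles between strains
#'
#' Pairwise correlation of the per-strain response vectors across
#' conditions (pairwise-complete observations); used to spot
#' ligand/receptor mutant pairs with matching phenotypic profiles.
#'
#' @param profiles Numeric matrix, strains in rows, conditions in columns
#'   (`NA` allowed).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal; `NA` where a
#'   strain pair shares fewer than 2 complete conditions.
#' @export
response_correlation <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  n <- nrow(profiles)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(profiles), rownames(profiles))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- is.finite(profiles[i, ]) & is.finite(profiles[j, ])
      out[i, j] <- out[j, i] <- if (sum(ok) < 2L) NA_real_ else {
        suppressWarnings(cor(profiles[i, ok], profiles[j, ok], method = method))
      }
    }
  }
  out
}
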