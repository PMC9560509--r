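#' Linearize an optical-density growth curve
#'
#' Returns `ln(OD_t / OD_0)`: the natural logarithm of each reading divided
#' by the first reading, so the series starts at exactly 0 and a pure
#' exponential becomes a straight line whose slope is the specific growth
#' rate.
#'
#' @param od Optical-density readings (all > 0).
#' @return Numeric vector, same length as `od`, first element 0.
#' @examples
#' linearize_od(0.05 * exp(0.6 * (0:10) / 6))
#' @export
linearize_od <- function(od) {
  bad <- which(od <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive OD at index ", bad[1],
                 "; linearization requires OD > 0"))
  }
  log(od / od[1])
}

smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

# Max rolling OLS slope over windows of `width` consecutive points: a
# low-noise estimate of the fastest sustained growth rate, used as the
# reference the drop_fraction threshold is anchored to.  (Anchoring to the
# raw max of point slopes would bias the threshold upward by the extreme
# statistic of the slope noise.)
rolling_max_slope <- function(time, log_od, width = 8) {
  n <- length(log_od)
  width <- min(width, n)
  best <- -Inf
  for (i in seq_len(n - width + 1)) {
    idx <- i:(i + width - 1)
    tt <- time[idx]
    s <- sum((tt - mean(tt)) * (log_od[idx] - mean(log_od[idx]))) /
      sum((tt - mean(tt))^2)
    if (s > best) best <- s
  }
  best
}

#' Detect the log-phase window of a linearized growth curve
#'
#' Point-to-point slopes of the linearized series are smoothed with a
#' centered 3-point mean and compared against
#' `(1 - drop_fraction) * mu_max`, where `mu_max` is a low-noise reference
#' slope (the maximum rolling 8-point least-squares slope).  The log phase
#' is the longest contiguous run of intervals at or above that threshold --
#' a sustained decrease in slope marks the end of log phase -- with dips
#' shorter than `window` intervals tolerated inside the run.  If `mu_max`
#' never reaches `floor` the curve is declared non-growing.  All
#' parameters are explicit and returned with the result; the underlying
#' slope-decrease rule leaves them open, so these defaults are this
#' package's documented choice.
#'
#' @param time Time points (hours, strictly increasing).
#' @param log_od Linearized series from [linearize_od()].
#' @param floor Minimum reference slope (1/h) below which "no growth
#'   detected" is raised.  Default 0.05/h, chosen to sit above plate-reader
#'   noise slopes and below any real growth rate of interest.
#' @param drop_fraction Fractional slope decrease that ends log phase
#'   (default 0.10).
#' @param window Number of consecutive below-threshold intervals required
#'   to break the run (default 3).
#' @return A list: `start`, `end` (point indices of the window), `mu_max`,
#'   `params`.
#' @export
detect_log_phase <- function(time, log_od, floor = 0.05,
                             drop_fraction = 0.10, window = 3) {
  n <- length(log_od)
  if (n < 4) abort("need >= 4 points to detect a log phase")
  if (length(time) != n) abort("time and log_od lengths differ")
  if (any(diff(time) <= 0)) abort("time must be strictly increasing")
  slopes <- diff(log_od) / diff(time)
  sm <- smooth3(slopes)
  smax <- rolling_max_slope(time, log_od)
  if (smax < floor) {
    abort("no growth detected: maximum smoothed slope below floor")
  }
  threshold <- (1 - drop_fraction) * smax
  above <- sm >= threshold
  # Tolerate brief dips (<= window consecutive intervals) inside the run:
  # one outlying reading contaminates exactly `window` smoothed slopes, so
  # only a longer sustained decrease counts as the end of log phase.
  r <- rle(above)
  short_gap <- !r$values & r$lengths <= window
  interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[short_gap & interior] <- TRUE
  above <- inverse.rle(r)
  r2 <- rle(above)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1
  runs <- which(r2$values)
  best <- runs[which.max(r2$lengths[runs])]
  list(
    start = as.integer(starts[best]),
    end = as.integer(ends[best] + 1L),
    mu_max = smax,
    params = list(floor = floor, drop_fraction = drop_fraction,
                  window = window, smoothing = "centered 3-point mean")
  )
}

#' Fit the specific growth rate over a window
#'
#' Ordinary least squares of the linearized series against time over the
#' chosen window; `mu` is the slope (1/h) and `mu_sd` the standard error of
#' the slope from the fit residuals, the study's stated uncertainty for the
#' growth rate.
#'
#' @param time,log_od As in [detect_log_phase()].
#' @param window Optional list/vector with `start` and `end` point indices;
#'   when `NULL` the window is detected automatically with defaults.
#' @param ... Passed to [detect_log_phase()] when `window` is `NULL`.
#' @return An object of class `growth_fit`: list with `mu`, `mu_sd`,
#'   `window`, `n_points`, `params`, and the window data for plotting.
#' @export
fit_growth_rate <- function(time, log_od, window = NULL, ...) {
  if (is.null(window)) {
    window <- detect_log_phase(time, log_od, ...)
  }
  if (is.list(window)) {
    i0 <- window$start
    i1 <- window$end
  } else {
    if (length(window) != 2) abort("window must be list(start, end) or c(start, end)")
    i0 <- window[[1]]
    i1 <- window[[2]]
  }
  if (i1 - i0 + 1 < 3) abort("log-phase window has < 3 points")
  tt <- time[i0:i1]
  yy <- log_od[i0:i1]
  if (sd(tt) == 0) abort("degenerate window: all time points equal")
  fit <- stats::lm(yy ~ tt)
  su <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(
      mu = unname(coef(fit)[2]),
      mu_sd = unname(su[2, 2]),
      window = c(start = as.integer(i0), end = as.integer(i1)),
      n_points = length(tt),
      params = if (is.list(window)) window$params %||% list() else list(),
      time = time, log_od = log_od
    ),
    class = "growth_fit"
  )
}

#' Fit growth rates for a table of growth curves
#'
#' Tidy front end: takes long-format curves (`time_h`, `od550` plus any
#' grouping columns such as strain and condition), linearizes each curve,
#' detects its log phase and fits the specific growth rate.
#'
#' @param curves A data frame with columns `time_h` and `od550`.
#' @param ... Grouping columns (tidy-select), e.g. `strain, condition`.
#' @param floor,drop_fraction,window Passed to [detect_log_phase()].
#' @return A tibble with one row per curve: grouping columns, `mu`, `mu_sd`,
#'   `window_start`, `window_end`, `n_points`.
#' @export
fit_growth_curves <- function(curves, ..., floor = 0.05,
                              drop_fraction = 0.10, window = 3) {
  grp <- dplyr::group_by(curves, ...)
  out <- dplyr::group_modify(grp, function(d, key) {
    d <- d[order(d$time_h), ]
    lo <- linearize_od(d$od550)
    win <- detect_log_phase(d$time_h, lo, floor = floor,
                            drop_fraction = drop_fraction, window = window)
    gf <- fit_growth_rate(d$time_h, lo, window = win)
    tibble::tibble(
      mu = gf$mu, mu_sd = gf$mu_sd,
      window_start = gf$window[["start"]], window_end = gf$window[["end"]],
      n_points = gf$n_points
    )
  })
  dplyr::ungroup(out)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> mu = ", signif(x$mu, 4), " 1/h (sd ",
      signif(x$mu_sd, 3), "), window points ", x$window[["start"]], "-",
      x$window[["end"]], " (n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_growth_rate
#' @param x A `growth_fit`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = "mu", estimate = x$mu, std.error = x$mu_sd
  )
}

#' @rdname fit_growth_rate
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, mu_sd = x$mu_sd,
    window_start = x$window[["start"]], window_end = x$window[["end"]],
    n_points = x$n_points
  )
}

#' @rdname fit_growth_rate
#' @param object A `growth_fit`.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- tibble::tibble(time = object$time, log_od = object$log_od)
  i0 <- object$window[["start"]]; i1 <- object$window[["end"]]
  win <- d[i0:i1, ]
  ggplot2::ggplot(d, ggplot2::aes(x = time, y = log_od)) +
    ggplot2::annotate("rect", xmin = min(win$time), xmax = max(win$time),
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_smooth(data = win, method = "lm", formula = y ~ x,
                         se = FALSE, linewidth = 0.6, colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "ln(OD / OD0)",
                  title = sprintf("specific growth rate %.3f 1/h (sd %.3f)",
                                  object$mu, object$mu_sd)) +
    ggplot2::theme_minimal()
}
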