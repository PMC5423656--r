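# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for clock results
#'
#' `tidy()` returns the per-row content of a result as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `clock_traj`, `prc_result`, `entrainment_summary`,
#'   `scan_result`, `actogram` or `clock_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name clock-tidiers
NULL

#' @rdname clock-tidiers
#' @export
tidy.clock_traj <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time", names_to = "variable",
                      values_to = "value")
}

#' @rdname clock-tidiers
#' @export
glance.clock_traj <- function(x, ...) {
  pk <- detect_peaks(x, "Mp1")
  per <- if (nrow(pk) >= 3) estimate_period(pk) else
    tibble(period = NA_real_, period_sd = NA_real_, n_peaks = nrow(pk))
  tibble(t_end = max(x$time), transient = attr(x, "transient"),
         genotype = attr(x, "genotype") %||% NA_character_,
         rhythm = tryCatch(classify_rhythmicity(x),
                           error = function(e) NA_character_),
         period = per$period, period_sd = per$period_sd,
         n_peaks = per$n_peaks)
}

#' @rdname clock-tidiers
#' @export
tidy.prc_result <- function(x, ...) as_tibble(x)

#' @rdname clock-tidiers
#' @export
glance.prc_result <- function(x, ...) {
  tibble(genotype = x$genotype[1], amplitude = x$amplitude[1],
         gated = x$gated[1],
         max_delay = min(x$shift_h), ct_max_delay = x$ct[which.min(x$shift_h)],
         max_advance = max(x$shift_h),
         ct_max_advance = x$ct[which.max(x$shift_h)])
}

#' @rdname clock-tidiers
#' @export
tidy.entrainment_summary <- function(x, ...) as_tibble(x)

#' @rdname clock-tidiers
#' @export
glance.entrainment_summary <- function(x, ...) {
  tibble(genotype = if (nrow(x)) x$genotype[1] else NA_character_,
         light_h = if (nrow(x)) x$light_h[1] else NA_real_,
         entrained = attr(x, "entrained"),
         phase_scale = attr(x, "phase_scale"),
         per1_per2_diff_h = attr(x, "per1_per2_diff_h"))
}

#' @rdname clock-tidiers
#' @export
tidy.scan_result <- function(x, ...) as_tibble(x)

#' @rdname clock-tidiers
#' @export
glance.scan_result <- function(x, ...) {
  hopf <- attr(x, "hopf")
  tibble(parameter = attr(x, "parameter"),
         n_oscillatory = sum(x$class == "oscillatory", na.rm = TRUE),
         n_stable = sum(x$class == "stable", na.rm = TRUE),
         n_hopf = nrow(hopf),
         hopf_lower = if (nrow(hopf)) hopf[1, "lower"] else NA_real_,
         hopf_upper = if (nrow(hopf)) hopf[1, "upper"] else NA_real_,
         max_period = suppressWarnings(max(x$period, na.rm = TRUE)))
}

#' @rdname clock-tidiers
#' @export
tidy.clock_fit <- function(x, ...) {
  tibble(parameter = x$free, estimate = as.numeric(x$par[x$free]))
}

#' @rdname clock-tidiers
#' @export
glance.clock_fit <- function(x, ...) {
  tibble(cost = x$cost, generations = length(x$history) - 1,
         pop_size = x$config$pop_size, seed = x$config$seed)
}

# ---------------------------------------------------------------------------
# autoplot methods

#' Plot methods for clock results
#'
#' `autoplot()` methods give quick ggplot2 views: normalized traces for a
#' trajectory, the phase response curve, the period-vs-parameter curve of a
#' scan, and the day-by-day raster of an actogram (double-plotted when
#' `double = TRUE`).
#'
#' @param object Result object.
#' @param variables Trajectory variables to draw.
#' @param normalize Normalize each trace to [0, 1] (default TRUE).
#' @param double Double-plot the actogram raster.
#' @param ... Unused.
#' @return A ggplot object.
#' @name clock-autoplot
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_tile facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' @rdname clock-autoplot
#' @export
autoplot.clock_traj <- function(object, variables = c("Mp1", "Mp2"),
                                normalize = TRUE, ...) {
  transient <- attr(object, "transient") %||% 0
  dat <- dplyr::bind_rows(lapply(variables, function(v) {
    if (normalize) {
      n <- normalize01(object, v)
      tibble(time = n$time, value = n$value, variable = v)
    } else {
      tibble(time = object$time[object$time >= transient],
             value = object[[v]][object$time >= transient], variable = v)
    }
  }))
  ggplot(dat, aes(x = .data$time, y = .data$value,
                  colour = .data$variable)) +
    geom_line() +
    labs(x = "time (h)", y = if (normalize) "normalized level" else
      "concentration (nM)") +
    theme_minimal()
}

#' @rdname clock-autoplot
#' @export
autoplot.prc_result <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$ct, y = .data$shift_h)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "circadian time of pulse (CT, h)",
         y = "phase shift (h, advance > 0)",
         title = paste0("PRC: ", object$genotype[1],
                        if (object$gated[1]) " (gated)" else "")) +
    theme_minimal()
}

#' @rdname clock-autoplot
#' @export
autoplot.scan_result <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot(dat, aes(x = .data$value)) +
    geom_line(aes(y = .data$period), na.rm = TRUE) +
    geom_point(aes(y = .data$period, colour = .data$class), na.rm = TRUE) +
    labs(x = attr(object, "parameter"), y = "period (h)") +
    theme_minimal()
}

#' @rdname clock-autoplot
#' @export
autoplot.actogram <- function(object, double = TRUE, ...) {
  dat <- as_tibble(object)
  dat <- dat[dat$active, ]
  if (double) {
    nxt <- dat
    nxt$bin <- nxt$bin + 24
    nxt$day <- nxt$day - 1
    dat <- dplyr::bind_rows(dat, nxt)
    dat <- dat[dat$day >= min(object$day), ]
  }
  ggplot(dat, aes(x = .data$bin, y = .data$day, fill = .data$channel)) +
    geom_tile(width = attr(object, "bin_h"), height = 0.8, alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    labs(x = "time of day (h)", y = "day") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
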