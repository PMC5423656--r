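# Steady states, linear stability, one-parameter scans (Hopf bracketing)
# and period sensitivity.

#' Locate a steady state of the model
#'
#' Finds a root of the right-hand side by damped Newton iteration with a
#' finite-difference Jacobian, starting from `start` (by default the
#' long-time mean of a forward simulation, which lies inside the limit cycle
#' or at the attractor). Convergence requires the residual max-norm below
#' `tol` (nM/h).
#'
#' @param params A [clock_params()] vector.
#' @param L Constant light level.
#' @param start Optional starting state; default is derived from a
#'   simulation.
#' @param tol Residual max-norm tolerance (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return A named steady-state vector with attribute `residual`.
#' @export
find_steady_state <- function(params, L = 0, start = NULL, tol = 1e-10,
                              max_iter = 200) {
  params <- validate_clock_params(params)
  if (is.null(start)) {
    traj <- simulate_clock(params, light_ll(L), t_end = 400, transient = 200,
                           dt = 0.05)
    post <- traj[traj$time >= 200, ]
    start <- vapply(.state_names, function(v) mean(post[[v]]), 0)
  }
  y <- pmax(as.numeric(start[.state_names]), 0)
  f <- function(y) unname(clock_rhs(setNames(pmax(y, 0), .state_names),
                                    0, params, L, L))
  fy <- f(y)
  for (i in seq_len(max_iter)) {
    if (max(abs(fy)) < tol) break
    J <- .rhs_jacobian(y, params, L)
    step <- tryCatch(solve(J, fy), error = function(e) NULL)
    if (is.null(step))
      stop("singular Jacobian in steady-state search", call. = FALSE)
    lam <- 1
    repeat {
      yn <- pmax(y - lam * step, 0)
      fn <- f(yn)
      if (sum(fn^2) <= sum(fy^2) * (1 - 1e-4 * lam) + 1e-300) {
        y <- yn; fy <- fn; break
      }
      lam <- lam / 2
      if (lam < 1e-8) { y <- pmax(y - 1e-8 * step, 0); fy <- f(y); break }
    }
  }
  if (max(abs(fy)) >= tol)
    stop("steady-state search did not converge (residual ",
         signif(max(abs(fy)), 3), ")", call. = FALSE)
  structure(setNames(y, .state_names), residual = max(abs(fy)))
}

# central finite-difference Jacobian of the rhs at a state
.rhs_jacobian <- function(y, params, L, h_rel = 1e-6) {
  n <- length(y)
  J <- matrix(0, n, n)
  f <- function(y) unname(clock_rhs(setNames(y, .state_names), 0, params,
                                    L, L))
  for (j in seq_len(n)) {
    h <- max(abs(y[j]), 1e-3) * h_rel
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  dimnames(J) <- list(.state_names, .state_names)
  J
}

#' Jacobian eigenvalues at a state
#'
#' Computes the 13 eigenvalues of the central-finite-difference Jacobian
#' (relative step 1e-6), sorted by real part, largest first. At a steady
#' state the sign of the leading real part classifies stability; a complex
#' pair crossing the imaginary axis marks a Hopf bifurcation.
#'
#' @inheritParams find_steady_state
#' @param state State at which to evaluate (normally a steady state).
#' @return Complex vector of length 13, sorted by decreasing real part.
#' @export
jacobian_eigenvalues <- function(params, state, L = 0) {
  params <- validate_clock_params(params)
  y <- as.numeric(state[.state_names])
  ev <- eigen(.rhs_jacobian(y, params, L), only.values = TRUE)$values
  ev[order(-Re(ev))]
}

#' One-parameter scan with stability classification and Hopf bracketing
#'
#' For each grid value of the scanned parameter (the light level `"L"` or
#' any kinetic constant), locates the steady state, classifies it by the
#' leading Jacobian eigenvalue, and, where the steady state is unstable,
#' simulates the limit cycle to record the oscillation amplitude
#' (peak-to-trough of per1 mRNA) and period. Adjacent grid points with
#' opposite leading-real-part signs bracket a Hopf bifurcation.
#'
#' @param params A [clock_params()] vector.
#' @param parameter `"L"` or a parameter symbol.
#' @param grid Sorted numeric grid of parameter values.
#' @param L Constant light level used when scanning a kinetic parameter.
#' @param sim_t_end,sim_transient Simulation span used for amplitude/period
#'   at oscillatory points.
#' @return A `scan_result` tibble: `value`, `class` (`"stable"` /
#'   `"oscillatory"`), steady state columns `ss_*`, `eig_re`, `eig_im`,
#'   `amplitude`, `period`; Hopf brackets in attribute `hopf` (two-column
#'   matrix of bracketing values).
#' @export
scan_parameter <- function(params, parameter = "L", grid, L = 0,
                           sim_t_end = 700, sim_transient = 400) {
  params <- validate_clock_params(params)
  if (is.unsorted(grid)) stop("grid must be sorted", call. = FALSE)
  if (parameter != "L" && !parameter %in% .param_names)
    stop("unknown parameter: ", parameter, call. = FALSE)
  prev_ss <- NULL
  rows <- lapply(grid, function(val) {
    if (parameter == "L") { p <- params; Lv <- val }
    else { p <- params; p[parameter] <- val; p <- validate_clock_params(p)
           Lv <- L }
    ss <- tryCatch(
      find_steady_state(p, Lv, start = prev_ss),
      error = function(e) tryCatch(find_steady_state(p, Lv),
                                   error = function(e2) NULL))
    if (is.null(ss))
      return(tibble(value = val, class = NA_character_,
                    eig_re = NA_real_, eig_im = NA_real_,
                    amplitude = NA_real_, period = NA_real_))
    prev_ss <<- ss
    ev <- jacobian_eigenvalues(p, ss, Lv)
    lead <- ev[1]
    oscillatory <- Re(lead) > 0
    amp <- NA_real_; per <- NA_real_
    if (oscillatory) {
      traj <- simulate_clock(p, light_ll(Lv), t_end = sim_t_end,
                             transient = sim_transient, dt = 0.02)
      post <- traj[traj$time >= sim_transient, ]
      amp <- diff(range(post$Mp1))
      pk <- detect_peaks(traj, "Mp1")
      if (nrow(pk) >= 3) per <- estimate_period(pk)$period
    }
    tibble(value = val,
           class = if (oscillatory) "oscillatory" else "stable",
           eig_re = Re(lead), eig_im = Im(lead),
           amplitude = amp, period = per)
  })
  out <- dplyr::bind_rows(rows)
  sgn <- sign(out$eig_re)
  flips <- which(diff(sgn) != 0 & !is.na(diff(sgn)))
  hopf <- if (length(flips))
    cbind(lower = out$value[flips], upper = out$value[flips + 1]) else
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lower", "upper")))
  structure(out, class = c("scan_result", class(out)),
            parameter = parameter, hopf = hopf)
}

#' Period sensitivity to parameter perturbations
#'
#' Re-estimates the free-running period with each parameter perturbed to
#' `(1 - delta) x` and `(1 + delta) x` its value and reports the logarithmic
#' sensitivity `d(period) / d(ln parameter)` by the central difference.
#' Parameters whose perturbation abolishes rhythmicity are flagged.
#'
#' @param params A [clock_params()] vector.
#' @param delta Relative perturbation (default 0.05).
#' @param subset Parameter symbols to scan (default all with nonzero value).
#' @param L Constant light level.
#' @param t_end,transient Simulation settings per evaluation.
#' @param ref Variable whose peaks define the period (default per1 mRNA;
#'   use a living variable for knockouts, e.g. `"Mp2"` for the per1
#'   mutant).
#' @return A tibble: `parameter`, `value`, `period_lo`, `period_hi`,
#'   `sensitivity`, `arrhythmic_flag`.
#' @export
period_sensitivity <- function(params, delta = 0.05, subset = NULL, L = 0,
                               t_end = 800, transient = 450, ref = "Mp1") {
  params <- validate_clock_params(params)
  if (is.null(subset))
    subset <- .param_names[params[.param_names] > 0 &
                             !.param_names %in% .hill_names]
  per_of <- function(p) {
    traj <- tryCatch(
      simulate_clock(p, light_ll(L), t_end = t_end, transient = transient,
                     dt = 0.02, rtol = 1e-7, atol = 1e-9),
      error = function(e) NULL)
    if (is.null(traj)) return(NA_real_)
    pk <- detect_peaks(traj, ref)
    if (nrow(pk) < 3) return(NA_real_)
    estimate_period(pk)$period
  }
  rows <- lapply(subset, function(nm) {
    p_lo <- params; p_lo[nm] <- params[nm] * (1 - delta)
    p_hi <- params; p_hi[nm] <- params[nm] * (1 + delta)
    lo <- per_of(validate_clock_params(p_lo))
    hi <- per_of(validate_clock_params(p_hi))
    sens <- if (is.na(lo) || is.na(hi)) NA_real_
      else if (delta == 0) 0
      else (hi - lo) / (log(1 + delta) - log(1 - delta))
    tibble(parameter = nm, value = unname(params[nm]),
           period_lo = lo, period_hi = hi, sensitivity = sens,
           arrhythmic_flag = is.na(lo) || is.na(hi))
  })
  dplyr::bind_rows(rows)
}
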