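# Two-cell morning/evening (VL/DM) model coupled by VIP and AVP, splitting
# simulations and molecular actograms.

.coupled_state_names <- function() {
  c(paste0(.state_names, "m"), paste0(.state_names, "e"), "VIP", "AVP")
}

#' Parameters of the coupled VL/DM model
#'
#' Bundles the kinetic constants of the two cells with the coupling block.
#' The ventrolateral (VL, "morning") cell receives light directly and is
#' per1-loop dominant; the dorsomedial (DM, "evening") cell is per2-loop
#' dominant and receives light information only through VIP. AVP made in
#' the DM cell induces per1/per2 transcription in the VL cell with maximal
#' rate `v_cm1`; VIP made in the VL cell induces per1/per2 in the DM cell
#' with maximal rate `v_cm2` (both saturating in the neuropeptide). VIP is
#' produced at rate `k_vs2` from cytosolic PER1/2 of the VL cell plus the
#' light input, with a small basal production `beta`; AVP is produced at
#' rate `k_vs1` from cytosolic PER1/2 of the DM cell. Both are cleared
#' linearly.
#'
#' The default VL/DM kinetic sets ship with the package (calibrated to
#' free-running periods of 23.3 h and 23.4 h respectively); the default
#' coupling constants give a synchronized "unsplit" state.
#'
#' @param params_vl,params_dm [clock_params()] vectors for the two cells.
#' @param v_cm1,v_cm2 Coupling strengths (nM/h).
#' @param k_vs1,k_vs2 AVP and VIP production rates (1/h).
#' @param K_avp,K_vip Saturation constants of the induction terms (nM).
#' @param kd_avp,kd_vip Neuropeptide clearance rates (1/h).
#' @param beta Basal VIP production (nM/h).
#' @return A `coupled_params` list.
#' @export
coupled_params <- function(params_vl = clock_params_me("vl"),
                           params_dm = clock_params_me("dm"),
                           v_cm1 = 0.35, v_cm2 = 0.25,
                           k_vs1 = 0.001, k_vs2 = 0.015,
                           K_avp = 0.8, K_vip = 0.3,
                           kd_avp = 0.1, kd_vip = 2,
                           beta = 0.01) {
  vals <- c(v_cm1 = v_cm1, v_cm2 = v_cm2, k_vs1 = k_vs1, k_vs2 = k_vs2,
            K_avp = K_avp, K_vip = K_vip, kd_avp = kd_avp,
            kd_vip = kd_vip, beta = beta)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("coupling constants must be finite and >= 0", call. = FALSE)
  structure(list(vl = validate_clock_params(params_vl),
                 dm = validate_clock_params(params_dm),
                 coupling = vals),
            class = "coupled_params")
}

#' Morning/evening cell parameter sets
#'
#' Calibrated kinetic sets for the two coupled cells: `"vl"` (per1-loop
#' dominant, free-running period 23.3 h in darkness) and `"dm"` (per2-loop
#' dominant, 23.4 h).
#'
#' @param cell `"vl"` or `"dm"`.
#' @return A `clock_params` vector.
#' @export
clock_params_me <- function(cell = c("vl", "dm")) {
  cell <- match.arg(cell)
  key <- paste0("me_", cell)
  if (!exists(key, envir = .param_sets))
    stop("parameter set ", key, " not available", call. = FALSE)
  get(key, envir = .param_sets)
}

#' Right-hand side of the coupled model
#'
#' Two copies of the single-cell equations with region-specific parameters,
#' plus VIP/AVP dynamics: light and the AVP induction term enter the VL
#' per1/per2 equations; the VIP induction term enters the DM per1/per2
#' equations.
#'
#' @param state Named 28-vector (`*m` VL components, `*e` DM components,
#'   `VIP`, `AVP`).
#' @param t Time (h; unused, standard signature).
#' @param cparams A [coupled_params()] object.
#' @param light_value Light input (>= 0).
#' @return Named 28-vector of derivatives.
#' @export
coupled_rhs <- function(state, t = 0, cparams, light_value = 0) {
  stopifnot(inherits(cparams, "coupled_params"))
  nm <- .coupled_state_names()
  s <- state[nm]
  if (anyNA(s) || any(!is.finite(s)))
    stop("non-finite state component(s): ",
         paste(nm[!is.finite(s)], collapse = ", "), call. = FALSE)
  cc <- cparams$coupling
  VIP <- s[["VIP"]]; AVP <- s[["AVP"]]
  ind_m <- cc[["v_cm1"]] * AVP / (cc[["K_avp"]] + AVP)
  ind_e <- cc[["v_cm2"]] * VIP / (cc[["K_vip"]] + VIP)
  sm <- setNames(as.numeric(s[1:13]), .state_names)
  se <- setNames(as.numeric(s[14:26]), .state_names)
  dm_ <- clock_rhs(sm, t, cparams$vl, light_value + ind_m)
  de_ <- clock_rhs(se, t, cparams$dm, ind_e)
  dvip <- cc[["beta"]] +
    cc[["k_vs2"]] * (sm[["P1c"]] + sm[["P2c"]] + light_value) -
    cc[["kd_vip"]] * VIP
  davp <- cc[["k_vs1"]] * (se[["P1c"]] + se[["P2c"]]) -
    cc[["kd_avp"]] * AVP
  setNames(c(dm_, de_, dvip, davp), nm)
}

.c_parms_coupled <- function(cparams, L_seg) {
  c(unname(cparams$vl), unname(cparams$dm),
    unname(cparams$coupling[c("v_cm1", "v_cm2", "k_vs1", "k_vs2",
                              "K_avp", "K_vip", "kd_avp", "kd_vip",
                              "beta")]),
    L_seg, 0, 0)
}

#' Schedule of coupling-parameter changes
#'
#' An ordered list of switch times (in days, 24 h blocks from t = 0) with
#' coupling overrides applied from that time on; used to model the gradual
#' weakening of inter-regional coupling under constant light that produces
#' splitting.
#'
#' @param times Switch times in days, strictly increasing.
#' @param overrides List (one element per switch time) of named coupling
#'   overrides, e.g. `list(list(v_cm1 = 0.28, k_vs2 = 0.009))`.
#' @return A `coupling_schedule` object.
#' @export
coupling_schedule <- function(times = numeric(0), overrides = list()) {
  if (length(times) != length(overrides))
    stop("one override set per switch time", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("switch times must be strictly increasing", call. = FALSE)
  structure(list(times = times, overrides = overrides),
            class = "coupling_schedule")
}

#' Simulate the coupled model
#'
#' Integrates the 28-variable coupled system under a light protocol,
#' applying scheduled coupling-parameter changes; integration restarts
#' state-continuously at every schedule switch and light discontinuity.
#'
#' @param cparams A [coupled_params()] object.
#' @param schedule A [coupling_schedule()] (default none).
#' @param protocol A `light_protocol`.
#' @param t_end_days Simulation length in days.
#' @param transient_days Days regarded as transient.
#' @param vip0 Initial VIP concentration (nM, default 0.1).
#' @param init_cells Initial value for the cell-state components.
#' @param dt,rtol,atol Solver settings.
#' @return A `coupled_traj` tibble (time + 28 state columns).
#' @export
simulate_coupled <- function(cparams, schedule = coupling_schedule(),
                             protocol = light_dd(), t_end_days = 40,
                             transient_days = 10, vip0 = 0.1,
                             init_cells = 0.1, dt = 0.02,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cparams, "coupled_params"),
            inherits(schedule, "coupling_schedule"))
  t_end <- t_end_days * 24
  sw <- schedule$times * 24
  if (any(sw >= t_end)) {
    keep <- sw < t_end
    sw <- sw[keep]
  }
  nm <- .coupled_state_names()
  y <- setNames(c(rep(init_cells, 26), vip0, 0), nm)
  y[["AVP"]] <- cparams$coupling[["beta"]]
  grid <- seq(0, t_end, by = dt)
  edges <- sort(unique(c(0, sw, .light_breaks(protocol, 0, t_end), t_end)))
  cur <- cparams
  seg_rows <- vector("list", length(edges) - 1L)
  for (i in seq_len(length(edges) - 1L)) {
    t0 <- edges[i]; t1 <- edges[i + 1]
    # apply any schedule switches at or before t0
    hit <- which(abs(sw - t0) < 1e-9)
    if (length(hit)) {
      ov <- schedule$overrides[[hit]]
      cur$coupling[names(ov)] <- unlist(ov)
    }
    times <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    if (length(times) < 2) times <- c(t0, t1)
    L_seg <- light_at(protocol, t0)
    out <- try(deSolve::lsoda(y, times, func = "me_derivs",
                              parms = .c_parms_coupled(cur, L_seg),
                              dllname = "meclock", initfunc = "me_initmod",
                              rtol = rtol, atol = atol, maxsteps = 100000),
               silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(times) ||
        anyNA(out))
      stop("coupled integration failed in segment [", round(t0, 2), ", ",
           round(t1, 2), "] h", call. = FALSE)
    out <- unclass(out)
    y <- setNames(out[nrow(out), -1L], nm)
    seg_rows[[i]] <- if (i < length(edges) - 1L)
      out[-nrow(out), , drop = FALSE] else out
  }
  mat <- do.call(rbind, seg_rows)
  mat[, -1L][mat[, -1L] < 0] <- 0
  tb <- as_tibble(as.data.frame(mat))
  names(tb) <- c("time", nm)
  structure(tb, class = c("coupled_traj", class(tb)),
            transient = transient_days * 24, protocol = protocol,
            schedule = schedule, cparams = cparams)
}

#' Build a molecular actogram from a coupled trajectory
#'
#' Mimics a wheel-running actogram from the model: each channel (nuclear
#' PER1 of the VL cell, `P1nm`, for morning activity; of the DM cell,
#' `P1ne`, for evening activity) is normalized to [0, 1] over the
#' post-transient trace, and a time bin is marked active when the
#' normalized value exceeds `threshold` times the mean of the normalized
#' trace. Rows of the raster are consecutive 24 h days.
#'
#' @param traj A `coupled_traj`.
#' @param threshold Threshold factor (default 1.3).
#' @param bin_h Bin width in hours (default 0.1 h = 6 min); must divide 24.
#' @param from_day First day to include (default 0).
#' @return An `actogram` tibble: `day`, `bin` (hour-of-day of bin start),
#'   `channel` (`"M"` or `"E"`), `active` (logical).
#' @export
build_actogram <- function(traj, threshold = 1.3, bin_h = 0.1,
                           from_day = 0) {
  stopifnot(inherits(traj, "coupled_traj") || all(c("P1nm", "P1ne") %in%
                                                    names(traj)))
  if (abs(24 / bin_h - round(24 / bin_h)) > 1e-9)
    stop("bin width must divide 24 h", call. = FALSE)
  tmax <- max(traj$time)
  if (tmax - from_day * 24 < 48)
    stop("need at least 2 days of trajectory", call. = FALSE)
  keep <- traj$time >= from_day * 24
  tt <- traj$time[keep]
  chans <- list(M = traj$P1nm[keep], E = traj$P1ne[keep])
  rows <- lapply(names(chans), function(ch) {
    x <- chans[[ch]]
    rng <- range(x)
    if (diff(rng) <= 0)
      stop("constant channel ", ch, " cannot be thresholded", call. = FALSE)
    xn <- (x - rng[1]) / diff(rng)
    thr <- threshold * mean(xn)
    day <- floor(tt / 24)
    bin <- floor((tt %% 24) / bin_h) * bin_h
    agg <- stats::aggregate(xn, by = list(day = day, bin = bin), FUN = mean)
    tibble(day = agg$day, bin = agg$bin, channel = ch,
           active = agg$x > thr)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), day, bin, channel)
  structure(out, class = c("actogram", class(out)),
            threshold = threshold, bin_h = bin_h)
}

#' Phase difference between the two cells' PER1 rhythms
#'
#' Converged peak-time difference between nuclear PER1 in the VL cell
#' (`P1nm`) and in the DM cell (`P1ne`), in hours; positive when the VL
#' (morning) cell leads. Cells that do not share a common period within
#' `sync_tol` hours are flagged as desynchronized.
#'
#' @param traj A `coupled_traj`.
#' @param sync_tol Tolerance on the two channels' mean peak intervals (h).
#' @return A one-row tibble: `phase_diff_h` (signed, M lead positive),
#'   `period_m`, `period_e`, `synchronized`.
#' @export
coupled_phase_difference <- function(traj, sync_tol = 0.05) {
  transient <- attr(traj, "transient") %||% 0
  pm <- detect_peaks(traj, "P1nm", transient = transient)
  pe <- detect_peaks(traj, "P1ne", transient = transient)
  if (nrow(pm) < 3 || nrow(pe) < 3)
    return(tibble(phase_diff_h = NA_real_, period_m = NA_real_,
                  period_e = NA_real_, synchronized = FALSE))
  per_m <- mean(diff(pm$time)); per_e <- mean(diff(pe$time))
  sync <- abs(per_m - per_e) <= sync_tol
  # median signed offset of nearest E peak to each of the last few M peaks
  last_m <- utils::tail(pm$time, 5)
  offs <- vapply(last_m, function(tm) {
    d <- pe$time - tm
    d[which.min(abs(d))]
  }, 0)
  d <- stats::median(offs)
  per <- mean(c(per_m, per_e))
  d <- ((d + per / 2) %% per) - per / 2
  tibble(phase_diff_h = d, period_m = per_m, period_e = per_e,
         synchronized = sync)
}

#' Scan the steady phase difference against a coupling parameter
#'
#' Simulates the coupled model over a grid of one coupling constant
#' (`v_cm1` or `k_vs2`) under constant light and records the converged
#' VL-DM phase difference; desynchronized runs are flagged.
#'
#' @param cparams A [coupled_params()] object.
#' @param parameter `"v_cm1"` or `"k_vs2"`.
#' @param grid Sorted grid of parameter values.
#' @param L Constant light level (default 0.02).
#' @param t_end_days,transient_days Simulation span per grid point.
#' @return A tibble: `value`, `phase_diff_h`, `abs_diff_h`, `synchronized`.
#' @export
phase_difference_scan <- function(cparams, parameter = c("v_cm1", "k_vs2"),
                                  grid, L = 0.02, t_end_days = 60,
                                  transient_days = 35) {
  parameter <- match.arg(parameter)
  if (is.unsorted(grid)) stop("grid must be sorted", call. = FALSE)
  rows <- lapply(grid, function(val) {
    cp <- cparams
    cp$coupling[[parameter]] <- val
    traj <- simulate_coupled(cp, protocol = light_ll(L),
                             t_end_days = t_end_days,
                             transient_days = transient_days)
    pd <- coupled_phase_difference(traj)
    tibble(value = val, phase_diff_h = pd$phase_diff_h,
           abs_diff_h = abs(pd$phase_diff_h),
           synchronized = pd$synchronized)
  })
  dplyr::bind_rows(rows)
}
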