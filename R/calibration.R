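# Closed-loop calibration: smart initialization from a reference dataset,
# low -> high agent chaining, online termination and safety rules, and the
# brute-force (BFA) and scripted-naive ramp baselines.

#' Online calibration limits
#'
#' @param step_cap Maximum delivered stimuli per phase.
#' @param window Consecutive-unchanged convergence window.
#' @param too_high_abort Abort a phase after this many consecutive
#'   too-high reports (safety rule).
#' @param stall_window Abort a phase when the last `stall_window`
#'   delivered parameter pairs contain at most two distinct values
#'   without meeting the convergence window: the state-aliased greedy
#'   policy can enter a two-point cycle across a narrow intensity band,
#'   and further stimulation cannot break it.
#' @param naive_pw Fixed pulse width (µs) of the naive protocol's PA ramp.
#' @return A list of class `calib_limits`.
#' @export
calib_limits <- function(step_cap = 100, window = 5, too_high_abort = 3,
                         stall_window = 8, naive_pw = 200) {
  structure(as.list(environment()), class = "calib_limits")
}

#' Wrap a virtual subject as a calibration responder
#'
#' A subject interface is a total responder over the grid plus the
#' covariates used by the smart initialization: `$respond(pa, pw)` returns
#' a one-row [sensation_report()] tibble.
#'
#' @param subject A [virtual_subject()].
#' @return A list of class `subject_interface`.
#' @export
subject_interface <- function(subject) {
  structure(
    list(respond = function(pa, pw) respond(subject, pa, pw)[, 1:4],
         gender = subject$gender, nerve = subject$nerve,
         subject_id = subject$subject_id),
    class = "subject_interface")
}

#' Wrap a fitted environment as a calibration responder
#'
#' The simulated environment does not model the in-loco component, so the
#' reports carry `se = 0`.
#'
#' @param env An `env_models` object.
#' @param covariates One-row covariate tibble (see [env_step()]).
#' @return A `subject_interface`.
#' @export
env_interface <- function(env, covariates) {
  structure(
    list(respond = function(pa, pw) {
      r <- env_step(env, covariates, pa, pw)$report
      r$se <- 0L
      r
    },
    gender = covariates$gender, nerve = covariates$nerve,
    subject_id = covariates$subject_id %||% "env"),
    class = "subject_interface")
}

#' Interactive console responder
#'
#' Prompts the operator for the four report fields after every stimulus;
#' inputs are validated and re-asked on error. Only usable in interactive
#' sessions.
#'
#' @param gender,nerve Covariates of the connected subject.
#' @return A `subject_interface`.
#' @export
console_interface <- function(gender = "M", nerve = "peroneal") {
  ask <- function(prompt, valid) {
    repeat {
      x <- toupper(trimws(readline(prompt)))
      if (x %in% valid) return(x)
      cat("  please answer one of:", paste(valid, collapse = "/"), "\n")
    }
  }
  structure(
    list(respond = function(pa, pw) {
      cat(sprintf("Delivered PA = %g mA, PW = %g us\n", pa, pw))
      intensity <- ask("  intensity [NP/LOW/HIGH/TOOHIGH]: ",
                       INTENSITY_LEVELS)
      if (intensity == "NP")
        return(sensation_report("NP", "COM", "SOM", 0L))
      stype <- ask("  type [UNC/COM]: ", TYPE_LEVELS)
      location <- ask("  location [NSOM/SOM]: ", LOCATION_LEVELS)
      se <- ask("  in-loco intensity [0-10]: ", as.character(0:10))
      sensation_report(intensity, stype, location, as.integer(se))
    }, gender = gender, nerve = nerve, subject_id = "console"),
    class = "subject_interface")
}

#' Smart initialization of the low-level search
#'
#' Among dataset rows with the subject's gender and nerve labeled at the
#' low intensity, the minimum-charge (PA, PW) pair; if the subgroup has
#' no low rows, the minimum-charge low row over the whole dataset. Ties
#' go to the lower PA, then lower PW. Starting from the lowest charge
#' known to elicit the target sensation in similar subjects keeps the
#' first stimuli safe and comfortable.
#'
#' @param dataset Reference trial tibble.
#' @param gender,nerve Subject covariates.
#' @param grid A [stim_grid()].
#' @return A list with `pa` and `pw`.
#' @export
init_low_params <- function(dataset, gender, nerve, grid = stim_grid()) {
  low <- dplyr::filter(dataset, .data$intensity == "LOW")
  if (nrow(low) == 0)
    stop("reference dataset has no low-level rows", call. = FALSE)
  sub <- dplyr::filter(low, .data$gender == !!gender, .data$nerve == !!nerve)
  if (nrow(sub) == 0) sub <- low
  sub <- dplyr::arrange(sub, .data$pa_mA * .data$pw_us, .data$pa_mA,
                        .data$pw_us)
  list(pa = sub$pa_mA[1], pw = sub$pw_us[1])
}

#' Smart initialization of the high-level search
#'
#' If the low-level parameters match a recorded low-level pair in the
#' dataset exactly, the high search starts from the matching subjects'
#' paired high-level parameters (minimum charge across multiple matches);
#' with no match, it starts from the low-level parameters themselves.
#' Pairing is per dataset subject: a subject's recorded low (high) pair
#' is their minimum-charge LOW (HIGH) row.
#'
#' @param dataset Reference trial tibble.
#' @param low_params Converged low-level parameters (list `pa`, `pw`).
#' @param grid A [stim_grid()].
#' @return A list with `pa` and `pw`.
#' @export
init_high_params <- function(dataset, low_params, grid = stim_grid()) {
  assert_on_grid(low_params$pa, low_params$pw, grid)
  pairs <- dataset_level_pairs(dataset)
  hit <- dplyr::filter(pairs, .data$low_pa == low_params$pa,
                       .data$low_pw == low_params$pw,
                       !is.na(.data$high_pa))
  if (nrow(hit) == 0) return(low_params)
  hit <- dplyr::arrange(hit, .data$high_pa * .data$high_pw, .data$high_pa,
                        .data$high_pw)
  list(pa = hit$high_pa[1], pw = hit$high_pw[1])
}

# Per-subject recorded (low, high) parameter pairs of a trial dataset.
dataset_level_pairs <- function(dataset) {
  pick <- function(df) df[order(df$pa_mA * df$pw_us, df$pa_mA, df$pw_us)[1],
                          c("pa_mA", "pw_us")]
  dataset |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      low <- df[df$intensity == "LOW", ]
      high <- df[df$intensity == "HIGH", ]
      tibble::tibble(
        low_pa = if (nrow(low)) pick(low)$pa_mA else NA_real_,
        low_pw = if (nrow(low)) pick(low)$pw_us else NA_real_,
        high_pa = if (nrow(high)) pick(high)$pa_mA else NA_real_,
        high_pw = if (nrow(high)) pick(high)$pw_us else NA_real_)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$low_pa))
}

# Shared greedy phase loop. Delivers the initial parameters, then lets the
# agent modulate until the window fills, the safety rule triggers or the
# cap is hit. Returns params, flags and the delivered trace.
calibration_phase <- function(agent, subject, start, limits, grid,
                              phase_name) {
  policy <- greedy_policy(agent)
  acts <- enumerate_actions()
  n_pa <- length(grid$pa_values); n_pw <- length(grid$pw_values)
  ipa <- match(start$pa, grid$pa_values)
  ipw <- match(start$pw, grid$pw_values)
  trace <- list()
  deliver <- function(ipa, ipw) {
    rep1 <- subject$respond(grid$pa_values[ipa], grid$pw_values[ipw])
    trace[[length(trace) + 1L]] <<- dplyr::mutate(
      rep1, pa = grid$pa_values[ipa], pw = grid$pw_values[ipw],
      phase = phase_name, .before = 1)
    rep1
  }
  rep1 <- deliver(ipa, ipw)
  unchanged <- 1L; n_toohigh <- as.integer(rep1$intensity == "TOOHIGH")
  converged <- FALSE; aborted <- FALSE
  recent <- character(0)
  recent <- sprintf("%g/%g", grid$pa_values[ipa], grid$pw_values[ipw])
  while (length(trace) < limits$step_cap) {
    sid <- encode_state(rep1$intensity, rep1$stype, rep1$location)
    a <- policy[sid + 1L]
    npa <- min(max(ipa + acts$d_pa[a], 1L), n_pa)
    npw <- min(max(ipw + acts$d_pw[a] %/% 10L, 1L), n_pw)
    unchanged <- if (npa == ipa && npw == ipw) unchanged + 1L else 1L
    ipa <- npa; ipw <- npw
    rep1 <- deliver(ipa, ipw)
    n_toohigh <- if (rep1$intensity == "TOOHIGH") n_toohigh + 1L else 0L
    recent <- utils::tail(
      c(recent, sprintf("%g/%g", grid$pa_values[ipa], grid$pw_values[ipw])),
      limits$stall_window)
    if (unchanged >= limits$window) { converged <- TRUE; break }
    if (n_toohigh >= limits$too_high_abort) { aborted <- TRUE; break }
    if (length(recent) >= limits$stall_window &&
        length(unique(recent)) <= 2) { aborted <- TRUE; break }
  }
  list(params = list(pa = grid$pa_values[ipa], pw = grid$pw_values[ipw]),
       converged = converged, aborted = aborted,
       trace = dplyr::bind_rows(trace))
}

new_calibration_result <- function(method, low, high, trace) {
  structure(list(method = method,
                 low_params = low$params, high_params = high$params,
                 n_stims = nrow(trace), trace = trace,
                 converged = c(low = low$converged, high = high$converged),
                 aborted = c(low = low$aborted, high = high$aborted)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  fmt <- function(p, conv) if (is.null(p) || !conv) "not converged"
    else sprintf("PA %g mA, PW %g us (Q = %.2f uC)", p$pa, p$pw,
                 p$pa * p$pw / 1000)
  cat(sprintf("<calibration_result> %s: %d stimuli\n  low:  %s\n  high: %s\n",
              x$method, x$n_stims,
              fmt(x$low_params, x$converged[["low"]]),
              fmt(x$high_params, x$converged[["high"]])))
  invisible(x)
}

#' Tidy a calibration trace
#'
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @return The delivered-stimulus trace tibble (phase, parameters, report).
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) x$trace

#' Run the closed-loop RL calibration on one subject
#'
#' Low phase: smart initialization ([init_low_params()]) and the greedy
#' low-level agent until the parameters are unchanged for `window`
#' consecutive iterations (or a safety/step abort). High phase: chained
#' initialization ([init_high_params()]) and the high-level agent, same
#' rules. Every delivered train is counted and recorded.
#'
#' @param agent_low,agent_high Trained [train_agent()] agents.
#' @param subject A `subject_interface`.
#' @param dataset Reference trial tibble for initialization.
#' @param limits A [calib_limits()].
#' @param grid A [stim_grid()].
#' @param previous Optional `calibration_result` from an earlier session;
#'   when given, its converged parameters override the dataset
#'   initialization (day-2 re-initialization).
#' @return A `calibration_result`.
#' @export
run_calibration <- function(agent_low, agent_high, subject, dataset,
                            limits = calib_limits(), grid = stim_grid(),
                            previous = NULL) {
  start_low <- if (!is.null(previous)) previous$low_params
    else init_low_params(dataset, subject$gender, subject$nerve, grid)
  low <- calibration_phase(agent_low, subject, start_low, limits, grid,
                           "low")
  start_high <- if (!is.null(previous)) previous$high_params
    else init_high_params(dataset, low$params, grid)
  high <- calibration_phase(agent_high, subject, start_high, limits, grid,
                            "high")
  new_calibration_result("RL", low, high,
                         dplyr::bind_rows(low$trace, high$trace))
}

# Shared monotone ramp for the two baselines: deliver points in order
# until accept(report) is true or the sequence is exhausted.
ramp_until <- function(subject, points, accept, limits, grid, phase_name,
                       trace) {
  found <- NULL
  for (i in seq_len(nrow(points))) {
    if (nrow(trace) >= limits$step_cap) break
    rep1 <- subject$respond(points$pa[i], points$pw[i])
    trace <- dplyr::bind_rows(trace, dplyr::mutate(
      rep1, pa = points$pa[i], pw = points$pw[i], phase = phase_name,
      .before = 1))
    if (accept(rep1)) {
      found <- list(pa = points$pa[i], pw = points$pw[i])
      break
    }
  }
  list(found = found, trace = trace)
}

# PW-major ramp points from a start, PA incremented (PW reset to the
# start value) when the PW array is exhausted.
bfa_ramp_points <- function(start, grid) {
  pa_seq <- grid$pa_values[grid$pa_values >= start$pa]
  pts <- list()
  for (j in seq_along(pa_seq)) {
    pw_from <- if (j == 1) start$pw else start$pw
    pws <- grid$pw_values[grid$pw_values >= pw_from]
    pts[[j]] <- tibble::tibble(pa = pa_seq[j], pw = pws)
  }
  dplyr::bind_rows(pts)
}

#' Brute-force calibration baseline
#'
#' Monotonic increasing PA/PW ramps: the search starts at the lowest
#' charge that elicited a low-level sensation across the reference
#' dataset, sweeps PW upward in 10 µs steps at fixed PA and increments PA
#' by 1 mA (PW back to its start) when the PW array is exhausted. The low
#' phase accepts the first stimulus reported low-intensity and
#' somatotopic; the found point seeds the identical high-phase ramp.
#' Because the ramp never decreases, a start above the target band makes
#' the search fail — the known failure mode of this baseline.
#'
#' @param subject A `subject_interface`.
#' @param dataset Reference trial tibble.
#' @param limits A [calib_limits()].
#' @param grid A [stim_grid()].
#' @return A `calibration_result` (method `"BFA"`).
#' @export
bfa_calibrate <- function(subject, dataset, limits = calib_limits(),
                          grid = stim_grid()) {
  low_rows <- dplyr::filter(dataset, .data$intensity == "LOW") |>
    dplyr::arrange(.data$pa_mA * .data$pw_us, .data$pa_mA, .data$pw_us)
  if (nrow(low_rows) == 0)
    stop("reference dataset has no low-level rows", call. = FALSE)
  start <- list(pa = low_rows$pa_mA[1], pw = low_rows$pw_us[1])
  empty <- tibble::tibble()
  low <- ramp_until(subject, bfa_ramp_points(start, grid),
                    function(r) r$intensity == "LOW" && r$location == "SOM",
                    limits, grid, "low", empty)
  if (is.null(low$found)) {
    res <- list(params = NULL, converged = FALSE, aborted = TRUE,
                trace = low$trace)
    return(new_calibration_result("BFA", res,
                                  list(params = NULL, converged = FALSE,
                                       aborted = TRUE,
                                       trace = tibble::tibble()),
                                  low$trace))
  }
  high <- ramp_until(subject, bfa_ramp_points(low$found, grid),
                     function(r) r$intensity == "HIGH" && r$location == "SOM",
                     limits, grid, "high", empty)
  new_calibration_result(
    "BFA",
    list(params = low$found, converged = TRUE, aborted = FALSE,
         trace = low$trace),
    list(params = high$found, converged = !is.null(high$found),
         aborted = is.null(high$found), trace = high$trace),
    dplyr::bind_rows(low$trace, high$trace))
}

#' Scripted naive calibration baseline
#'
#' The fixed beginner protocol: a PA ramp at a fixed pulse width from the
#' grid minimum in 1 mA steps until a perceived somatotopic sensation,
#' then a PW ramp in 10 µs steps to find first the low and then the high
#' target (both somatotopic). Fully deterministic.
#'
#' @param subject A `subject_interface`.
#' @param limits A [calib_limits()] (`naive_pw` sets the PA-ramp pulse
#'   width).
#' @param grid A [stim_grid()].
#' @return A `calibration_result` (method `"naive"`).
#' @export
naive_calibrate <- function(subject, limits = calib_limits(),
                            grid = stim_grid()) {
  pw0 <- limits$naive_pw
  if (!pw0 %in% grid$pw_values)
    stop("naive_pw must lie on the grid", call. = FALSE)
  empty <- tibble::tibble()
  pa_pts <- tibble::tibble(pa = grid$pa_values, pw = pw0)
  som <- ramp_until(subject, pa_pts,
                    function(r) r$intensity != "NP" && r$location == "SOM",
                    limits, grid, "low", empty)
  fail <- list(params = NULL, converged = FALSE, aborted = TRUE,
               trace = tibble::tibble())
  if (is.null(som$found))
    return(new_calibration_result("naive", c(fail, list(trace = som$trace)),
                                  fail, som$trace))
  pw_pts <- tibble::tibble(pa = som$found$pa,
                           pw = grid$pw_values[grid$pw_values >= som$found$pw])
  low <- ramp_until(subject, pw_pts,
                    function(r) r$intensity == "LOW" && r$location == "SOM",
                    limits, grid, "low", som$trace)
  # the PA-ramp end point may already satisfy the low target
  last <- utils::tail(som$trace, 1)
  if (is.null(low$found) && last$intensity == "LOW" && last$location == "SOM")
    low$found <- list(pa = last$pa, pw = last$pw)
  if (is.null(low$found))
    return(new_calibration_result("naive", c(fail, list(trace = low$trace)),
                                  fail, low$trace))
  pw_pts2 <- tibble::tibble(pa = low$found$pa,
                            pw = grid$pw_values[grid$pw_values >= low$found$pw])
  high <- ramp_until(subject, pw_pts2,
                     function(r) r$intensity == "HIGH" && r$location == "SOM",
                     limits, grid, "high", empty)
  new_calibration_result(
    "naive",
    list(params = low$found, converged = TRUE, aborted = FALSE,
         trace = low$trace),
    list(params = high$found, converged = !is.null(high$found),
         aborted = is.null(high$found), trace = high$trace),
    dplyr::bind_rows(low$trace, high$trace))
}
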