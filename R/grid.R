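#' Stimulation parameter grid
#'
#' The discrete search space for TENS calibration: pulse amplitudes (PA, mA)
#' crossed with pulse widths (PW, µs). Pulse trains are biphasic,
#' charge-balanced, delivered at a fixed frequency for a fixed duration; the
#' agents only modulate PA and PW.
#'
#' Defaults: PA from 1 to 16 mA in 1 mA steps (16 values), PW from 70 to
#' 600 µs in 10 µs steps (54 values), 50 Hz, 2 s trains. The stimulator
#' hardware resolves amplitude to 0.5 mA; that finer resolution is recorded
#' as metadata only — the action space moves in 1 mA steps.
#'
#' @param pa_values Ordered pulse amplitudes (mA).
#' @param pw_values Ordered pulse widths (µs).
#' @param frequency Pulse-train frequency (Hz), fixed.
#' @param train_duration Train duration (s), fixed.
#' @param pa_resolution_hw Hardware amplitude resolution (mA), metadata.
#' @return An object of class `stim_grid`.
#' @examples
#' g <- stim_grid()
#' length(g$pa_values) # 16
#' length(g$pw_values) # 54
#' @export
stim_grid <- function(pa_values = seq(1, 16, by = 1),
                      pw_values = seq(70, 600, by = 10),
                      frequency = 50,
                      train_duration = 2,
                      pa_resolution_hw = 0.5) {
  stopifnot(length(pa_values) >= 1, length(pw_values) >= 1,
            !is.unsorted(pa_values, strictly = TRUE),
            !is.unsorted(pw_values, strictly = TRUE),
            all(pa_values > 0), all(pw_values > 0))
  pa_step <- if (length(pa_values) > 1) diff(pa_values)[1] else NA_real_
  pw_step <- if (length(pw_values) > 1) diff(pw_values)[1] else NA_real_
  structure(
    list(pa_values = as.numeric(pa_values),
         pw_values = as.numeric(pw_values),
         pa_step = pa_step, pw_step = pw_step,
         frequency = frequency, train_duration = train_duration,
         pa_resolution_hw = pa_resolution_hw),
    class = "stim_grid")
}

#' @export
print.stim_grid <- function(x, ...) {
  cat(sprintf("<stim_grid> PA: %g-%g mA (%d values), PW: %g-%g us (%d values), %g Hz, %g s trains\n",
              min(x$pa_values), max(x$pa_values), length(x$pa_values),
              min(x$pw_values), max(x$pw_values), length(x$pw_values),
              x$frequency, x$train_duration))
  invisible(x)
}

#' Check that (PA, PW) pairs lie on the grid
#'
#' @param pa,pw Numeric vectors (recycled to common length).
#' @param grid A [stim_grid()].
#' @return Logical vector.
#' @export
on_grid <- function(pa, pw, grid = stim_grid()) {
  n <- max(length(pa), length(pw))
  pa <- rep_len(pa, n); pw <- rep_len(pw, n)
  pa %in% grid$pa_values & pw %in% grid$pw_values
}

assert_on_grid <- function(pa, pw, grid) {
  ok <- on_grid(pa, pw, grid)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("stimulation parameters off grid: PA = %g mA, PW = %g us",
                 pa[min(bad, length(pa))], pw[min(bad, length(pw))]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Injected charge per phase
#'
#' Charge of one pulse phase, `Q = PA * PW`, converted from mA·µs to µC
#' (factor 1/1000). Perceived threshold is roughly proportional to this
#' charge, which is why both parameters matter for calibration.
#'
#' @inheritParams on_grid
#' @param check Validate that the parameters lie on `grid`.
#' @return Charge in µC.
#' @examples
#' charge(10, 100) # 1 µC
#' @export
charge <- function(pa, pw, grid = stim_grid(), check = TRUE) {
  if (check) assert_on_grid(pa, pw, grid)
  pa * pw / 1000
}

#' Enumerate the nine parameter-delta actions
#'
#' Each action shifts PA by -1, 0 or +1 mA and PW by -10, 0 or +10 µs.
#' The canonical order is d_pa-major, d_pw-minor, and indexes the Q-network
#' output neurons: action 1 = (-1, -10), action 5 = (0, 0) (hold), action
#' 9 = (+1, +10).
#'
#' @return A tibble with columns `action`, `d_pa`, `d_pw`.
#' @export
enumerate_actions <- function() {
  tibble::tibble(
    action = 1:9,
    d_pa = rep(c(-1, 0, 1), each = 3),
    d_pw = rep(c(-10, 0, 10), times = 3))
}

#' Apply an action to stimulation parameters
#'
#' Component-wise shift along the grid, clamped at the grid bounds; the
#' result always lies on the grid.
#'
#' @param pa,pw Current parameters (on grid).
#' @param action Action index 1-9 (see [enumerate_actions()]); vectorized.
#' @param grid A [stim_grid()].
#' @return A list with numeric vectors `pa` and `pw`.
#' @export
apply_action <- function(pa, pw, action, grid = stim_grid()) {
  assert_on_grid(pa, pw, grid)
  stopifnot(all(action %in% 1:9))
  acts <- enumerate_actions()
  pa_idx <- match(pa, grid$pa_values) + acts$d_pa[action] / grid$pa_step
  pw_idx <- match(pw, grid$pw_values) + acts$d_pw[action] / grid$pw_step
  pa_idx <- pmin(pmax(pa_idx, 1L), length(grid$pa_values))
  pw_idx <- pmin(pmax(pw_idx, 1L), length(grid$pw_values))
  list(pa = grid$pa_values[pa_idx], pw = grid$pw_values[pw_idx])
}
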