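test_that("low-level initialization picks the minimum-charge subgroup row", {
  ds <- init_dataset()
  # singleton subgroup
  expect_equal(init_low_params(ds, "F", "tibial"), list(pa = 6, pw = 150))
  # minimum charge, not minimum amplitude: 2x100 = 0.2 uC < 1x300 = 0.3 uC
  expect_equal(init_low_params(ds, "M", "peroneal"), list(pa = 2, pw = 100))
  # empty subgroup falls back to the global minimum-charge low row
  expect_equal(init_low_params(ds, "F", "sural"), list(pa = 2, pw = 100))
  no_low <- dplyr::mutate(ds, intensity = "HIGH")
  expect_error(init_low_params(no_low, "M", "peroneal"), "no low-level")
})

test_that("high-level initialization chains through the dataset pairing", {
  ds <- init_dataset()
  # subject A's recorded low pair is (2, 100); its high pair is (4, 200)
  expect_equal(init_high_params(ds, list(pa = 2, pw = 100)),
               list(pa = 4, pw = 200))
  # no exact match: the low parameters seed the high search
  expect_equal(init_high_params(ds, list(pa = 7, pw = 310)),
               list(pa = 7, pw = 310))
  # multiple matches resolve to the minimum-charge paired high row
  ds2 <- dplyr::bind_rows(ds, tibble::tibble(
    subject_id = c("D", "D"), gender = "M", weight_kg = 75,
    nerve = "peroneal", neuropathic = 0L,
    pa_mA = c(2, 3), pw_us = c(100, 200),
    intensity = c("LOW", "HIGH"), stype = "COM", location = "SOM",
    se = 0L))
  # candidates: A's (4,200) = 0.8 uC vs D's (3,200) = 0.6 uC
  expect_equal(init_high_params(ds2, list(pa = 2, pw = 100)),
               list(pa = 3, pw = 200))
})

test_that("an identity agent reproduces the initialization without drift", {
  s <- ref_subject()
  si <- subject_interface(s)
  ds <- small_trials()
  res <- run_calibration(identity_agent("low"), identity_agent("high"),
                         si, ds)
  start <- init_low_params(ds, s$gender, s$nerve)
  expect_equal(res$low_params, start)
  expect_equal(res$high_params, init_high_params(ds, start))
  expect_true(all(res$converged))
  expect_equal(res$n_stims, nrow(res$trace))
  expect_equal(res$n_stims, 10) # two phases x 5-stimulus window
  expect_true(all(on_grid(res$trace$pa, res$trace$pw)))
})

test_that("a previous result overrides the dataset initialization", {
  s <- ref_subject()
  prev <- structure(list(method = "RL",
                         low_params = list(pa = 5, pw = 300),
                         high_params = list(pa = 7, pw = 400)),
                    class = "calibration_result")
  res <- run_calibration(identity_agent("low"), identity_agent("high"),
                         subject_interface(s), small_trials(),
                         previous = prev)
  expect_equal(res$low_params, prev$low_params)
  expect_equal(res$high_params, prev$high_params)
})

# Independent replay of the brute-force ramp, written as a plain loop.
bfa_oracle <- function(subject, start, accept, grid = stim_grid()) {
  n <- 0L
  for (pa in grid$pa_values[grid$pa_values >= start$pa]) {
    for (pw in grid$pw_values[grid$pw_values >= start$pw]) {
      n <- n + 1L
      r <- respond(subject, pa, pw)
      if (accept(r)) return(list(pa = pa, pw = pw, n = n))
    }
  }
  NULL
}

test_that("BFA finds the first acceptable ramp point of a monotone subject", {
  s <- ref_subject()
  # a reference dataset whose cheapest low row starts the ramp below the
  # subject's threshold, and a cap large enough for the full ramp
  ds <- init_dataset()
  res <- bfa_calibrate(subject_interface(s), ds,
                       calib_limits(step_cap = 400))
  low_rows <- dplyr::filter(ds, intensity == "LOW") |>
    dplyr::arrange(pa_mA * pw_us, pa_mA, pw_us)
  start <- list(pa = low_rows$pa_mA[1], pw = low_rows$pw_us[1])
  olow <- bfa_oracle(s, start, function(r)
    r$intensity == "LOW" && r$location == "SOM")
  expect_equal(res$low_params, olow[c("pa", "pw")])
  ohigh <- bfa_oracle(s, olow[c("pa", "pw")], function(r)
    r$intensity == "HIGH" && r$location == "SOM")
  expect_equal(res$high_params, ohigh[c("pa", "pw")])
  expect_equal(res$n_stims, olow$n + ohigh$n)
  # the charge trace never decreases within a fixed-amplitude sweep
  tr <- res$trace
  for (grp in split(tr, paste(tr$phase, tr$pa)))
    expect_true(all(diff(grp$pa * grp$pw) >= 0))
})

test_that("BFA fails when initialized above the subject's target band", {
  s <- ref_subject()
  # a reference dataset whose cheapest low-level row is already painful
  ds <- init_dataset()
  ds$pa_mA <- 12; ds$pw_us <- 500
  res <- bfa_calibrate(subject_interface(s), ds,
                       calib_limits(step_cap = 60))
  expect_false(res$converged[["low"]])
  expect_true(res$aborted[["low"]])
})

# Independent replay of the scripted naive protocol.
naive_oracle <- function(subject, pw0, grid = stim_grid()) {
  n <- 0L
  som <- NULL
  for (pa in grid$pa_values) {
    n <- n + 1L
    r <- respond(subject, pa, pw0)
    if (r$intensity != "NP" && r$location == "SOM") {
      som <- list(pa = pa, pw = pw0); break
    }
  }
  if (is.null(som)) return(NULL)
  low <- NULL
  for (pw in grid$pw_values[grid$pw_values >= som$pw]) {
    n <- n + 1L
    r <- respond(subject, som$pa, pw)
    if (r$intensity == "LOW" && r$location == "SOM") {
      low <- list(pa = som$pa, pw = pw); break
    }
  }
  if (is.null(low)) return(NULL)
  high <- NULL
  for (pw in grid$pw_values[grid$pw_values >= low$pw]) {
    n <- n + 1L
    r <- respond(subject, low$pa, pw)
    if (r$intensity == "HIGH" && r$location == "SOM") {
      high <- list(pa = low$pa, pw = pw); break
    }
  }
  list(low = low, high = high, n = n)
}

test_that("the naive protocol is deterministic and matches its oracle", {
  s <- ref_subject()
  res <- naive_calibrate(subject_interface(s))
  res2 <- naive_calibrate(subject_interface(s))
  expect_identical(res$trace, res2$trace)
  oracle <- naive_oracle(s, calib_limits()$naive_pw)
  expect_equal(res$low_params, oracle$low)
  expect_equal(res$high_params, oracle$high)
  expect_equal(res$n_stims, oracle$n)
  expect_equal(res$n_stims, nrow(res$trace))
})
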