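# A stub responder that always answers with a fixed report.
stub_subject <- function(intensity, stype = "COM", location = "SOM",
                         se = 0L) {
  structure(list(
    respond = function(pa, pw) sensation_report(intensity, stype,
                                                location, se),
    gender = "M", nerve = "peroneal", subject_id = "stub"),
    class = "subject_interface")
}

stub_result <- function(n_stims = 10, high = list(pa = 8, pw = 300),
                        converged = TRUE) {
  structure(list(method = "RL", low_params = list(pa = 4, pw = 200),
                 high_params = high, n_stims = n_stims,
                 trace = tibble::tibble(),
                 converged = c(low = TRUE, high = converged),
                 aborted = c(low = FALSE, high = FALSE)),
            class = "calibration_result")
}

test_that("quality scoring combines the final high-level report", {
  expect_equal(score_result(stub_result(), stub_subject("HIGH")), 1.0)
  expect_equal(score_result(stub_result(),
                            stub_subject("HIGH", stype = "UNC")), 0.85)
  # reaching only a low level forfeits the intensity credit
  expect_equal(score_result(stub_result(), stub_subject("LOW")), 0.4)
  # non-converged mapping scores with I = 0
  expect_equal(score_result(stub_result(converged = FALSE),
                            stub_subject("HIGH")), 0.4)
  expect_equal(score_result(stub_result(high = NULL),
                            stub_subject("HIGH")), 0)
  expect_equal(score_result(stub_result(), stub_subject("NP")), 0)
})

test_that("proxy time scales linearly with the stimulus count", {
  expect_equal(proxy_time(stub_result(n_stims = 0)), 0)
  expect_equal(proxy_time(stub_result(n_stims = 10), 5, 15), 200)
  expect_lt(proxy_time(stub_result(n_stims = 3)),
            proxy_time(stub_result(n_stims = 4)))
  expect_error(proxy_time(stub_result(), t_stim = 0))
})

fake_records <- function(shift = 0) {
  base <- expand.grid(subject_id = sprintf("S%02d", 1:15),
                      method = c("RL", "BFA", "naive", "expert"),
                      stringsAsFactors = FALSE)
  set.seed(31)
  base$nerve <- rep(c("peroneal", "tibial", "sural"), length.out = 5)[
    as.integer(factor(base$subject_id)) %% 3 + 1]
  base$n_stims <- round(runif(nrow(base), 10, 40))
  base$n_stims[base$method == "RL"] <-
    base$n_stims[base$method == "RL"] - shift
  base$quality <- runif(nrow(base))
  base$proxy_time <- base$n_stims * 20
  tibble::tibble(base)
}

test_that("four methods give six Bonferroni-corrected pairwise tests", {
  st <- compare_methods(fake_records(), metrics = "n_stims")
  wil <- dplyr::filter(st, test == "wilcoxon_signed_rank")
  expect_equal(nrow(wil), 6)
  expect_equal(unique(wil$threshold), 0.05 / 6)
  expect_lt(abs(unique(wil$threshold) - 0.0083), 6e-4)
  expect_equal(nrow(dplyr::filter(st, test == "friedman")), 1)
  expect_equal(nrow(dplyr::filter(st, test == "ks_normality")), 4)
})

test_that("identical metric vectors yield no significant comparisons", {
  rec <- fake_records()
  rec$n_stims <- rep(rep(c(10, 20, 30), 20)[1:15], 4)
  st <- compare_methods(rec, metrics = "n_stims")
  wil <- dplyr::filter(st, test == "wilcoxon_signed_rank")
  expect_true(all(!wil$significant))
  expect_false(dplyr::filter(st, test == "friedman")$significant)
})

test_that("a uniform paired shift of 15 nerves is flagged at p < 0.0083", {
  st <- compare_methods(fake_records(shift = 50), metrics = "n_stims")
  rl_pairs <- dplyr::filter(st, test == "wilcoxon_signed_rank",
                            grepl("RL", comparison))
  expect_true(all(rl_pairs$significant))
  expect_true(all(rl_pairs$p_value < 0.0083))
})

test_that("the Wilcoxon implementation matches the exact sign-enumeration null", {
  set.seed(7)
  for (n in c(6, 9, 12)) {
    x <- round(rnorm(n, 10, 3), 3)
    y <- round(rnorm(n, 11, 3), 3)
    p_ref <- wilcoxon_exact_p(x, y)
    p_imp <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p_imp, p_ref, tolerance = 1e-12)
  }
})

test_that("the benchmark produces one record per subject and method", {
  co <- small_cohort()[1:3]
  ds <- small_trials()
  rec <- run_benchmark(co, identity_agent("low"), identity_agent("high"),
                       ds, methods = c("RL", "BFA", "naive"),
                       limits = calib_limits(step_cap = 40))
  expect_equal(nrow(rec), 9)
  expect_setequal(unique(rec$method), c("RL", "BFA", "naive"))
  expect_true(all(rec$quality >= 0 & rec$quality <= 1))
  expect_true(all(rec$n_stims == round(rec$n_stims) & rec$n_stims > 0))
  rec2 <- run_benchmark(co, identity_agent("low"), identity_agent("high"),
                        ds, methods = c("RL", "BFA", "naive"),
                        limits = calib_limits(step_cap = 40))
  expect_identical(tibble::as_tibble(rec), tibble::as_tibble(rec2))
  # summary means agree with direct recomputation
  summ <- summarize_benchmark(rec)
  m <- dplyr::filter(summ, method == "BFA", metric == "n_stims")$mean
  expect_equal(m, round(mean(rec$n_stims[rec$method == "BFA"]), 2))
})

test_that("group comparison reports Mann-Whitney statistics per method", {
  a <- fake_records(); a$charge_low <- runif(nrow(a), 0.5, 1)
  a$charge_high <- runif(nrow(a), 1, 2)
  b <- a; b$charge_low <- b$charge_low * 3; b$charge_high <- b$charge_high * 3
  out <- compare_groups(a, b)
  expect_equal(nrow(out), 2 * length(unique(a$method)))
  expect_true(all(out$mean_b > out$mean_a))
  expect_true(all(out$p_value < 0.05))
})
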