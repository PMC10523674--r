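# Helpers building small fitted environments and oracles.

# Trials whose intensity code is an exact linear function of PA.
linear_trials <- function() {
  pts <- expand.grid(pa_mA = 1:4, pw_us = c(100, 200, 300, 400))
  tibble::tibble(
    subject_id = "L", gender = "M", weight_kg = 75, nerve = "peroneal",
    neuropathic = 0L, pa_mA = pts$pa_mA, pw_us = pts$pw_us,
    intensity = INTENSITY_LEVELS[pts$pa_mA],
    stype = rep(c("UNC", "COM"), length.out = nrow(pts)),
    location = rep(c("NSOM", "SOM"), each = 2, length.out = nrow(pts)),
    se = 0L)
}

test_that("the intensity regression recovers an exact linear law", {
  env <- suppressWarnings(fit_environment(linear_trials()))
  rmse <- glance(env)$intensity_rmse
  expect_lt(rmse, 1e-10)
  pred <- predict_intensity(env, linear_trials())
  expect_equal(pred, linear_trials()$intensity)
})

test_that("continuous intensity predictions are rounded and clamped", {
  tr <- tibble::tibble(
    subject_id = "R", gender = "M", weight_kg = 75, nerve = "peroneal",
    neuropathic = 0L, pa_mA = c(1, 2, 3, 4), pw_us = 300,
    intensity = INTENSITY_LEVELS[c(1, 2, 3, 4)],
    stype = c("UNC", "COM", "UNC", "COM"),
    location = c("NSOM", "SOM", "NSOM", "SOM"), se = 0L)
  env <- suppressWarnings(fit_environment(tr)) # icode = pa - 1 exactly
  q <- function(pa) tibble::tibble(
    subject_id = "R", gender = "M", weight_kg = 75, nerve = "peroneal",
    neuropathic = 0L, pa_mA = pa, pw_us = 300)
  expect_equal(suppressWarnings(predict_intensity(env, q(3.6))), "TOOHIGH")
  expect_equal(suppressWarnings(predict_intensity(env, q(0.6))), "NP")
  expect_equal(suppressWarnings(predict_intensity(env, q(-5))), "NP")
})

test_that("single-class labels fall back to constant predictors", {
  tr <- linear_trials()
  tr$stype <- "COM"
  expect_warning(env <- fit_environment(tr), "single-class type")
  expect_equal(unique(predict_type(env, tr)), "COM")
  tr2 <- linear_trials()
  tr2$location <- "SOM"
  expect_warning(env2 <- fit_environment(tr2), "single-class location")
  expect_equal(unique(predict_location(env2, tr2)), "SOM")
})

test_that("a single 1-NN learner reproduces an exhaustive nearest-neighbour scan", {
  tr <- small_trials()[1:60, ]
  env <- fit_environment(tr, env_config(n_learners = 1, k = 1,
                                        subspace_size = 8, seed = 3))
  query <- small_trials()[61:90, ]
  pred <- predict_type(env, query)
  # oracle: brute-force nearest row in the standardized feature space
  Xtr <- env$type$train
  Xq <- tenscal:::standardize(tenscal:::env_features(query), env$center,
                              env$scale)
  for (i in seq_len(nrow(Xq))) {
    d2 <- colSums((t(Xtr) - Xq[i, ])^2)
    nn <- order(d2)[1]
    # ties in distance are broken identically only when unique
    if (sum(abs(d2 - d2[nn]) < 1e-12) == 1)
      expect_equal(pred[i], as.character(tr$stype[nn]))
  }
})

test_that("an even ensemble split is resolved to comfortable", {
  # stub environment: two 1-NN learners on orthogonal single-feature
  # subspaces voting differently for the query at the origin
  X <- rbind(c(0, 5, 0, 0, 0, 0, 0, 0),
             c(5, 0, 0, 0, 0, 0, 0, 0))
  env <- structure(list(
    center = rep(0, 8), scale = rep(1, 8),
    type = list(train = X, labels = factor(c("UNC", "COM"),
                                           levels = TYPE_LEVELS),
                subspaces = list(1L, 2L), k = 1, constant = NULL)),
    class = "env_models")
  query <- tibble::tibble(subject_id = "q", gender = "M", weight_kg = 0,
                          nerve = "peroneal", neuropathic = 0L,
                          pa_mA = 0, pw_us = 0)
  expect_equal(predict_type(env, query), "COM")
})

test_that("the GP location model matches a dense linear-algebra oracle", {
  set.seed(9)
  for (n in c(10, 30, 50)) {
    tr <- small_trials()[sample.int(nrow(small_trials()), n), ]
    cfg <- env_config(gp_length = 2, gp_noise = 1e-4, seed = 1)
    env <- suppressWarnings(fit_environment(tr, cfg))
    if (is.null(env$location$gp)) next
    query <- small_trials()[sample.int(nrow(small_trials()), 20), ]
    post <- predict_location(env, query, posterior = TRUE)
    Xtr <- env$location$train
    Xq <- tenscal:::standardize(tenscal:::env_features(query), env$center,
                                env$scale)
    oracle <- gp_oracle(Xtr, as.numeric(tr$location == "SOM"), Xq,
                        sigma_f = 1, ell = 2, noise = 1e-4)
    expect_lt(max(abs(post - pmin(pmax(oracle, 0), 1))), 1e-8)
  }
})

test_that("GP interpolation and decay behave as kernel theory predicts", {
  tr <- small_trials()[1:20, ]
  env <- fit_environment(tr, env_config(gp_noise = 1e-10, gp_length = 1))
  post <- predict_location(env, tr, posterior = TRUE)
  expect_equal(post, as.numeric(tr$location == "SOM"), tolerance = 1e-5)
  # a query far beyond every training point decays to 0 -> not somatotopic
  far <- tr[1, ]
  far$pa_mA <- 16; far$pw_us <- 600; far$weight_kg <- 500
  expect_lt(predict_location(env, far, posterior = TRUE), 0.05)
  expect_equal(predict_location(env, far), "NSOM")
})

test_that("environment steps compose the three heads deterministically", {
  env <- small_env()
  covs <- tibble::tibble(subject_id = "S", gender = "M", weight_kg = 75,
                         nerve = "peroneal", neuropathic = 0L)
  s1 <- env_step(env, covs, 4, 200)
  s2 <- env_step(env, covs, 4, 200)
  expect_identical(s1, s2)
  # a not-perceived intensity forces the collapsed state
  tab <- env_state_table(env, covs)
  grid_pts <- expand.grid(pa = stim_grid()$pa_values,
                          pw = stim_grid()$pw_values)
  ints <- predict_intensity(env, tibble::tibble(
    subject_id = "S", gender = "M", weight_kg = 75, nerve = "peroneal",
    neuropathic = 0L, pa_mA = grid_pts$pa, pw_us = grid_pts$pw))
  expect_true(all(as.vector(tab)[ints == "NP"] == 0L))
  expect_true(any(ints == "NP"))
})

test_that("refitting with the same seed reproduces the environment", {
  e1 <- fit_environment(small_trials(), env_config(seed = 8))
  e2 <- fit_environment(small_trials(), env_config(seed = 8))
  expect_identical(e1$type$subspaces, e2$type$subspaces)
  expect_identical(stats::coef(e1$intensity_model),
                   stats::coef(e2$intensity_model))
})

test_that("an environment fitted on one subject's dense trials mimics that subject", {
  s <- ref_subject()
  g <- stim_grid()
  pts <- expand.grid(pa_mA = g$pa_values,
                     pw_us = g$pw_values[seq(1, 54, by = 2)])
  rep0 <- respond(s, pts$pa_mA, pts$pw_us)
  tr <- tibble::tibble(
    subject_id = s$subject_id, gender = s$gender, weight_kg = s$weight,
    nerve = s$nerve, neuropathic = 0L, pa_mA = pts$pa_mA,
    pw_us = pts$pw_us, intensity = rep0$intensity, stype = rep0$stype,
    location = rep0$location, se = rep0$se)
  env <- suppressWarnings(fit_environment(tr))
  pred <- suppressWarnings(predict_intensity(env, tr))
  # a linear interaction plane approximating a saturating monotone
  # psychometric surface: most of the grid agrees, band edges blur
  agreement <- mean(pred == tr$intensity)
  expect_gt(agreement, 0.6)
})
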