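# Data-driven simulated environment: three predictors fitted on a trial
# dataset that stand in for a subject during offline RL training/testing.
#
# (1) intensity: ordinary least squares on the 4-level intensity code
#     {0,1,2,3} with a PA x PW interaction and subject covariates,
#     round-and-clamp decoded back to a level;
# (2) type: majority-vote ensemble of KNN classifiers, each trained on a
#     random feature subspace;
# (3) location: Gaussian-process regression on the 0/1 somatotopy label
#     with an exponential kernel, binarized at a threshold.

#' Environment configuration
#'
#' @param n_learners Number of KNN base learners in the type ensemble.
#' @param k Neighbours per learner.
#' @param subspace_size Features per learner (default `ceiling(sqrt(p))`).
#' @param gp_sigma_f GP signal standard deviation.
#' @param gp_length GP length scale; `NULL` = median pairwise distance.
#' @param gp_noise GP noise variance on the kernel diagonal.
#' @param gp_threshold Posterior-mean threshold for the somatotopic call.
#' @param seed Seed for subspace sampling.
#' @return A list of class `env_config`.
#' @export
env_config <- function(n_learners = 30, k = 5, subspace_size = NULL,
                       gp_sigma_f = 1, gp_length = NULL, gp_noise = 1e-4,
                       gp_threshold = 0.5, seed = 1L) {
  stopifnot(n_learners >= 1, k >= 1, gp_threshold > 0, gp_threshold < 1,
            gp_noise >= 0)
  structure(as.list(environment()), class = "env_config")
}

# Numeric feature matrix from a trial tibble (or any tibble carrying the
# schema's covariate and parameter columns).
env_features <- function(trials) {
  cbind(pa = trials$pa_mA,
        pw = trials$pw_us,
        charge = trials$pa_mA * trials$pw_us / 1000,
        gender = as.numeric(trials$gender == "F"),
        weight = trials$weight_kg,
        nerve_tibial = as.numeric(trials$nerve == "tibial"),
        nerve_sural = as.numeric(trials$nerve == "sural"),
        neuropathic = as.numeric(trials$neuropathic))
}

standardize <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' Fit the simulated-subject environment
#'
#' @param trials A trial tibble in the documented schema (see
#'   [read_trials()]).
#' @param config An [env_config()].
#' @return An object of class `env_models`.
#' @export
fit_environment <- function(trials, config = env_config()) {
  stopifnot(nrow(trials) > 0)
  validate_trials(trials)
  X <- env_features(trials)
  p <- ncol(X)
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Xs <- standardize(X, ctr, scl)

  # intensity: OLS with interaction on the raw (unstandardized) features
  df <- data.frame(icode = intensity_code(trials$intensity),
                   pa = trials$pa_mA, pw = trials$pw_us,
                   gender = X[, "gender"], weight = X[, "weight"],
                   nerve_tibial = X[, "nerve_tibial"],
                   nerve_sural = X[, "nerve_sural"],
                   neuropathic = X[, "neuropathic"])
  intensity_model <- stats::lm(
    icode ~ pa * pw + gender + weight + nerve_tibial + nerve_sural +
      neuropathic, data = df)

  # type: random-subspace KNN ensemble
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  ss <- config$subspace_size %||% ceiling(sqrt(p))
  ss <- min(ss, p)
  y_type <- factor(trials$stype, levels = TYPE_LEVELS)
  type_constant <- NULL
  if (length(unique(trials$stype)) < 2) {
    warning("single-class type labels; using a constant type predictor")
    type_constant <- trials$stype[1]
  }
  subspaces <- lapply(seq_len(config$n_learners),
                      function(i) sort(sample.int(p, ss)))

  # location: exponential-kernel GP regression on 0/1 labels
  y_loc <- location_code(trials$location)
  loc_constant <- NULL
  gp <- NULL
  if (length(unique(y_loc)) < 2) {
    warning("single-class location labels; using a constant location predictor")
    loc_constant <- trials$location[1]
  } else {
    D <- as.matrix(stats::dist(Xs))
    ell <- config$gp_length %||% stats::median(D[upper.tri(D)])
    K <- config$gp_sigma_f^2 * exp(-D / ell)
    diag(K) <- diag(K) + config$gp_noise
    gp <- list(alpha = solve(K, y_loc), ell = ell,
               sigma_f = config$gp_sigma_f)
  }

  structure(
    list(version = 1L, config = config,
         center = ctr, scale = scl,
         intensity_model = intensity_model,
         type = list(train = Xs, labels = y_type, subspaces = subspaces,
                     k = config$k, constant = type_constant),
         location = list(train = Xs, gp = gp,
                         threshold = config$gp_threshold,
                         constant = loc_constant),
         n_train = nrow(trials)),
    class = "env_models")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.env_models <- function(x, ...) {
  cat(sprintf(
    "<env_models> fitted on %d trials: OLS intensity, %d-learner KNN type, GP location\n",
    x$n_train, length(x$type$subspaces)))
  invisible(x)
}

#' Summarize a fitted environment
#'
#' @param x An `env_models` object.
#' @param ... Unused.
#' @return A one-row tibble with training-set fit statistics.
#' @method glance env_models
#' @export
glance.env_models <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    intensity_rmse = sqrt(mean(stats::residuals(x$intensity_model)^2)),
    gp_length = if (is.null(x$location$gp)) NA_real_ else x$location$gp$ell,
    n_learners = length(x$type$subspaces),
    k = x$type$k)
}

#' Predict the perceived intensity level
#'
#' The continuous OLS prediction is rounded to the nearest integer,
#' clamped to `[0, 3]` and decoded to a level.
#'
#' @param env An `env_models` object.
#' @param newdata A tibble carrying the trial-schema feature columns.
#' @return Character vector of intensity levels.
#' @export
predict_intensity <- function(env, newdata) {
  X <- env_features(newdata)
  df <- data.frame(pa = newdata$pa_mA, pw = newdata$pw_us,
                   gender = X[, "gender"], weight = X[, "weight"],
                   nerve_tibial = X[, "nerve_tibial"],
                   nerve_sural = X[, "nerve_sural"],
                   neuropathic = X[, "neuropathic"])
  raw <- stats::predict(env$intensity_model, df)
  code <- pmin(pmax(round(raw), 0), 3)
  INTENSITY_LEVELS[code + 1L]
}

#' Predict the sensation type
#'
#' Majority vote across the KNN subspace learners; an even split is
#' resolved to `COM` (an optimistic tie is safer for exploration than
#' punishing it).
#'
#' @inheritParams predict_intensity
#' @return Character vector, `UNC`/`COM`.
#' @export
predict_type <- function(env, newdata) {
  if (!is.null(env$type$constant))
    return(rep(env$type$constant, nrow(newdata)))
  Xq <- standardize(env_features(newdata), env$center, env$scale)
  votes <- matrix(0L, nrow(Xq), 2L)
  for (sub in env$type$subspaces) {
    pred <- class::knn(env$type$train[, sub, drop = FALSE],
                       Xq[, sub, drop = FALSE],
                       env$type$labels, k = env$type$k)
    ii <- cbind(seq_len(nrow(Xq)), as.integer(pred))
    votes[ii] <- votes[ii] + 1L
  }
  ifelse(votes[, 2] >= votes[, 1], "COM", "UNC")
}

# GP posterior mean at query rows (internal; shared by predict_location
# and tests via the exported predictor).
gp_posterior_mean <- function(env, Xq) {
  gp <- env$location$gp
  # cross-distances by direct differencing: the squared-norm expansion
  # loses ~8 digits near training points once the square root is taken
  Xt <- t(env$location$train)
  Dq <- t(apply(Xq, 1, function(q) sqrt(colSums((Xt - q)^2))))
  if (nrow(Xq) == 1) Dq <- matrix(Dq, nrow = 1)
  as.numeric((gp$sigma_f^2 * exp(-Dq / gp$ell)) %*% gp$alpha)
}

#' Predict the sensation location
#'
#' The GP posterior mean at the query, clamped to `[0, 1]`, is compared
#' with the decision threshold: above it the point is somatotopic.
#'
#' @inheritParams predict_intensity
#' @param posterior Return the clamped posterior mean instead of labels.
#' @return Character vector `NSOM`/`SOM`, or numeric posterior means.
#' @export
predict_location <- function(env, newdata, posterior = FALSE) {
  if (!is.null(env$location$constant)) {
    if (posterior)
      return(rep(as.numeric(env$location$constant == "SOM"), nrow(newdata)))
    return(rep(env$location$constant, nrow(newdata)))
  }
  Xq <- standardize(env_features(newdata), env$center, env$scale)
  post <- pmin(pmax(gp_posterior_mean(env, Xq), 0), 1)
  if (posterior) return(post)
  ifelse(post > env$location$threshold, "SOM", "NSOM")
}

#' One environment step: stimulus in, state out
#'
#' Composes the three predictions into a sensation report (without the
#' in-loco component, which the simulated environment does not model) and
#' encodes it as a state id. A not-perceived intensity forces the
#' collapsed state 0 regardless of the other heads. Inference is pure:
#' identical inputs give identical states.
#'
#' @param env An `env_models` object.
#' @param covariates One-row tibble with `gender`, `weight_kg`, `nerve`,
#'   `neuropathic`.
#' @param pa,pw Stimulation parameters.
#' @return A list with `state_id` and the `report` tibble.
#' @export
env_step <- function(env, covariates, pa, pw) {
  n <- max(length(pa), length(pw))
  newdata <- tibble::tibble(
    pa_mA = rep_len(pa, n), pw_us = rep_len(pw, n),
    gender = covariates$gender, weight_kg = covariates$weight_kg,
    nerve = covariates$nerve, neuropathic = covariates$neuropathic)
  intensity <- predict_intensity(env, newdata)
  stype <- predict_type(env, newdata)
  location <- predict_location(env, newdata)
  list(state_id = encode_state(intensity, stype, location),
       report = tibble::tibble(intensity = intensity, stype = stype,
                               location = location))
}

#' Precompute a subject's state over the whole grid
#'
#' Environment inference is deterministic, so for a fixed set of
#' covariates the state at every (PA, PW) grid point can be tabulated
#' once; training and testing then read states in O(1).
#'
#' @param env An `env_models` object.
#' @param covariates One-row covariate tibble (see [env_step()]).
#' @param grid A [stim_grid()].
#' @return An integer matrix `length(pa_values) x length(pw_values)` of
#'   state ids.
#' @export
env_state_table <- function(env, covariates, grid = stim_grid()) {
  pts <- expand.grid(pa = grid$pa_values, pw = grid$pw_values)
  st <- env_step(env, covariates, pts$pa, pts$pw)$state_id
  matrix(st, nrow = length(grid$pa_values))
}
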