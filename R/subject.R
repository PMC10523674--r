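# Psychometric virtual subjects: the synthetic-data generator.
#
# Each subject is a deterministic strength-duration responder. The
# perception threshold current at pulse width PW follows the
# Weiss-Lapicque law I_th(PW) = rheobase * (1 + chronaxie/PW); the
# normalized supra-threshold drive maps onto a 0-10 perceived-intensity
# rating whose bands define the four reported intensity classes. Type and
# location are charge-band labels; the in-loco component grows with drive.

#' Construct a virtual subject
#'
#' A ground-truth psychometric model that answers stimulation with
#' sensation reports. Perceived rating is `r = clamp(10 * d, 0, 10)` where
#' the drive `d = (PA - I_th(PW)) / ((pain_margin - 1) * rheobase)`
#' normalizes the supra-threshold current by the subject's dynamic range
#' (`pain_margin * rheobase` is the pain-level current as PW grows large).
#' Rating bands give the intensity class: `NP` below 0.5, `LOW` to 5,
#' `HIGH` to 9, `TOOHIGH` above — anchoring the low/high targets at
#' ratings 2 and 8 of the 0 (nothing) to 10 (pain) scale. Type is comfortable inside `comfort_band` (µC) and location
#' somatotopic inside `somatotopy_band` (µC); both bands are derived from
#' the subject's own psychometrics at a reference pulse width unless given
#' explicitly. `se = clamp(round(10 * se_slope * max(d, 0)), 0, 10)`.
#'
#' Reports are deterministic by default. With `rating_sd > 0` a Gaussian
#' jitter is added to the rating and with `flip_prob > 0` the type and
#' location labels flip independently; both are reproducible given
#' (`rng_seed`, stimulus).
#'
#' At construction the full grid is scanned and the ground-truth low- and
#' high-level parameter pairs — the minimum-charge somatotopic point of
#' each class, i.e. the just-perceivable somatotopic sensation and the
#' onset of the clearly-strong band — are stored in `$gt_low` /
#' `$gt_high` for oracle-based testing.
#'
#' @param subject_id Identifier.
#' @param gender `"M"` or `"F"`.
#' @param weight Body weight (kg).
#' @param nerve `"peroneal"`, `"tibial"` or `"sural"`.
#' @param neuropathic Logical; neuropathic subjects carry elevated
#'   thresholds (the rheobase passed here must already include the factor).
#' @param rheobase Threshold current as PW tends to infinity (mA), > 0.
#' @param chronaxie PW at which threshold = 2 * rheobase (µs), > 0.
#' @param pain_margin Pain current / rheobase, > 1.
#' @param comfort_band,somatotopy_band Charge intervals (µC), or `NULL` to
#'   derive from the psychometrics.
#' @param se_slope In-loco growth rate per unit drive.
#' @param rating_sd,flip_prob Optional report noise (default none).
#' @param grid The governing [stim_grid()].
#' @param rng_seed Seed for the subject's report noise stream.
#' @return An object of class `virtual_subject`.
#' @export
virtual_subject <- function(subject_id, gender = "M", weight = 75,
                            nerve = "peroneal", neuropathic = FALSE,
                            rheobase = 2, chronaxie = 250, pain_margin = 3,
                            comfort_band = NULL, somatotopy_band = NULL,
                            se_slope = 0.15, rating_sd = 0, flip_prob = 0,
                            grid = stim_grid(), rng_seed = 1L) {
  stopifnot(rheobase > 0, chronaxie > 0, pain_margin > 1,
            gender %in% c("M", "F"),
            nerve %in% c("peroneal", "tibial", "sural"))
  s <- structure(
    list(subject_id = subject_id, gender = gender, weight = weight,
         nerve = nerve, neuropathic = isTRUE(neuropathic),
         rheobase = rheobase, chronaxie = chronaxie,
         pain_margin = pain_margin,
         comfort_band = comfort_band, somatotopy_band = somatotopy_band,
         se_slope = se_slope, rating_sd = rating_sd, flip_prob = flip_prob,
         grid = grid, rng_seed = as.integer(rng_seed)),
    class = "virtual_subject")
  pw_ref <- 300
  q_at <- function(d) (threshold_current(s, pw_ref) +
                         d * (pain_margin - 1) * rheobase) * pw_ref / 1000
  if (is.null(comfort_band)) s$comfort_band <- c(0, q_at(0.95))
  if (is.null(somatotopy_band)) s$somatotopy_band <- c(q_at(0.02), q_at(1.6))
  s$gt_low <- find_ground_truth(s, class = "LOW")
  s$gt_high <- find_ground_truth(s, class = "HIGH")
  s
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf(
    "<virtual_subject> %s (%s, %g kg, %s%s) rheobase %.2f mA, chronaxie %.0f us\n",
    x$subject_id, x$gender, x$weight, x$nerve,
    if (x$neuropathic) ", neuropathic" else "", x$rheobase, x$chronaxie))
  invisible(x)
}

#' Strength-duration threshold current
#'
#' Weiss-Lapicque law: `I_th(PW) = rheobase * (1 + chronaxie / PW)`,
#' strictly decreasing in PW; the rheobase is the PW -> infinity limit and
#' at `PW = chronaxie` the threshold is exactly twice the rheobase.
#'
#' @param subject A [virtual_subject()].
#' @param pw Pulse width (µs), > 0; vectorized.
#' @return Threshold current (mA).
#' @export
threshold_current <- function(subject, pw) {
  if (any(pw <= 0)) stop("pw must be positive", call. = FALSE)
  subject$rheobase * (1 + subject$chronaxie / pw)
}

# Deterministic noiseless rating and drive; internal.
subject_drive <- function(subject, pa, pw) {
  (pa - threshold_current(subject, pw)) /
    ((subject$pain_margin - 1) * subject$rheobase)
}

#' Ask a virtual subject to report a stimulus
#'
#' @param subject A [virtual_subject()].
#' @param pa,pw Stimulation parameters on the subject's grid; vectorized.
#' @param noise Apply the subject's configured report noise.
#' @return A [sensation_report()] tibble with an extra `rating` column.
#' @export
respond <- function(subject, pa, pw, noise = TRUE) {
  assert_on_grid(pa, pw, subject$grid)
  n <- max(length(pa), length(pw))
  pa <- rep_len(pa, n); pw <- rep_len(pw, n)
  d <- subject_drive(subject, pa, pw)
  r <- pmin(pmax(10 * d, 0), 10)
  q <- pa * pw / 1000
  comfortable <- q >= subject$comfort_band[1] & q <= subject$comfort_band[2]
  somatotopic <- q >= subject$somatotopy_band[1] & q <= subject$somatotopy_band[2]
  if (noise && (subject$rating_sd > 0 || subject$flip_prob > 0)) {
    # per-stimulus deterministic noise stream: the same (subject, stimulus)
    # pair always answers the same way
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    for (i in seq_len(n)) {
      set.seed(subject$rng_seed + 7919L * (pa[i] * 1000L + pw[i]) %% 2100000000L)
      if (subject$rating_sd > 0)
        r[i] <- min(max(r[i] + stats::rnorm(1, 0, subject$rating_sd), 0), 10)
      if (subject$flip_prob > 0) {
        if (stats::runif(1) < subject$flip_prob) comfortable[i] <- !comfortable[i]
        if (stats::runif(1) < subject$flip_prob) somatotopic[i] <- !somatotopic[i]
      }
    }
  }
  bands <- rating_bands()
  intensity <- INTENSITY_LEVELS[findInterval(r, bands) + 1L]
  se <- pmin(pmax(round(10 * subject$se_slope * pmax(d, 0)), 0), 10)
  out <- sensation_report(intensity,
                          ifelse(comfortable, "COM", "UNC"),
                          ifelse(somatotopic, "SOM", "NSOM"),
                          as.integer(se))
  out$rating <- r
  out
}

# Rating band edges: NP below 0.5, LOW to 5, HIGH to 9, TOOHIGH above.
rating_bands <- function() c(0.5, 5, 9)

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

# Grid scan for the ground-truth pair of a class: the minimum-charge
# somatotopic point of the class. For the low level this is the
# just-perceivable somatotopic sensation (the onset of the low band,
# which is what a calibration seeks); for the high level the onset of
# the clearly-strong band. Ties go to the lower amplitude.
find_ground_truth <- function(subject, class) {
  g <- subject$grid
  pts <- expand.grid(pa = g$pa_values, pw = g$pw_values)
  rep0 <- respond(subject, pts$pa, pts$pw, noise = FALSE)
  ok <- rep0$intensity == class & rep0$location == "SOM"
  if (!any(ok)) return(NULL)
  cand <- pts[ok, ]
  q <- cand$pa * cand$pw / 1000
  sel <- order(q, cand$pa)[1]
  list(pa = cand$pa[sel], pw = cand$pw[sel], charge = q[sel])
}

#' Cohort specification
#'
#' Composition and parameter distributions of a synthetic cohort emulating
#' the offline trial dataset: 27 men and 22 women (49 subjects) and 888
#' trials split 552 peroneal / 108 tibial / 228 sural. Rheobase and
#' chronaxie are log-normal with nerve- and gender-specific means; the
#' pain margin is uniform. Neuropathic subjects get their rheobase scaled
#' by `neuropathic_factor` (> 1), reflecting elevated perception
#' thresholds in polyneuropathy.
#'
#' @param n_men,n_women Subject counts.
#' @param trials_per_nerve Named integer vector of per-nerve trial totals.
#' @param neuropathic_fraction Fraction of subjects flagged neuropathic.
#' @param neuropathic_factor Multiplicative rheobase elevation.
#' @param rheobase_mean Named per-nerve mean rheobase (mA).
#' @param rheobase_cv,chronaxie_cv Coefficients of variation.
#' @param chronaxie_mean Mean chronaxie (µs).
#' @param gender_factor Multiplier applied to female rheobase means.
#' @param pain_margin_range Uniform range of the pain margin.
#' @param weight_mean,weight_sd Named per-gender weight parameters (kg).
#' @param rating_sd,flip_prob Report-noise settings for all subjects.
#' @param seed Cohort sampling seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_men = 27, n_women = 22,
                        trials_per_nerve = c(peroneal = 552, tibial = 108,
                                             sural = 228),
                        neuropathic_fraction = 0,
                        neuropathic_factor = 2,
                        rheobase_mean = c(peroneal = 2.0, tibial = 2.8,
                                          sural = 2.4),
                        rheobase_cv = 0.25,
                        chronaxie_mean = 250, chronaxie_cv = 0.3,
                        gender_factor = c(M = 1, F = 0.9),
                        pain_margin_range = c(2.5, 3.5),
                        weight_mean = c(M = 78, F = 65),
                        weight_sd = c(M = 10, F = 9),
                        rating_sd = 0, flip_prob = 0,
                        seed = 1L) {
  stopifnot(n_men >= 0, n_women >= 0, all(trials_per_nerve >= 0),
            neuropathic_fraction >= 0, neuropathic_fraction <= 1,
            neuropathic_factor > 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Sample a cohort of virtual subjects
#'
#' Subjects are assigned to nerves proportionally to the per-nerve trial
#' totals, genders interleaved across nerve groups; psychometric
#' parameters are drawn from the cohort specification's distributions.
#' Reproducible under
#' a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param grid The governing [stim_grid()].
#' @return A list of [virtual_subject()] objects (class `cohort`).
#' @export
sample_cohort <- function(spec = cohort_spec(), grid = stim_grid()) {
  n <- spec$n_men + spec$n_women
  if (n == 0) return(structure(list(), class = "cohort", spec = spec))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  # interleave M/F so every nerve group gets both genders
  genders <- character(0)
  m_left <- spec$n_men; f_left <- spec$n_women
  while (length(genders) < n) {
    if (m_left > 0) { genders <- c(genders, "M"); m_left <- m_left - 1 }
    if (f_left > 0 && length(genders) < n) {
      genders <- c(genders, "F"); f_left <- f_left - 1
    }
  }
  nerves <- names(spec$trials_per_nerve)
  n_per_nerve <- round(n * spec$trials_per_nerve / sum(spec$trials_per_nerve))
  # fix rounding so group sizes total n, each nerve nonempty when it has trials
  n_per_nerve[n_per_nerve == 0 & spec$trials_per_nerve > 0] <- 1
  while (sum(n_per_nerve) > n) n_per_nerve[which.max(n_per_nerve)] <-
      n_per_nerve[which.max(n_per_nerve)] - 1
  while (sum(n_per_nerve) < n) n_per_nerve[which.max(spec$trials_per_nerve)] <-
      n_per_nerve[which.max(spec$trials_per_nerve)] + 1
  nerve_of <- rep(nerves, times = n_per_nerve)
  n_neuro <- round(spec$neuropathic_fraction * n)
  neuro <- seq_len(n) %in% sample.int(n, n_neuro)
  lnorm_pars <- function(m, cv) {
    s2 <- log(1 + cv^2); list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genders[i]; nv <- nerve_of[i]
    rp <- lnorm_pars(spec$rheobase_mean[[nv]] * spec$gender_factor[[g]],
                     spec$rheobase_cv)
    cp <- lnorm_pars(spec$chronaxie_mean, spec$chronaxie_cv)
    rb <- stats::rlnorm(1, rp$meanlog, rp$sdlog)
    if (neuro[i]) rb <- rb * spec$neuropathic_factor
    subjects[[i]] <- virtual_subject(
      subject_id = sprintf("S%02d", i), gender = g,
      weight = round(stats::rnorm(1, spec$weight_mean[[g]],
                                  spec$weight_sd[[g]]), 1),
      nerve = nv, neuropathic = neuro[i],
      rheobase = rb,
      chronaxie = stats::rlnorm(1, cp$meanlog, cp$sdlog),
      pain_margin = stats::runif(1, spec$pain_margin_range[1],
                                 spec$pain_margin_range[2]),
      rating_sd = spec$rating_sd, flip_prob = spec$flip_prob,
      grid = grid, rng_seed = spec$seed + i)
  }
  structure(subjects, class = "cohort", spec = spec)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d virtual subjects (%d M / %d F)\n", length(x),
              sum(vapply(x, function(s) s$gender == "M", logical(1))),
              sum(vapply(x, function(s) s$gender == "F", logical(1)))))
  invisible(x)
}

#' Summarize a cohort as a tibble
#'
#' @param x A cohort from [sample_cohort()].
#' @param ... Unused.
#' @return One row per subject with covariates, psychometric parameters
#'   and ground-truth target charges.
#' @method tidy cohort
#' @export
tidy.cohort <- function(x, ...) {
  purrr::map_dfr(x, function(s) tibble::tibble(
    subject_id = s$subject_id, gender = s$gender, weight_kg = s$weight,
    nerve = s$nerve, neuropathic = as.integer(s$neuropathic),
    rheobase = s$rheobase, chronaxie = s$chronaxie,
    pain_margin = s$pain_margin,
    gt_low_pa = if (is.null(s$gt_low)) NA_real_ else s$gt_low$pa,
    gt_low_pw = if (is.null(s$gt_low)) NA_real_ else s$gt_low$pw,
    gt_low_charge = if (is.null(s$gt_low)) NA_real_ else s$gt_low$charge,
    gt_high_pa = if (is.null(s$gt_high)) NA_real_ else s$gt_high$pa,
    gt_high_pw = if (is.null(s$gt_high)) NA_real_ else s$gt_high$pw,
    gt_high_charge = if (is.null(s$gt_high)) NA_real_ else s$gt_high$charge))
}

#' Generate an offline trial dataset from a cohort
#'
#' Emulates mapping sessions: for each subject a ramp-like exploration of
#' the grid — pulse-amplitude sweeps at a few pulse widths from below the
#' perception threshold to just past the pain level — produces one row per
#' delivered stimulus with the subject's report. Per-nerve row totals
#' follow the cohort specification (default 552/108/228 = 888 rows).
#' Reproducible bit-for-bit under the specification's seed.
#'
#' @param cohort A cohort from [sample_cohort()].
#' @param spec The [cohort_spec()] (defaults to the cohort's own).
#' @return A trial tibble in the documented CSV schema.
#' @export
generate_trials <- function(cohort, spec = attr(cohort, "spec")) {
  stopifnot(length(cohort) > 0)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed + 104729L)
  nerves <- names(spec$trials_per_nerve)
  out <- list()
  for (nv in nerves) {
    subs <- purrr::keep(cohort, function(s) s$nerve == nv)
    total <- spec$trials_per_nerve[[nv]]
    if (total == 0 || length(subs) == 0) next
    base <- total %/% length(subs)
    extra <- total %% length(subs)
    counts <- rep(base, length(subs)) + (seq_along(subs) <= extra)
    for (j in seq_along(subs)) {
      out[[length(out) + 1L]] <- subject_ramp_trials(subs[[j]], counts[j])
    }
  }
  dplyr::bind_rows(out)
}

# Ramp-like exploration for one subject: PA sweeps at sampled PWs from
# sub-threshold to just supra-pain, truncated/recycled to n rows.
subject_ramp_trials <- function(s, n) {
  g <- s$grid
  rows <- list()
  pw_pool <- sample(g$pw_values, length(g$pw_values))
  k <- 0L
  for (pw in pw_pool) {
    ith <- threshold_current(s, pw)
    pain <- ith + (s$pain_margin - 1) * s$rheobase
    pa_lo <- max(min(g$pa_values), floor(ith) - 1)
    pa_hi <- min(max(g$pa_values), ceiling(pain) + 1)
    if (pa_lo > pa_hi) next
    pas <- g$pa_values[g$pa_values >= pa_lo & g$pa_values <= pa_hi]
    if (length(pas) == 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(pa = pas, pw = pw)
    k <- k + length(pas)
    if (k >= n) break
  }
  ramp <- dplyr::bind_rows(rows)
  if (nrow(ramp) == 0) stop("subject thresholds outside the grid", call. = FALSE)
  idx <- rep_len(seq_len(nrow(ramp)), n)
  ramp <- ramp[idx, ]
  rep0 <- respond(s, ramp$pa, ramp$pw)
  tibble::tibble(
    subject_id = s$subject_id, gender = s$gender, weight_kg = s$weight,
    nerve = s$nerve, neuropathic = as.integer(s$neuropathic),
    pa_mA = ramp$pa, pw_us = ramp$pw,
    intensity = rep0$intensity, stype = rep0$stype,
    location = rep0$location, se = rep0$se)
}
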