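# Sensation coding. Levels are ordered: intensity by increasing perceived
# strength; type/location so that code 1 is the desirable class.

#' Sensation level codes
#'
#' Canonical spellings and numeric codes of the three reported sensation
#' components: perceived intensity (`NP` not perceived, `LOW`, `HIGH`,
#' `TOOHIGH`; codes 0-3), type (`UNC` uncomfortable = 0, `COM` comfortable
#' = 1) and location (`NSOM` not somatotopic = 0, `SOM` somatotopic = 1).
#'
#' @format Character vectors named by code.
#' @name sensation-levels
NULL

#' @rdname sensation-levels
#' @export
INTENSITY_LEVELS <- c("NP", "LOW", "HIGH", "TOOHIGH")

#' @rdname sensation-levels
#' @export
TYPE_LEVELS <- c("UNC", "COM")

#' @rdname sensation-levels
#' @export
LOCATION_LEVELS <- c("NSOM", "SOM")

intensity_code <- function(intensity) {
  match(intensity, INTENSITY_LEVELS) - 1L
}
type_code <- function(stype) match(stype, TYPE_LEVELS) - 1L
location_code <- function(location) match(location, LOCATION_LEVELS) - 1L

#' Build a tibble of sensation reports
#'
#' One row per delivered stimulus: the subject's answer in terms of
#' perceived intensity (4 classes), type (2 classes), location (2 classes)
#' and in-loco intensity `se` (integer 0-10, sensation felt directly under
#' the electrodes). When intensity is `NP` the other components are
#' meaningless and are ignored by every consumer.
#'
#' @param intensity Character, one of `r toString(INTENSITY_LEVELS)`.
#' @param stype Character, `UNC` or `COM`.
#' @param location Character, `NSOM` or `SOM`.
#' @param se Integer 0-10.
#' @return A tibble with the four validated columns.
#' @export
sensation_report <- function(intensity, stype, location, se = 0L) {
  n <- max(length(intensity), length(stype), length(location), length(se))
  intensity <- rep_len(intensity, n); stype <- rep_len(stype, n)
  location <- rep_len(location, n); se <- rep_len(se, n)
  if (!all(intensity %in% INTENSITY_LEVELS))
    stop("invalid intensity level", call. = FALSE)
  if (!all(stype %in% TYPE_LEVELS)) stop("invalid sensation type", call. = FALSE)
  if (!all(location %in% LOCATION_LEVELS))
    stop("invalid sensation location", call. = FALSE)
  if (any(se < 0 | se > 10)) stop("se must lie in [0, 10]", call. = FALSE)
  tibble::tibble(intensity = intensity, stype = stype,
                 location = location, se = as.integer(se))
}

#' Encode a sensation report as a state id
#'
#' The three report components give 4 x 2 x 2 = 16 raw combinations, but a
#' not-perceived sensation has no describable type or location, so all
#' `NP` reports collapse to one state: the MDP has 13 states, ids 0-12.
#' Id 0 is `NP`; ids 1-12 enumerate intensity (LOW, HIGH, TOOHIGH) blocks
#' of four, each block ordered (SOM, COM), (SOM, UNC), (NSOM, COM),
#' (NSOM, UNC).
#'
#' @param intensity,stype,location Character vectors (recycled).
#' @return Integer state ids in 0-12.
#' @seealso [decode_state()], [state_ordering()]
#' @export
encode_state <- function(intensity, stype, location) {
  ic <- intensity_code(intensity)
  tc <- type_code(stype)
  lc <- location_code(location)
  # type/location of a not-perceived sensation are unobservable: any value
  # (including NA) is accepted and ignored
  tc[ic == 0L] <- 0L
  lc[ic == 0L] <- 0L
  if (anyNA(ic) || anyNA(tc) || anyNA(lc))
    stop("invalid sensation levels", call. = FALSE)
  within <- (1L - lc) * 2L + (1L - tc)
  id <- 1L + (ic - 1L) * 4L + within
  id[ic == 0L] <- 0L
  id
}

#' Decode a state id back to sensation components
#'
#' Inverse of [encode_state()] on ids 1-12; id 0 decodes to `NP` with
#' `NA` type/location (unobservable).
#'
#' @param state_id Integer vector, ids in 0-12.
#' @return A tibble with columns `state_id`, `intensity`, `stype`, `location`.
#' @export
decode_state <- function(state_id) {
  stopifnot(all(state_id %in% 0:12))
  ic <- ifelse(state_id == 0L, 0L, (state_id - 1L) %/% 4L + 1L)
  within <- ifelse(state_id == 0L, NA_integer_, (state_id - 1L) %% 4L)
  lc <- 1L - within %/% 2L
  tc <- 1L - within %% 2L
  tibble::tibble(
    state_id = as.integer(state_id),
    intensity = INTENSITY_LEVELS[ic + 1L],
    stype = ifelse(is.na(tc), NA_character_, TYPE_LEVELS[tc + 1L]),
    location = ifelse(is.na(lc), NA_character_, LOCATION_LEVELS[lc + 1L]))
}

# Numeric state vector fed to the Q-network: the 3 raw components scaled to
# [0, 1]. NP has no observable type/location; both are fed as 0.
state_vector <- function(state_id) {
  d <- decode_state(state_id)
  ic <- intensity_code(d$intensity)
  tc <- ifelse(is.na(d$stype), 0L, type_code(d$stype))
  lc <- ifelse(is.na(d$location), 0L, location_code(d$location))
  cbind(ic / 3, tc, lc, deparse.level = 0)
}

#' Sensation quality weights
#'
#' Weights of the sensation quality index. Intensity dominates (a clearly
#' perceived target-level sensation is the primary goal), location is next
#' (somatotopic feedback is intuitive), type has the lowest weight.
#' Defaults w1 = 0.6, w2 = 0.15, w3 = 0.25; they sum to 1 so the ideal
#' mapping scores exactly 1.
#'
#' @param w1,w2,w3 Intensity, type and location weights.
#' @return A named numeric vector.
#' @export
quality_weights <- function(w1 = 0.6, w2 = 0.15, w3 = 0.25) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0)
  if (abs(w1 + w2 + w3 - 1) > 1e-8)
    stop("quality weights must sum to 1", call. = FALSE)
  c(w1 = w1, w2 = w2, w3 = w3)
}

#' Sensation quality index
#'
#' Grades a completed calibration from the subject's final report:
#' `Q = w1*I + w2*T + w3*L*(1 - SE/10)` where `I` indicates the target
#' intensity level was reached, `T` that the sensation was comfortable,
#' `L` that it was somatotopic, and `SE` (0-10) is the in-loco intensity
#' under the electrodes, which discounts the location credit.
#'
#' @param I,T,L Binary indicators (0/1), vectorized.
#' @param se In-loco intensity, 0-10.
#' @param weights A [quality_weights()] vector.
#' @return Scores in `[0, 1]`.
#' @examples
#' quality_index(1, 1, 1, 0) # 1
#' @export
quality_index <- function(I, T, L, se, weights = quality_weights()) {
  stopifnot(all(I %in% 0:1), all(T %in% 0:1), all(L %in% 0:1))
  if (any(se < 0 | se > 10)) stop("se must lie in [0, 10]", call. = FALSE)
  weights[["w1"]] * I + weights[["w2"]] * T +
    weights[["w3"]] * L * (1 - se / 10)
}
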