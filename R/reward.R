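# Level-specific state desirability and reward tables.

#' Rank the 13 states by desirability for a target level
#'
#' States are ordered prioritizing (1) intensity, (2) location, (3) type.
#' For the low-level agent the target intensity class is `LOW` (for the
#' high-level agent, `HIGH`); the other perceivable-but-wrong class is safe
#' but undesired, and `TOOHIGH` is always the worst perceived class.
#' `NP` (not perceived) sits at a neutral pivot between the undesired and
#' the target block: it earns zero reward.
#'
#' @param level Target level, `"low"` or `"high"`.
#' @return Integer vector of the 13 state ids, least to most desirable.
#' @export
state_ordering <- function(level = c("low", "high")) {
  level <- match.arg(level)
  target <- if (level == "low") "LOW" else "HIGH"
  wrong <- if (level == "low") "HIGH" else "LOW"
  # within one intensity class, ascending desirability:
  # (NSOM,UNC) < (NSOM,COM) < (SOM,UNC) < (SOM,COM)
  block <- function(int) encode_state(
    rep(int, 4),
    c("UNC", "COM", "UNC", "COM"),
    c("NSOM", "NSOM", "SOM", "SOM"))
  c(block("TOOHIGH"), block(wrong), 0L, block(target))
}

#' Reward table for one agent
#'
#' A discrete nonlinear reward keyed by state id. Constraints: zero reward
#' at `NP`; increasing positive rewards over the target-level block
#' (+0.2/+0.4/+0.6 and +1 at the top-ranked state); increasing negative
#' rewards for wrong-but-safe intensity (-0.4/-0.3/-0.2/-0.1) and for
#' too-high states (-1/-0.9/-0.8/-0.6); rewards strictly increase along
#' [state_ordering()]. The unit scale keeps the discounted action values
#' within a range the critic reaches quickly at the configured learning
#' rate; the values are configurable and only their ordering constraints
#' are essential.
#'
#' @param level `"low"` or `"high"`.
#' @param values Optional numeric vector of 13 rewards ordered least to
#'   most desirable along [state_ordering()] (position 9 is the `NP` pivot).
#' @return An object of class `reward_table` with `level`, `values` (named
#'   by state id 0-12) and `ordering`.
#' @export
reward_table <- function(level = c("low", "high"), values = NULL) {
  level <- match.arg(level)
  ord <- state_ordering(level)
  if (is.null(values))
    values <- c(-1, -0.9, -0.8, -0.6, -0.4, -0.3, -0.2, -0.1, 0,
                0.2, 0.4, 0.6, 1)
  stopifnot(length(values) == 13)
  if (values[ord == 0L] != 0)
    stop("the not-perceived state must earn zero reward", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("rewards must strictly increase with desirability", call. = FALSE)
  v <- numeric(13)
  v[ord + 1L] <- values
  names(v) <- 0:12
  structure(list(level = level, values = v, ordering = ord),
            class = "reward_table")
}

#' @export
print.reward_table <- function(x, ...) {
  cat(sprintf("<reward_table> level = %s\n", x$level))
  d <- decode_state(x$ordering)
  cat(sprintf("  %s: %g\n",
              paste(d$intensity, d$stype, d$location, sep = "/"),
              x$values[as.character(x$ordering)]), sep = "")
  invisible(x)
}

#' Look up the reward of a state
#'
#' @param state_id Integer ids 0-12, vectorized.
#' @param table A [reward_table()].
#' @return Numeric rewards.
#' @export
reward <- function(state_id, table) {
  stopifnot(inherits(table, "reward_table"), all(state_id %in% 0:12))
  unname(table$values[as.character(state_id)])
}

#' Discounted return of a reward sequence
#'
#' `G = sum_k gamma^k r_k` over a finite episode; the discount rate
#' `gamma` in `[0, 1]` keeps the total bounded (default 0.99).
#'
#' @param rewards Numeric sequence, first reward undiscounted.
#' @param gamma Discount rate.
#' @return A scalar.
#' @export
discounted_return <- function(rewards, gamma = 0.99) {
  stopifnot(gamma >= 0, gamma <= 1)
  if (length(rewards) == 0) return(0)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}
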