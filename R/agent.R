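# DQN agent: epsilon-greedy exploration over the 9 parameter-delta
# actions, one critic gradient step per environment step, soft target
# updates, multiplicative epsilon decay per learning step.

#' DQN hyperparameters
#'
#' Defaults follow standard DQN toolbox settings for this task: learn
#' rate 1e-4, L2 regularization 1e-4, target smooth factor 1e-3, discount
#' 0.99, mini-batch 64, epsilon starting at 1 and decaying
#' multiplicatively by 0.005 per learning step down to `epsilon_min`.
#'
#' @param learn_rate Adam learning rate.
#' @param l2_factor L2 penalty on the weights.
#' @param tau Target-network smoothing factor.
#' @param gamma Discount rate.
#' @param batch_size Mini-batch size.
#' @param epsilon0,epsilon_decay,epsilon_min Exploration schedule:
#'   `eps <- max(epsilon_min, eps * (1 - epsilon_decay))` per learning
#'   step. The floor of 0.1 keeps the replay buffer stocked with
#'   off-policy actions in every recurring state; with only 13 distinct
#'   states, stale action-value estimates otherwise dominate the argmax.
#' @param max_steps_per_episode Step cap; reaching it ends the episode as
#'   a successful (non-terminal) truncation.
#' @param max_episodes Training episode budget.
#' @param avg_reward_stop Stop early when the running-average episode
#'   return over `avg_window` episodes reaches this value. Independently
#'   of early stopping, the critic returned by training is the snapshot
#'   with the best running average seen.
#' @param avg_window Window of the running average.
#' @param buffer_capacity Replay-buffer size; learning starts once the
#'   buffer holds at least `batch_size` transitions.
#' @param explore_start_frac Fraction of training episodes initialized at
#'   a uniform-random grid point instead of the dataset rule (exploring
#'   starts). Off by default: random starts improve state coverage but
#'   make the episode-return distribution — and with it the running
#'   average that selects the returned snapshot — reflect the luck of the
#'   start draw rather than policy quality.
#' @return A list of class `dqn_hyperparams`.
#' @export
dqn_hyperparams <- function(learn_rate = 1e-4, l2_factor = 1e-4,
                            tau = 1e-3, gamma = 0.99, batch_size = 64,
                            epsilon0 = 1, epsilon_decay = 0.005,
                            epsilon_min = 0.1,
                            max_steps_per_episode = 100,
                            max_episodes = 1200,
                            avg_reward_stop = Inf, avg_window = 50,
                            buffer_capacity = 10000,
                            explore_start_frac = 0) {
  structure(as.list(environment()), class = "dqn_hyperparams")
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform-random action; otherwise the
#' action with the highest Q-value, ties broken by the lowest index.
#'
#' @param net A [q_network()].
#' @param state State vector (network input).
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return An action index.
#' @export
select_action <- function(net, state, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  n_actions <- utils::tail(net$layers, 1)
  if (epsilon > 0 && stats::runif(1) < epsilon)
    return(sample.int(n_actions, 1))
  which.max(q_forward(net, state))
}

#' TD target of a transition
#'
#' `r + gamma * max_a Q_target(s', a)`, with the bootstrap term dropped
#' for terminal transitions.
#'
#' @param reward_value Observed reward.
#' @param next_state Next-state vector.
#' @param terminal Terminal flag.
#' @param target_net The target [q_network()].
#' @param gamma Discount rate.
#' @return A scalar.
#' @export
td_target <- function(reward_value, next_state, terminal, target_net,
                      gamma) {
  if (terminal) return(reward_value)
  reward_value + gamma * max(q_forward(target_net, next_state))
}

#' One critic update from a replay batch
#'
#' A single Adam step on the mean squared TD error of the batch plus the
#' L2 weight penalty; only the sampled (state, action) outputs enter the
#' data term. An empty buffer is a no-op.
#'
#' @param net Online [q_network()].
#' @param target_net Target network used for the bootstrap.
#' @param batch A batch as returned by [rb_sample()].
#' @param hp [dqn_hyperparams()].
#' @return The updated online network.
#' @export
update_critic <- function(net, target_net, batch, hp) {
  if (is.null(batch) || length(batch$actions) == 0) return(net)
  qn <- q_forward(target_net, batch$next_states)
  boot <- apply(qn, 1, max)
  targets <- batch$rewards + hp$gamma * boot * !batch$terminal
  critic_step(net, batch$states, batch$actions, targets,
              hp$learn_rate, hp$l2_factor)
}

# Generic episodic DQN training loop over closures:
#   reset_fn(episode) -> initial state vector (also resets the episode),
#   step_fn(action)   -> list(state, reward, terminal),
#   eval_fn(net)      -> scalar greedy-policy score (optional).
# Returns the trained networks, the epsilon state and an episode log.
# The returned critic is the snapshot with the best evaluation score
# (eval_fn every eval_every episodes) or, without an eval_fn, the best
# running-average training return.
dqn_train_loop <- function(reset_fn, step_fn, hp = dqn_hyperparams(),
                           layers = c(3, 40, 30, 9), seed = 1L,
                           eval_fn = NULL, eval_every = 25L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  net <- q_network(layers, seed = seed)
  target_net <- net # target equals online net at initialization
  rb <- replay_buffer(hp$buffer_capacity, state_dim = layers[1])
  eps <- hp$epsilon0
  log <- vector("list", hp$max_episodes)
  returns <- numeric(0)
  # the returned critic is the snapshot with the best running-average
  # episode return: continued training under function approximation can
  # degrade an already-good policy (policy churn)
  best <- list(net = net, target_net = target_net, avg = -Inf)
  for (ep in seq_len(hp$max_episodes)) {
    state <- reset_fn(ep)
    rewards <- numeric(0)
    for (t in seq_len(hp$max_steps_per_episode)) {
      a <- select_action(net, state, eps)
      res <- step_fn(a)
      rb_add(rb, state, a, res$reward, res$state, res$terminal)
      rewards <- c(rewards, res$reward)
      if (rb_size(rb) >= hp$batch_size) {
        net <- update_critic(net, target_net, rb_sample(rb, hp$batch_size),
                             hp)
        target_net <- soft_update(target_net, net, hp$tau)
        eps <- max(hp$epsilon_min, eps * (1 - hp$epsilon_decay))
      }
      state <- res$state
      if (res$terminal) break
    }
    ret <- discounted_return(rewards, hp$gamma)
    returns <- c(returns, sum(rewards))
    log[[ep]] <- tibble::tibble(episode = ep, steps = length(rewards),
                                return_disc = ret,
                                return_raw = sum(rewards), epsilon = eps)
    if (!is.null(eval_fn)) {
      if (ep %% eval_every == 0 || ep == hp$max_episodes) {
        score <- eval_fn(net)
        if (score > best$avg)
          best <- list(net = net, target_net = target_net, avg = score)
      }
    } else if (length(returns) >= hp$avg_window) {
      avg <- mean(utils::tail(returns, hp$avg_window))
      if (avg > best$avg)
        best <- list(net = net, target_net = target_net, avg = avg)
    }
    if (length(returns) >= hp$avg_window &&
        mean(utils::tail(returns, hp$avg_window)) >= hp$avg_reward_stop)
      break
  }
  list(net = best$net, target_net = best$target_net, epsilon = eps,
       log = dplyr::bind_rows(log), best_avg = best$avg)
}

#' Train a DQN agent against the simulated environment
#'
#' Each training episode simulates the characterization of one randomly
#' drawn subject of the cohort: parameters start from the smart
#' initialization rules (dataset minimum-charge low-level match by gender
#' and nerve; for the high-level agent, the dataset low-to-high pairing),
#' and the agent modulates PA/PW until the simulated subject reports a
#' too-high intensity (failure, terminal) or the step cap is reached
#' (successful truncation, non-terminal for bootstrapping). Rewards come
#' from the level-specific [reward_table()]. Subject states over the grid
#' are tabulated once per subject ([env_state_table()]), so episode steps
#' are table lookups.
#'
#' @param env A fitted [fit_environment()] model set.
#' @param cohort The cohort whose covariates are sampled per episode.
#' @param level `"low"` or `"high"`: the target intensity.
#' @param dataset Reference trial dataset for smart initialization.
#' @param hp [dqn_hyperparams()].
#' @param grid A [stim_grid()].
#' @param rewards A [reward_table()] (defaults to the level's table).
#' @param seed Training seed (weights, exploration, episode order).
#' @return An object of class `dqn_agent` with the trained network, the
#'   training log and the configuration.
#' @export
train_agent <- function(env, cohort, level = c("low", "high"), dataset,
                        hp = dqn_hyperparams(), grid = stim_grid(),
                        rewards = NULL, seed = 1L) {
  level <- match.arg(level)
  if (!inherits(env, "env_models")) stop("env must be a fitted env_models",
                                         call. = FALSE)
  rewards <- rewards %||% reward_table(level)
  rtab <- rewards$values[as.character(0:12)]
  covs <- cohort_covariates(cohort)
  tables <- lapply(seq_len(nrow(covs)), function(i)
    env_state_table(env, covs[i, ], grid))
  inits <- agent_inits(covs, dataset, level, grid)
  svecs <- state_vector(0:12)
  toohigh <- decode_state(0:12)$intensity == "TOOHIGH"
  n_pa <- length(grid$pa_values); n_pw <- length(grid$pw_values)
  acts <- enumerate_actions()
  # mutable episode context
  ctx <- new.env(parent = emptyenv())
  reset_fn <- function(ep) {
    i <- sample.int(nrow(covs), 1)
    ctx$tab <- tables[[i]]
    if (stats::runif(1) < hp$explore_start_frac) {
      ctx$ipa <- sample.int(n_pa, 1)
      ctx$ipw <- sample.int(n_pw, 1)
    } else {
      ctx$ipa <- match(inits$pa[i], grid$pa_values)
      ctx$ipw <- match(inits$pw[i], grid$pw_values)
    }
    ctx$sid <- ctx$tab[ctx$ipa, ctx$ipw]
    svecs[ctx$sid + 1L, ]
  }
  step_fn <- function(a) {
    ctx$ipa <- min(max(ctx$ipa + acts$d_pa[a], 1L), n_pa)
    ctx$ipw <- min(max(ctx$ipw + acts$d_pw[a] %/% 10L, 1L), n_pw)
    sid <- ctx$tab[ctx$ipa, ctx$ipw]
    ctx$sid <- sid
    list(state = svecs[sid + 1L, ], reward = rtab[sid + 1L],
         terminal = toohigh[sid + 1L])
  }
  # checkpoint selection: deterministic greedy rollouts from the rule
  # initializations across the whole cohort, scored by mean episode
  # return — free of exploration and start noise
  d_pa <- acts$d_pa; d_pw <- acts$d_pw %/% 10L
  eval_fn <- function(net) {
    policy <- apply(q_forward(net, svecs), 1, which.max)
    total <- 0
    for (i in seq_len(nrow(covs))) {
      tab <- tables[[i]]
      ipa <- match(inits$pa[i], grid$pa_values)
      ipw <- match(inits$pw[i], grid$pw_values)
      sid <- tab[ipa, ipw]
      for (t in seq_len(hp$max_steps_per_episode)) {
        a <- policy[sid + 1L]
        ipa <- min(max(ipa + d_pa[a], 1L), n_pa)
        ipw <- min(max(ipw + d_pw[a], 1L), n_pw)
        sid <- tab[ipa, ipw]
        total <- total + rtab[sid + 1L]
        if (toohigh[sid + 1L]) break
      }
    }
    total / nrow(covs)
  }
  fit <- dqn_train_loop(reset_fn, step_fn, hp,
                        layers = c(3, 40, 30, 9), seed = seed,
                        eval_fn = eval_fn)
  structure(list(level = level, net = fit$net, target_net = fit$target_net,
                 epsilon = fit$epsilon, hp = hp, grid = grid,
                 rewards = rewards, log = fit$log, seed = seed),
            class = "dqn_agent")
}

# One covariate row per subject.
cohort_covariates <- function(cohort) {
  purrr::map_dfr(cohort, function(s) tibble::tibble(
    subject_id = s$subject_id, gender = s$gender, weight_kg = s$weight,
    nerve = s$nerve, neuropathic = as.integer(s$neuropathic)))
}

# Smart initialization per subject for a level.
agent_inits <- function(covs, dataset, level, grid) {
  init <- purrr::map_dfr(seq_len(nrow(covs)), function(i) {
    low <- init_low_params(dataset, covs$gender[i], covs$nerve[i], grid)
    if (level == "high") {
      hi <- init_high_params(dataset, low, grid)
      tibble::tibble(pa = hi$pa, pw = hi$pw)
    } else tibble::tibble(pa = low$pa, pw = low$pw)
  })
  init
}

#' @export
print.dqn_agent <- function(x, ...) {
  cat(sprintf("<dqn_agent> %s-level, %d training episodes, epsilon = %.4f\n",
              x$level, nrow(x$log), x$epsilon))
  invisible(x)
}

#' Tidy the training log of an agent
#'
#' @param x A `dqn_agent`.
#' @param ... Unused.
#' @return The per-episode training log tibble.
#' @method tidy dqn_agent
#' @export
tidy.dqn_agent <- function(x, ...) x$log

#' One-line summary of a trained agent
#'
#' @param x A `dqn_agent`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance dqn_agent
#' @export
glance.dqn_agent <- function(x, ...) {
  tibble::tibble(level = x$level, episodes = nrow(x$log),
                 mean_return = mean(x$log$return_raw),
                 final_epsilon = x$epsilon)
}

#' Plot a training log
#'
#' Episode return (raw sum of rewards) with a running mean.
#'
#' @param object A `dqn_agent`.
#' @param window Running-mean window.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dqn_agent
#' @export
autoplot.dqn_agent <- function(object, window = 50, ...) {
  log <- object$log
  log$running <- stats::filter(log$return_raw, rep(1 / window, window),
                               sides = 1)
  ggplot2::ggplot(log, ggplot2::aes(x = .data$episode)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$return_raw), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$running), colour = "firebrick",
                       na.rm = TRUE) +
    ggplot2::labs(x = "episode", y = "episode return",
                  title = sprintf("%s-level agent training", object$level)) +
    ggplot2::theme_minimal()
}

# Greedy 13-state policy of a trained agent: inference is deterministic,
# so the action per state is tabulated once.
greedy_policy <- function(agent) {
  sv <- state_vector(0:12)
  apply(q_forward(agent$net, sv), 1, which.max)
}

#' Test a trained agent on the simulated environment
#'
#' Greedy (epsilon = 0) episodes per subject: the first starts exactly at
#' the smart-initialization rule (or a supplied per-subject start), the
#' remaining `n_init - 1` from seeded small jitters of that start (within
#' `jitter_pa` amplitude steps and `jitter_pw` width steps, clamped to
#' the grid) emulating session-to-session variation. An episode
#' converges when the (PA, PW) pair is identical for `window` consecutive
#' iterations, or stops at `step_cap`; it is correct when the final
#' state's intensity equals the target level.
#'
#' @param agent A trained [train_agent()] object.
#' @param env The fitted environment.
#' @param cohort The cohort of simulated subjects.
#' @param dataset Reference dataset for the initialization rule.
#' @param n_init Episodes per subject.
#' @param window Consecutive-unchanged convergence window.
#' @param step_cap Maximum stimuli per episode.
#' @param init_params Optional tibble (`subject_id`, `pa`, `pw`)
#'   overriding the first episode's start (e.g. the converged low-level
#'   parameters when testing the high-level agent).
#' @param jitter_pa,jitter_pw Maximum start jitter (grid steps) of the
#'   replicate episodes.
#' @param grid A [stim_grid()].
#' @param seed Seed for the random starts.
#' @return A tibble with one row per episode (`subject_id`, `init_pa`,
#'   `init_pw`, `steps`, `converged`, `final_state_id`, `final_intensity`,
#'   `correct`).
#' @export
test_agent <- function(agent, env, cohort, dataset, n_init = 5,
                       window = 5, step_cap = 100, init_params = NULL,
                       jitter_pa = 2, jitter_pw = 5,
                       grid = stim_grid(), seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  target <- if (agent$level == "low") "LOW" else "HIGH"
  covs <- cohort_covariates(cohort)
  policy <- greedy_policy(agent)
  acts <- enumerate_actions()
  intensity_of <- decode_state(0:12)$intensity
  n_pa <- length(grid$pa_values); n_pw <- length(grid$pw_values)
  rule_inits <- if (is.null(init_params)) {
    agent_inits(covs, dataset, agent$level, grid)
  } else {
    ord <- match(covs$subject_id, init_params$subject_id)
    tibble::tibble(pa = init_params$pa[ord], pw = init_params$pw[ord])
  }
  out <- list()
  for (i in seq_len(nrow(covs))) {
    tab <- env_state_table(env, covs[i, ], grid)
    ipa0 <- match(rule_inits$pa[i], grid$pa_values)
    ipw0 <- match(rule_inits$pw[i], grid$pw_values)
    jpa <- c(0L, sample(-jitter_pa:jitter_pa, n_init - 1, replace = TRUE))
    jpw <- c(0L, sample(-jitter_pw:jitter_pw, n_init - 1, replace = TRUE))
    starts <- tibble::tibble(
      pa = grid$pa_values[pmin(pmax(ipa0 + jpa, 1L), n_pa)],
      pw = grid$pw_values[pmin(pmax(ipw0 + jpw, 1L), n_pw)])
    for (r in seq_len(n_init)) {
      ipa <- match(starts$pa[r], grid$pa_values)
      ipw <- match(starts$pw[r], grid$pw_values)
      # the initial delivery is iteration 1 of the unchanged-window count
      unchanged <- 1L; steps <- 1L; converged <- FALSE
      sid <- tab[ipa, ipw]
      while (steps < step_cap) {
        a <- policy[sid + 1L]
        npa <- min(max(ipa + acts$d_pa[a], 1L), n_pa)
        npw <- min(max(ipw + acts$d_pw[a] %/% 10L, 1L), n_pw)
        steps <- steps + 1L
        unchanged <- if (npa == ipa && npw == ipw) unchanged + 1L else 1L
        ipa <- npa; ipw <- npw
        sid <- tab[ipa, ipw]
        if (unchanged >= window) { converged <- TRUE; break }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        subject_id = covs$subject_id[i], rep = r,
        init_pa = starts$pa[r], init_pw = starts$pw[r],
        final_pa = grid$pa_values[ipa], final_pw = grid$pw_values[ipw],
        steps = steps, converged = converged,
        final_state_id = sid,
        final_intensity = intensity_of[sid + 1L],
        correct = intensity_of[sid + 1L] == target)
    }
  }
  dplyr::bind_rows(out)
}
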