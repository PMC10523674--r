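# Independent oracles shared across test files. Each is a deliberately
# plain reimplementation (loops, enumeration, dense solves) kept separate
# from the package's own code paths.

# Deterministic 4-state chain MDP: states 1..4 (one-hot), actions
# left/right, reward on entering state 3, terminal penalty at state 4.
chain_mdp <- function() {
  reward_of <- c(0, 0, 1, -1)
  step <- function(s, a) {
    s2 <- min(max(s + if (a == 1) -1L else 1L, 1L), 4L)
    list(state = s2, reward = reward_of[s2], terminal = s2 == 4L)
  }
  list(step = step, reward_of = reward_of)
}

# Value iteration over the chain MDP to convergence.
chain_value_iteration <- function(gamma = 0.99) {
  mdp <- chain_mdp()
  Q <- matrix(0, 4, 2)
  for (iter in 1:2000) {
    Qn <- Q
    for (s in 1:3) for (a in 1:2) {
      r <- mdp$step(s, a)
      Qn[s, a] <- r$reward +
        if (r$terminal) 0 else gamma * max(Q[r$state, ])
    }
    if (max(abs(Qn - Q)) < 1e-10) break
    Q <- Qn
  }
  Q
}

# Train a DQN on the chain MDP and return the greedy action per state.
chain_dqn_policy <- function(seed = 2) {
  mdp <- chain_mdp()
  onehot <- diag(4)
  ctx <- new.env()
  reset_fn <- function(ep) {
    ctx$s <- sample(1:3, 1)
    onehot[ctx$s, ]
  }
  step_fn <- function(a) {
    r <- mdp$step(ctx$s, a)
    ctx$s <- r$state
    list(state = onehot[r$state, ], reward = r$reward,
         terminal = r$terminal)
  }
  hp <- dqn_hyperparams(learn_rate = 1e-3, max_episodes = 250,
                        max_steps_per_episode = 25, batch_size = 32,
                        buffer_capacity = 2000)
  fit <- tenscal:::dqn_train_loop(reset_fn, step_fn, hp,
                                  layers = c(4, 16, 2), seed = seed)
  apply(q_forward(fit$net, onehot[1:3, ]), 1, which.max)
}

# GP posterior mean by explicit kernel loops and a dense solve.
gp_oracle <- function(Xtr, y, Xq, sigma_f, ell, noise) {
  n <- nrow(Xtr)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sigma_f^2 * exp(-sqrt(sum((Xtr[i, ] - Xtr[j, ])^2)) / ell)
  K <- K + diag(noise, n)
  alpha <- solve(K) %*% y
  out <- numeric(nrow(Xq))
  for (i in seq_len(nrow(Xq))) {
    ks <- vapply(seq_len(n), function(j)
      sigma_f^2 * exp(-sqrt(sum((Xq[i, ] - Xtr[j, ])^2)) / ell), 0)
    out[i] <- sum(ks * alpha)
  }
  out
}

# Two-sided exact signed-rank p-value by enumerating all 2^n sign vectors.
wilcoxon_exact_p <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}
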