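# Q-network: a fully connected 3-40-30-9 ReLU network mapping the scaled
# 3-component sensation state to one Q-value per action. At this scale a
# hand-written forward/backward pass on base matrices is the natural
# implementation; the optimizer is Adam with an L2 penalty on the weights.

#' Construct a Q-network
#'
#' @param layers Layer sizes; input must equal the state dimension and
#'   output the number of actions (defaults 3 and 9, two hidden layers of
#'   40 and 30 ReLU units).
#' @param seed Weight-initialization seed (He-scaled normal).
#' @return An object of class `q_network`.
#' @export
q_network <- function(layers = c(3, 40, 30, 9), seed = 1L) {
  stopifnot(length(layers) >= 2)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  nl <- length(layers) - 1
  W <- vector("list", nl); b <- vector("list", nl)
  for (i in seq_len(nl)) {
    W[[i]] <- matrix(stats::rnorm(layers[i] * layers[i + 1],
                                  sd = sqrt(2 / layers[i])),
                     nrow = layers[i])
    b[[i]] <- numeric(layers[i + 1])
  }
  structure(list(layers = layers, W = W, b = b, opt = NULL),
            class = "q_network")
}

#' Forward pass
#'
#' @param net A [q_network()].
#' @param X State matrix (rows = states) or a single state vector.
#' @param cache Keep pre-activations for backpropagation.
#' @return Q-value matrix (rows = states, columns = actions); with
#'   `cache = TRUE`, a list `q`, `A`, `Z`.
#' @export
q_forward <- function(net, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  nl <- length(net$W)
  A <- vector("list", nl + 1); Z <- vector("list", nl)
  A[[1]] <- X
  for (i in seq_len(nl)) {
    Z[[i]] <- sweep(A[[i]] %*% net$W[[i]], 2, net$b[[i]], "+")
    A[[i + 1]] <- if (i < nl) pmax(Z[[i]], 0) else Z[[i]]
  }
  if (cache) list(q = A[[nl + 1]], A = A, Z = Z) else A[[nl + 1]]
}

# One Adam gradient step on the TD loss of a batch. Returns the updated
# network. Loss = mean over the batch of (Q(s,a) - y)^2 + l2 * sum(W^2);
# only the sampled (s, a) outputs contribute to the data term.
critic_step <- function(net, states, actions, targets, learn_rate,
                        l2_factor) {
  fw <- q_forward(net, states, cache = TRUE)
  nl <- length(net$W)
  n <- nrow(states)
  delta <- matrix(0, n, ncol(fw$q))
  ii <- cbind(seq_len(n), actions)
  delta[ii] <- 2 * (fw$q[ii] - targets) / n
  gW <- vector("list", nl); gb <- vector("list", nl)
  d <- delta
  for (i in rev(seq_len(nl))) {
    gW[[i]] <- crossprod(fw$A[[i]], d) + 2 * l2_factor * net$W[[i]]
    gb[[i]] <- colSums(d)
    if (i > 1) d <- (d %*% t(net$W[[i]])) * (fw$Z[[i - 1]] > 0)
  }
  adam_update(net, gW, gb, learn_rate)
}

# Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8); state rides on net$opt.
adam_update <- function(net, gW, gb, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  nl <- length(net$W)
  if (is.null(net$opt)) {
    net$opt <- list(t = 0L,
                    mW = lapply(net$W, function(w) w * 0),
                    vW = lapply(net$W, function(w) w * 0),
                    mb = lapply(net$b, function(x) x * 0),
                    vb = lapply(net$b, function(x) x * 0))
  }
  net$opt$t <- net$opt$t + 1L
  c1 <- 1 - beta1^net$opt$t; c2 <- 1 - beta2^net$opt$t
  for (i in seq_len(nl)) {
    net$opt$mW[[i]] <- beta1 * net$opt$mW[[i]] + (1 - beta1) * gW[[i]]
    net$opt$vW[[i]] <- beta2 * net$opt$vW[[i]] + (1 - beta2) * gW[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (net$opt$mW[[i]] / c1) / (sqrt(net$opt$vW[[i]] / c2) + eps)
    net$opt$mb[[i]] <- beta1 * net$opt$mb[[i]] + (1 - beta1) * gb[[i]]
    net$opt$vb[[i]] <- beta2 * net$opt$vb[[i]] + (1 - beta2) * gb[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (net$opt$mb[[i]] / c1) / (sqrt(net$opt$vb[[i]] / c2) + eps)
  }
  net
}

#' Soft target-network update
#'
#' `theta_target <- tau * theta + (1 - tau) * theta_target` per parameter;
#' `tau = 1` copies, `tau = 0` leaves the target untouched.
#'
#' @param target_net,net Congruent [q_network()] objects.
#' @param tau Smoothing factor in `[0, 1]`.
#' @return The updated target network.
#' @export
soft_update <- function(target_net, net, tau) {
  if (!identical(target_net$layers, net$layers))
    stop("network shapes differ", call. = FALSE)
  for (i in seq_along(net$W)) {
    target_net$W[[i]] <- tau * net$W[[i]] + (1 - tau) * target_net$W[[i]]
    target_net$b[[i]] <- tau * net$b[[i]] + (1 - tau) * target_net$b[[i]]
  }
  target_net
}

# --- circular replay buffer -------------------------------------------------

#' Circular experience replay buffer
#'
#' Fixed-capacity FIFO store of transitions
#' `(state, action, reward, next state, terminal)`; once full, the oldest
#' experience is overwritten.
#'
#' @param capacity Maximum number of stored transitions.
#' @param state_dim State vector length.
#' @return An environment of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 10000, state_dim = 3) {
  rb <- new.env(parent = emptyenv())
  rb$capacity <- capacity
  rb$S <- matrix(0, capacity, state_dim)
  rb$S2 <- matrix(0, capacity, state_dim)
  rb$A <- integer(capacity)
  rb$R <- numeric(capacity)
  rb$terminal <- logical(capacity)
  rb$n <- 0L
  rb$cursor <- 0L
  class(rb) <- "replay_buffer"
  rb
}

#' @rdname replay_buffer
#' @param rb A `replay_buffer`.
#' @param state,next_state State vectors.
#' @param action Action index.
#' @param reward_value Scalar reward.
#' @param terminal Terminal-transition flag.
#' @export
rb_add <- function(rb, state, action, reward_value, next_state, terminal) {
  rb$cursor <- rb$cursor %% rb$capacity + 1L
  rb$S[rb$cursor, ] <- state
  rb$S2[rb$cursor, ] <- next_state
  rb$A[rb$cursor] <- action
  rb$R[rb$cursor] <- reward_value
  rb$terminal[rb$cursor] <- terminal
  rb$n <- min(rb$n + 1L, rb$capacity)
  invisible(rb)
}

#' @rdname replay_buffer
#' @export
rb_size <- function(rb) rb$n

#' @rdname replay_buffer
#' @param batch_size Transitions to draw (uniform without replacement).
#' @export
rb_sample <- function(rb, batch_size) {
  idx <- sample.int(rb$n, min(batch_size, rb$n))
  list(states = rb$S[idx, , drop = FALSE],
       actions = rb$A[idx],
       rewards = rb$R[idx],
       next_states = rb$S2[idx, , drop = FALSE],
       terminal = rb$terminal[idx])
}
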