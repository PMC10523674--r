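test_that("the forward pass computes ReLU layer arithmetic", {
  net <- q_network(c(2, 2, 2), seed = 1)
  net$W[[1]] <- matrix(c(1, 0, -1, 1), 2, 2) # columns are units
  net$b[[1]] <- c(0.5, -0.5)
  net$W[[2]] <- matrix(c(1, 1, 0, 2), 2, 2)
  net$b[[2]] <- c(0, 1)
  x <- c(1, 2)
  h <- pmax(c(1 * 1 + 2 * 0 + 0.5, 1 * -1 + 2 * 1 - 0.5), 0) # (1.5, 0.5)
  expect_equal(as.numeric(q_forward(net, x)),
               c(h[1] + h[2], 2 * h[2] + 1))
  # batched rows agree with single rows
  X <- rbind(c(1, 2), c(-3, 0.5))
  expect_equal(q_forward(net, X)[2, ], as.numeric(q_forward(net, X[2, ])))
})

test_that("default network geometry maps 3 state inputs to 9 action values", {
  net <- q_network(seed = 2)
  expect_equal(net$layers, c(3, 40, 30, 9))
  expect_equal(dim(q_forward(net, matrix(runif(15), 5, 3))), c(5, 9))
})

test_that("epsilon-greedy selection explores and exploits as specified", {
  net <- q_network(seed = 1)
  for (i in seq_along(net$W)) net$W[[i]][] <- 0
  net$b[[3]] <- c(0, 0, 0, 0, 0, 3, 0, 0, 0)
  s <- c(0.5, 1, 0)
  expect_equal(select_action(net, s, epsilon = 0), 6)
  # tie between actions 2 and 3 resolves to the lower index
  net$b[[3]] <- c(0, 5, 5, 0, 0, 0, 0, 0, 0)
  expect_equal(select_action(net, s, epsilon = 0), 2)
  set.seed(42)
  draws <- replicate(9000, select_action(net, s, epsilon = 1))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:9)))$p.value,
            0.001)
  expect_error(select_action(net, s, epsilon = 2))
})

test_that("TD targets bootstrap from the target network except at terminals", {
  net <- q_network(seed = 1)
  for (i in seq_along(net$W)) net$W[[i]][] <- 0
  net$b[[3]] <- 1:9
  s2 <- c(0, 0, 0)
  expect_equal(td_target(1, s2, terminal = FALSE, net, gamma = 0.5),
               1 + 0.5 * 9)
  expect_equal(td_target(1, s2, terminal = TRUE, net, gamma = 0.5), 1)
  expect_equal(td_target(7, s2, terminal = FALSE, net, gamma = 0), 7)
})

test_that("critic updates descend the TD loss and apply the ridge penalty", {
  hp0 <- dqn_hyperparams(learn_rate = 1e-3, l2_factor = 0)
  # zero-TD batch with no penalty leaves the weights unchanged
  net <- q_network(seed = 3)
  for (i in seq_along(net$W)) net$W[[i]][] <- 0
  for (i in seq_along(net$b)) net$b[[i]][] <- 0
  batch <- list(states = matrix(runif(12), 4, 3), actions = c(1, 5, 9, 3),
                rewards = rep(0, 4),
                next_states = matrix(runif(12), 4, 3),
                terminal = rep(TRUE, 4))
  upd <- update_critic(net, net, batch, hp0)
  expect_equal(upd$W, net$W, tolerance = 1e-12)
  # pure ridge step shrinks the weight norm when TD error is zero
  net2 <- q_network(seed = 4)
  fw <- q_forward(net2, batch$states)
  batch2 <- batch
  batch2$rewards <- fw[cbind(1:4, batch$actions)]
  hp_l2 <- dqn_hyperparams(learn_rate = 1e-3, l2_factor = 1e-2)
  upd2 <- update_critic(net2, net2, batch2, hp_l2)
  norm_w <- function(n) sum(vapply(n$W, function(w) sum(w^2), 0))
  expect_lt(norm_w(upd2), norm_w(net2))
  # a single-transition update reduces its own squared TD error
  net3 <- q_network(seed = 5)
  tr1 <- list(states = matrix(c(0.3, 0.6, 1), 1, 3), actions = 2L,
              rewards = 1.5, next_states = matrix(0, 1, 3),
              terminal = TRUE)
  before <- (q_forward(net3, tr1$states)[1, 2] - 1.5)^2
  upd3 <- update_critic(net3, net3, tr1,
                        dqn_hyperparams(learn_rate = 1e-3, l2_factor = 0))
  after <- (q_forward(upd3, tr1$states)[1, 2] - 1.5)^2
  expect_lt(after, before)
  # empty batch is a no-op
  expect_identical(update_critic(net3, net3, NULL, hp0), net3)
})

test_that("soft updates interpolate the target parameters", {
  a <- q_network(seed = 1); b <- q_network(seed = 2)
  expect_equal(soft_update(a, b, tau = 1)$W, b$W)
  expect_equal(soft_update(a, b, tau = 0)$W, a$W)
  a$W[[1]][] <- 0; b$W[[1]][] <- 2
  expect_equal(soft_update(a, b, tau = 0.001)$W[[1]][1, 1], 0.002)
  expect_error(soft_update(a, q_network(c(2, 2))), "shapes")
})

test_that("the replay buffer overwrites oldest experiences first", {
  rb <- replay_buffer(capacity = 3, state_dim = 2)
  expect_equal(rb_size(rb), 0)
  for (k in 1:5)
    rb_add(rb, c(k, k), k %% 9 + 1, k * 10, c(-k, -k), k == 5)
  expect_equal(rb_size(rb), 3)
  # slots hold transitions 4, 5, 3 after wrapping twice
  expect_equal(rb$R, c(40, 50, 30))
  expect_equal(rb$S[3, ], c(3, 3))
  expect_equal(rb$terminal, c(FALSE, TRUE, FALSE))
  set.seed(1)
  b <- rb_sample(rb, 2)
  expect_length(b$actions, 2)
  expect_true(all(b$rewards %in% c(30, 40, 50)))
})
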