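# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no stored data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small mixed cohort with its trial dataset and fitted environment.
small_cohort <- function() fixture("small_cohort", function() {
  sample_cohort(cohort_spec(
    n_men = 3, n_women = 3,
    trials_per_nerve = c(peroneal = 60, tibial = 30, sural = 30),
    seed = 5))
})

small_trials <- function() fixture("small_trials", function() {
  generate_trials(small_cohort())
})

small_env <- function() fixture("small_env", function() {
  fit_environment(small_trials(), env_config(seed = 5))
})

# A convenient deterministic subject: threshold current 4 mA at the
# 250 us chronaxie point, pain at 3x rheobase.
ref_subject <- function() fixture("ref_subject", function() {
  virtual_subject("REF", gender = "M", weight = 75, nerve = "peroneal",
                  rheobase = 2, chronaxie = 250, pain_margin = 3)
})

# An agent whose greedy policy is the identity action in every state:
# zero weights, output bias one-hot on the hold action.
identity_agent <- function(level = "low") {
  net <- q_network(c(3, 40, 30, 9), seed = 1)
  for (i in seq_along(net$W)) net$W[[i]][] <- 0
  net$b[[length(net$b)]] <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  structure(list(level = level, net = net, target_net = net, epsilon = 0,
                 hp = dqn_hyperparams(), grid = stim_grid(),
                 rewards = reward_table(level),
                 log = tibble::tibble(), seed = 1L),
            class = "dqn_agent")
}

# A tiny hand-written trial dataset for the initialization rules.
init_dataset <- function() {
  tibble::tibble(
    subject_id = c("A", "A", "A", "B", "B", "C"),
    gender = c("M", "M", "M", "M", "M", "F"),
    weight_kg = 75,
    nerve = c("peroneal", "peroneal", "peroneal", "peroneal", "peroneal",
              "tibial"),
    neuropathic = 0L,
    pa_mA = c(2, 4, 5, 1, 3, 6),
    pw_us = c(100, 200, 300, 300, 400, 150),
    intensity = c("LOW", "HIGH", "TOOHIGH", "LOW", "HIGH", "LOW"),
    stype = "COM", location = "SOM", se = 0L)
}
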