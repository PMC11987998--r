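# shared fixtures, built in code once per test run

the_space <- default_space()

# a full 13-dimension setting with sane defaults, overridable per test
make_setting <- function(...) {
  vals <- list(n_layers = 1L, n_nodes = 4L, activation = "relu",
               kernel_init = "he_uniform", optimizer = "adam",
               learning_rate = 0.01, momentum = 0, decay = 0, dropout = 0,
               epochs = 15L, batch_size = 32L, l1 = 0, l2 = 0.001)
  over <- list(...)
  vals[names(over)] <- over
  new_setting(the_space, vals)
}

# candidate lists where every dimension is pinned except the overrides
make_candidates <- function(...) {
  cand <- list(n_layers = 1L, n_nodes = 4L, activation = "relu",
               kernel_init = "he_uniform", optimizer = "adam",
               learning_rate = 0.01, momentum = 0, decay = 0, dropout = 0,
               epochs = 15L, batch_size = 32L, l1 = 0, l2 = 0.001)
  over <- list(...)
  cand[names(over)] <- over
  cand
}

# a search log built from bare AUC values (no training), for analytics
log_from_aucs <- function(aucs, cycle = "custom", wall = 1) {
  recs <- lapply(seq_along(aucs), function(i) {
    threestage:::new_trial_record(make_setting(epochs = 5L + i),
                                  rep(aucs[i], 5), wall, cycle)
  })
  search_log(recs, cycle)
}

# small planted-signal cohort reused across model tests
signal_dataset <- function(seed = 7L, n = 160L) {
  generate_dataset(generator_config(n, 6, 0.3, effect_sizes = c(1.5, 1, 0, 0, 0, 0),
                                    seed = seed))
}
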