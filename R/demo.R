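# Desk-scale demonstration study: a small synthetic cohort and a compact
# three-stage schedule that exercise every cycle type in minutes on one
# CPU. The generator mirrors the statistical shape the search assumes
# (integer-coded predictors, imbalanced binary outcome, planted logistic
# signal); sizes are chosen so one full run stays in the tens of seconds.

#' Desk-scale demo study configuration
#'
#' `demo_dataset_config()` describes a small synthetic cohort (160 cases,
#' 6 coded predictors, 30% prevalence, two signal predictors with
#' log-odds 1.5 and 1.0 per level step -- Bayes AUC about 0.81).
#' `demo_search_config()` builds the matching three-stage schedule over
#' the full 13-dimension space: lean candidate lists that still span
#' good and poor values (extreme learning rates, undertrained epoch
#' counts, a symmetric constant initializer), Stage-2 capped at 16
#' settings, sweet-spot radius 1 with 12 settings per SSGS cycle, and a
#' 16-setting randomized cycle.
#'
#' @param n_cases Cohort size.
#' @param seed Generator seed.
#' @return A [generator_config()] / [three_stage_config()].
#' @export
demo_dataset_config <- function(n_cases = 160L, seed = 1L) {
  generator_config(n_cases, n_features = 6, positive_rate = 0.3,
                   n_levels_per_feature = 3,
                   effect_sizes = c(1.5, 1.0, 0, 0, 0, 0), seed = seed,
                   horizon_label = "demo")
}

#' @rdname demo_dataset_config
#' @export
demo_search_config <- function() {
  space <- default_space()
  candidates <- list(
    n_layers = c(1L, 2L),
    n_nodes = c(1L, 2L, 4L, 8L, 12L),
    activation = "relu",
    kernel_init = c("constant", "glorot_uniform", "he_uniform"),
    optimizer = c("adam", "sgd"),
    learning_rate = c(0.002, 0.01, 0.05, 0.15, 0.3),
    momentum = 0,
    decay = 0,
    dropout = c(0, 0.15, 0.3, 0.45),
    epochs = c(5L, 10L, 15L, 22L, 30L),
    batch_size = 32L,
    l1 = 0,
    l2 = 0.001)
  base <- new_setting(space, list(
    n_layers = 1L, n_nodes = 4L, activation = "relu",
    kernel_init = "he_uniform", optimizer = "adam", learning_rate = 0.01,
    momentum = 0, decay = 0, dropout = 0, epochs = 15L, batch_size = 32L,
    l1 = 0, l2 = 0.001))
  three_stage_config(space, candidates, base_setting = base,
                     stage2_max = 16L, ssgs_radius = 1L, ssgs_max = 12L,
                     rgs_n = 16L)
}
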