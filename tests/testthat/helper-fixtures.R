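# shared fixture builders; all data are generated in code

# small deterministic event table for likelihood arithmetic
toy_data <- function() {
  data.frame(
    individual_id = c("a", "a", "b", "b"),
    site = "site_1",
    activity = factor(c("drum", "stone", "stone_and_drum", "drum"),
                      levels = c("drum", "stone_and_drum", "stone")),
    period = "before",
    duration_s = c(1L, 10L, 30L, 61L),
    behaviour = "pant_hoot",
    occurred = c(1L, 0L, 1L, 1L),
    event_id = sprintf("ev_%05d", 1:4),
    stringsAsFactors = FALSE
  )
}

toy_design <- function(d = toy_data()) {
  list(y = d$occurred,
       X = model.matrix(~activity, d),
       id = d$individual_id,
       T = d$duration_s)
}

# medium recovery dataset used by several fitting tests
recovery_data <- function(seed = 11, n_individuals = 200,
                          events_per_individual = 10) {
  simulate_occurrence(sim_config(
    n_individuals = n_individuals,
    events_per_individual = events_per_individual,
    true_B = 0.05, true_beta = c(0.5, -0.5, 1.0), true_sigma = 1.0,
    seed = seed))
}

# random tiny instance for quadrature-vs-brute-force comparisons
random_small_instance <- function(seed) {
  set.seed(seed)
  G <- sample(2:10, 1)
  n_per <- sample(1:5, G, replace = TRUE)
  id <- rep(sprintf("i%02d", seq_len(G)), n_per)
  n <- length(id)
  X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
  list(beta = stats::rnorm(3, 0, 0.8),
       sigma = stats::runif(1, 0.2, 2),
       B = stats::runif(1, 0.01, 0.3),
       y = stats::rbinom(n, 1, 0.5),
       X = X, id = id,
       T = sample(1:61, n, replace = TRUE))
}
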