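## Small graphs reused across tests.

two_node_graph <- function() {
  relational_graph(c("a", "b"), rbind(c("a", "b")),
                   layout = rbind(a = c(0, 0), b = c(1, 0)))
}

triangle_graph <- function() {
  relational_graph(1:3, rbind(c(1, 2), c(2, 3), c(1, 3)))
}

path3_graph <- function() {
  relational_graph(1:3, rbind(c(1, 2), c(2, 3)))
}

## Shared ensemble for the 7-node / 7-edge null (enumeration is the costly
## step; memoised per test run).
ensemble_cache <- new.env(parent = emptyenv())
full_ensemble <- function() {
  if (is.null(ensemble_cache$e77)) {
    ensemble_cache$e77 <- enumerate_null_graphs(7, 7)
  }
  ensemble_cache$e77
}

## Noiseless link-metric cohort for end-to-end recovery tests.
noiseless_link_cohort <- function(n_subjects = 5L, seed = 101L) {
  simulate_adaptation_cohort(
    cohort_config(n_subjects = n_subjects, generative_metric = "link",
                  beta_metric = 1, object_effect_sd = 0, noise_sd = 0,
                  seed = seed),
    default_reduced_graph())
}
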