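# Small in-code fixtures shared across test files.

# hand-written four-record table exercising both formats
tiny_table_df <- function() {
  data.frame(
    person_id = c("p1", "p1", "p2", "p2"),
    item_id = c("E01", "E02", "E01", "E02"),
    trait = "E",
    occasion = 1L,
    format = c("VAS", "DRS", "VAS", "DRS"),
    value_low = c(65, 40, 20, 10),
    value_high = c(65, 90, 20, 55),
    reverse_coded = FALSE,
    block_order = "VAS_first",
    response_time_s = c(4, 7, 5, 6),
    serious = TRUE,
    stringsAsFactors = FALSE)
}

# complete simulated study at a configurable (small) scale
small_simulation <- function(n_persons = 20, items_per_trait = 4, seed = 7,
                             pop = reference_population()) {
  simulate_dataset(n_persons = n_persons, items_per_trait = items_per_trait,
                   seed = seed, pop = pop)
}

# quick sampler settings for fits inside unit tests
test_config <- function(...) {
  args <- list(chains = 2, iter = 100, warmup = 150, max_treedepth = 7,
               target_accept = 0.85, seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

expect_simplex <- function(x, tol = 1e-12) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  expect_true(all(abs(rowSums(x) - 1) < tol))
}
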