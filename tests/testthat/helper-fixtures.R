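# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-scale coupled spaces + lists + similarity table for one seed
default_run <- function(seed = 11L) {
  memo(paste0("run", seed), {
    spaces <- generate_coupled_spaces(generator_config(seed = seed))
    lists <- build_lists(spaces$vision, list_config(seed = seed))
    tab <- similarity_table(lists, spaces$vision, spaces$language)
    list(spaces = spaces, lists = lists, tab = tab)
  })
}

# small space with known geometry for oracle checks
toy_space <- function(n = 20L, d = 6L, seed = 3L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * d), n, d)
    embedding_space(m, sprintf("it%02d", seq_len(n)), modality = "vision")
  })
}

# tiny hand-coded trial table for counting oracles
toy_trials <- function() {
  tibble::tibble(
    participant_id = "p01",
    list_id = 1L,
    item_id = sprintf("i%02d", 1:9),
    role = c(rep("target", 4), rep("lure_close", 3), rep("lure_far", 2)),
    category = "animal",
    sim_vision_z = c(rep(NA, 4), rnorm(5)),
    sim_language_z = c(rep(NA, 4), rnorm(5)),
    response = c(1, 1, 1, 0, 1, 0, 0, 0, 0),
    gonogo_accuracy = 0.95)
}
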