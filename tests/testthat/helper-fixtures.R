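# Shared fixtures, built once per test run.

fixture_atlas <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_atlas(32)
    val
  }
})

# Small cohort + triage for table-level tests.
fixture_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- triage_cohort(generate_cohort(generator_config(n_samples = 300, seed = 42)))
    }
    val
  }
})

# A tiny 16^3 phantom set for fast network unit tests: strong signal,
# moderate noise, 12 per class.
fixture_tiny_volumes <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      set.seed(99)
      n_per <- 12L
      edge <- 16L
      mk <- function(label, i) {
        base <- array(1, c(edge, edge, edge))
        if (label == 1) base[4:9, 4:9, 4:9] <- 0.7  # focal hypometabolism
        base + array(stats::rnorm(edge^3, 0, 0.05), c(edge, edge, edge))
      }
      vols <- c(lapply(seq_len(n_per), mk, label = 1),
                lapply(seq_len(n_per), mk, label = 0))
      val <<- list(volumes = vols, labels = rep(c(1L, 0L), each = n_per))
    }
    val
  }
})

tiny_spec <- function() network_spec(input_edge = 16, n_blocks = 3,
                                     head_channels = 16)
tiny_config <- function(seed = 7, max_epochs = 12) {
  train_config(seed = seed, max_epochs = max_epochs)
}
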