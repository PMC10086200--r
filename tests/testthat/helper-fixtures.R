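# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

small_cohort <- function() {
  memo("small_cohort", function()
    generate_cohort(phantom_spec(n_patients = 4, rng_seed = 421)))
}

# full study-scale run shared by the acceptance tests
study_run <- function() {
  memo("study_run", function()
    run_pipeline(run_config(phantom = phantom_spec(n_patients = 86,
                                                   rng_seed = 20260927L),
                            seed = 1L)))
}

# a single small depot volume + mask for feature tests
toy_depot <- function() {
  memo("toy_depot", function() {
    set.seed(99)
    d <- c(6L, 16L, 16L)
    vals <- array(rnorm(prod(d), -100, 12), d)
    vol <- volume_grid(vals, c(5, 1, 1))
    mask <- array(0L, d)
    mask[2:5, 5:12, 5:12] <- 1L
    list(vol = vol, mask = mask)
  })
}
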