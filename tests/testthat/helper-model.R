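# shared fixtures: default config/model and the canonical noise-free runs
default_config <- function(...) sacc_config(...)

default_model <- function(cfg = default_config()) {
  discretize(build_plant(cfg), cfg)
}

# cached per test file; a 200-step noise-free rollout
canonical_saccade <- local({
  cache <- NULL
  function(cfg = default_config()) {
    if (is.null(cache)) {
      cache <<- run_closed_loop(make_saccade_task(20, cfg), cfg)
    }
    cache
  }
})

expect_symmetric_psd <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - t(M))), tol * max(1, max(abs(M))))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(1, max(ev)))
}
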