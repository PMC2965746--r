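# Shared fixtures: the reference habitat and a memoized preset runner so the
# long scenario integrations are performed once per test session.

ref_env <- function() chemostat_env()

preset_run <- local({
  cache <- new.env(parent = emptyenv())
  function(name, ...) {
    key <- paste(name, ..., sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- run_preset(name, ...)
    cache[[key]]
  }
})

# relative difference with a floor to avoid 0/0
rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-30)
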