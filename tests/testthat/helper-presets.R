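## Memoized full-scale preset experiments shared by the acceptance tests:
## the in-plane R=10 and SMS MB=4/R=3 study conditions are each run once
## per test session and reused by every criterion that inspects them.

.preset_cache <- new.env(parent = emptyenv())

cached_experiment <- function(preset, seed = 1L) {
  key <- paste0(preset, "_", seed)
  if (!exists(key, envir = .preset_cache)) {
    ex <- suppressWarnings(run_experiment(preset, seed = seed))
    assign(key, ex, envir = .preset_cache)
  }
  get(key, envir = .preset_cache)
}
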