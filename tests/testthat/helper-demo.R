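# The seeded demo runs are expensive (a few minutes each), so they are
# trained once per session and shared across test files.
.demo_cache <- new.env(parent = emptyenv())

cached_demo <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.demo_cache[[key]]))
    .demo_cache[[key]] <- demo_run(seed = seed)
  .demo_cache[[key]]
}
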