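# shared simulation runs, cached across test files (all noise-free and
# deterministic, so caching cannot leak state between tests)
.run_cache <- new.env(parent = emptyenv())

cached_stack <- function(name, ...) {
  key <- paste(name, ..., sep = "_")
  if (!exists(key, .run_cache)) {
    assign(key, generate_experiment(canned_config(name, ...)), .run_cache)
  }
  get(key, .run_cache)
}

cached_traces <- function(name, ...) {
  key <- paste("tr", name, ..., sep = "_")
  if (!exists(key, .run_cache)) {
    assign(key, extract_traces(cached_stack(name, ...)), .run_cache)
  }
  get(key, .run_cache)
}

roi_trace <- function(name, roi = 1, channel = NULL) {
  tr <- cached_traces(name)
  tr <- tr[tr$roi_id == roi, ]
  if (!is.null(channel)) tr <- tr[tr$channel == channel, ]
  tr
}

roi_ratio <- function(name, roi = 1) {
  key <- paste("rt", name, sep = "_")
  if (!exists(key, .run_cache)) {
    assign(key, pair_ratio(cached_traces(name)), .run_cache)
  }
  rt <- get(key, .run_cache)
  rt[rt$roi_id == roi, ]
}
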