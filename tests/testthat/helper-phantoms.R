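# Phantom generation is the expensive fixture; cache by (seed, corridor)
# so acceptance and module tests share one instance per configuration.
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(seed, corridor = "open") {
  key <- paste0("s", seed, "_", corridor)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(
      phantom_spec(seed = seed, corridor = corridor),
      verify = FALSE)
  .phantom_cache[[key]]
}

# ranked plans, cached alongside the phantom
cached_plan <- function(seed, method, corridor = "open", stride = 2) {
  key <- paste0("p", seed, "_", corridor, "_", method, "_", stride)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- plan_trajectories(
      cached_phantom(seed, corridor)$scene,
      spec = target_spec(method), stride = stride)
  .phantom_cache[[key]]
}
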