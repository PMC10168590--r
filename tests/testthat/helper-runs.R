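# Shared cache for expensive simulation runs reused by several test files
# (built lazily on first use within a test session).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache, inherits = FALSE)
}

# The desk-scale balanced layer of the parameter table (N = 2000, 4:1, P=0.1)
desk_layer <- function(seed = 301) {
  cached_run(paste0("layer_", seed), build_cortical_layer(N = 2000, seed = seed))
}

# 10 s sham epoch on the desk layer (amplitude 0), with weight snapshots
sham_run <- function() {
  cached_run("sham10", {
    net <- desk_layer()
    run_protocol(net, epoch_schedule(4, 10, 10), amplitude = 0,
                 frequency = 25, seed = 401)
  })
}

# Full pre/stim/post protocol at 25 Hz, A = 1 mV, heterogeneous layer
het_stim_run <- function() {
  cached_run("het25", {
    net <- desk_layer()
    run_protocol(net, epoch_schedule(4, 40, 60), amplitude = 1,
                 frequency = 25, seed = 402)
  })
}
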