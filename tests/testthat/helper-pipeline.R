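## Shared, lazily computed phantom pipeline runs.  Several test files
## exercise the same default-parameter phantoms; caching them keeps the
## suite inside a sensible runtime without changing what is tested.

.pipeline_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pipeline_cache))
    assign(key, expr, envir = .pipeline_cache)
  get(key, envir = .pipeline_cache)
}

cached_phantom <- function(seed, ...) {
  cached(paste0("ph_", seed, "_", paste(c(...), collapse = "_")),
         generate_phantom(phantom_params(seed = seed, ...)))
}

## preprocessing of every cycle-1 frame (barrier-independent)
cached_preprocessed <- function(seed) {
  cached(paste0("pp_", seed), {
    ph <- cached_phantom(seed)
    n1 <- ph$truth$params$frames_per_cycle
    lapply(0:(n1 - 1L), function(k) preprocess_frame(ph$sequence, k))
  })
}

## full pipeline run with the true initial barrier
cached_run <- function(seed) {
  cached(paste0("run_", seed), {
    ph <- cached_phantom(seed)
    segr <- segment_sequence(ph$sequence, true_initial_barrier(ph$truth),
                             preprocessed = cached_preprocessed(seed))
    list(phantom = ph, seg = segr, avc = build_avc(segr, ph$sequence))
  })
}

## small, fast phantom for structural tests
small_phantom_params <- function(seed = 11, ...) {
  phantom_params(image_size = c(128L, 128L), frames_per_cycle = 12L,
                 seed = seed, ...)
}
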