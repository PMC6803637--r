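# Shared simulation scenarios for the acceptance properties, built once per
# test run. Each scenario runs the full two-pass pipeline on a fixed seed.
.scenario_cache <- new.env(parent = emptyenv())

run_pipeline <- function(sim, config = denoiser_config()) {
  channel <- estimate_channel(sim$reads, t_m = config$t_m,
                              scheme = config$scheme)
  store <- count_contexts(sim$reads, channel, k = config$k)
  denoised <- denoise_reads(sim$reads, channel, store, config)
  list(sim = sim, channel = channel, store = store, denoised = denoised,
       report = attr(denoised, "report"))
}

scenario <- function(name) {
  if (!exists(name, envir = .scenario_cache)) {
    val <- switch(name,
      clean = run_pipeline(simulate_reads(
        ref_length = 5e4, coverage = 30, read_length = 100,
        error_by_bin = 0, seed = 20101)),
      noisy = run_pipeline(simulate_reads(
        ref_length = 1e5, coverage = 30, read_length = 100,
        error_by_bin = 0.01, seed = 20102)),
      het = run_pipeline(simulate_reads(
        ref_length = 5e4, coverage = 30, read_length = 100,
        error_by_bin = 0.01, het_rate = 1e-3, seed = 20103)),
      stop("unknown scenario: ", name))
    assign(name, val, envir = .scenario_cache)
  }
  get(name, envir = .scenario_cache)
}
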