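# shared fixtures and memoised heavy simulations

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# desk-scale constant-pH MC runs shared across test files.  The low-salt
# run is longer: the orientation profile converges more slowly in the
# adsorbed regime.
desk_run <- function(c_salt, seed = 1) {
  key <- paste0("desk_", c_salt)
  cached(key, {
    sys <- slit_system(n_tails = 32, c_salt = c_salt,
                       cutoff_el = "auto", cutoff_lj = 12)
    if (c_salt <= 0.05)
      cpmc_run(sys, n_equil = 3000, n_prod = 10000, sample_every = 5,
               seed = seed, runs = 2)
    else
      cpmc_run(sys, n_equil = 2000, n_prod = 6000, sample_every = 5,
               seed = seed, runs = 2)
  })
}

# the fig2-analog synthetic plate and its seeded fit
fig2_plate <- function() cached("fig2_plate", {
  simulate_plate(make_salt_series(rng_seed = 1L))
})

fig2_traces <- function() cached("fig2_traces", {
  pl <- fig2_plate()
  d <- tempfile("plate")
  paths <- write_plate(pl, d)
  read_plate(paths["plate"], paths["meta"])
})

fig2_fit <- function() cached("fig2_fit", {
  fit_salt_series(fig2_traces())
})

# small mixed system for energy bookkeeping tests
small_system <- function(...) {
  tail <- asyn_ctail()
  free <- protein_sequence(paste(rep("KEGD", 5), collapse = ""),
                           name = "toy20")
  slit_system(free_seq = free, tail_seq = tail, n_tails = 4,
              c_salt = 0.1, ...)
}

logistic_trace <- function(t, baseline, amplitude, t_half, width = 1,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- baseline + amplitude / (1 + exp(-(t - t_half) / width))
  if (noise_sd > 0) F <- F + rnorm(length(t), 0, noise_sd)
  F
}
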