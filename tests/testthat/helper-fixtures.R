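# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

nh_sim <- function() fixture("nh_sim",
  simulate_trial(hopper_params(n_hops = 10, seed = 7)))

g1_sim <- function() fixture("g1_sim",
  simulate_trial(hopper_params(n_hops = 10, seed = 3,
                               grf_shape_exponent = 1)))

dg_sim <- function() fixture("dg_sim",
  simulate_trial(hopper_params(n_hops = 20, seed = 7,
                               exo = prescribed_exo("DG", 66))))

dg_noisy_sim <- function() fixture("dg_noisy_sim",
  simulate_trial(hopper_params(n_hops = 20, seed = 7, marker_noise_sd = 0.001,
                               exo = prescribed_exo("DG", 66))))

ln_hyst_sim <- function() fixture("ln_hyst_sim",
  simulate_trial(hopper_params(n_hops = 10, seed = 11,
                               exo = prescribed_exo("LN", 66,
                                                    hysteresis_fraction = 0.2))))

pg_sim <- function() fixture("pg_sim",
  simulate_trial(hopper_params(n_hops = 10, seed = 5,
                               exo = prescribed_exo("PG", 66))))

nh_analysis <- function() fixture("nh_analysis", analyze_trial(nh_sim()$trial))
g1_analysis <- function() fixture("g1_analysis", analyze_trial(g1_sim()$trial))
dg_analysis <- function() fixture("dg_analysis", analyze_trial(dg_sim()$trial))
dg_noisy_analysis <- function() fixture("dg_noisy_analysis",
                                        analyze_trial(dg_noisy_sim()$trial))
ln_hyst_analysis <- function() fixture("ln_hyst_analysis",
                                       analyze_trial(ln_hyst_sim()$trial))
pg_analysis <- function() fixture("pg_analysis", analyze_trial(pg_sim()$trial))

# hand-built hop_cycles covering given [start, end] ranges on one grid
make_cycles <- function(start, end, toeoff, rate) {
  structure(list(
    onsets = start, toeoffs = toeoff,
    cycles = data.frame(start = start, end = end, toeoff = toeoff,
                        contact_time_s = (toeoff - start) / rate,
                        aerial_time_s = (end + 1L - toeoff) / rate,
                        aerial_fraction = (end + 1L - toeoff) /
                          (end + 1L - start)),
    rate = rate, threshold_n = 20), class = "hop_cycles")
}

# interior samples of the complete cycles (drops first/last cycle to stay
# clear of filter transients)
interior_cycle_samples <- function(analysis) {
  cyc <- analysis$cycles$cycles
  keep <- if (nrow(cyc) > 2) 2:(nrow(cyc) - 1) else seq_len(nrow(cyc))
  unlist(mapply(seq, cyc$start[keep], cyc$end[keep], SIMPLIFY = FALSE))
}
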