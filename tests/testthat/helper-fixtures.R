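# Shared fixtures for the suite.  Everything is generated in code; no data
# files are read from disk.

s1 <- calorimeter_s1()
s2 <- calorimeter_s2()

# short uniform grid for fast forward simulations
grid_30min <- seq(0, 1799)

# relative error helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# a steady noise-free bench record: constant Joule load on the plate
steady_bench_record <- function(params = s1, W1 = 0.05, W2 = 1,
                                Ipel = 0.09, Troom = 21.5,
                                t = grid_30min) {
  simulate_forward(params, forward_inputs(W1 = W1, W2 = W2, Ipel = Ipel,
                                          Troom = Troom), t)
}

# every (T2, phase) row of the bundled flux table as phase_fit objects
all_flux_fit_rows <- function() {
  tab <- subject_flux_fits()
  lapply(seq_len(nrow(tab)), function(i)
    preset_phase_fit(tab, tab$T2[i], tab$phase[i]))
}
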