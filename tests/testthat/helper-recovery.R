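# End-to-end minor-state recovery: synthesize two-state RDC data with known
# minor population p, run restrained replica annealing, and measure the
# recovered minor-basin fraction.  Shared by the acceptance tests.

recover_minor_population <- function(seed, p = 0.13) {
  toy <- make_toy_protein(generator_spec(minor_population = p))
  media <- calibrate_default_media(toy, n_orient = 144)
  two <- make_two_state_ensemble(toy, 200, seed = seed)
  rdc <- make_rdc_tables(two$ensemble, toy, media, seed = seed + 1000,
                         n_orient = 144)
  sys <- build_system(toy, toy_potential(), rdc, media, M = 16, alpha = 60,
                      n_orient = 144)
  sched <- annealing_schedule(cycles = 16, sweeps_high = 20, sweeps_low = 40,
                              collect_ps = 12, frames_per_ps = 1,
                              cycles_retained = 12, equil_sweeps = 60)
  res <- run_annealing(sys, sched, seed = seed)
  bp <- basin_population(res$ensemble, toy$regions,
                         basin_partition(two$truth$boundary))
  list(fraction = bp$fraction[bp$basin == "unlocked"], result = res,
       toy = toy, truth = two$truth, rdc = rdc, media = media)
}
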