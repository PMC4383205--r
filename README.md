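# rdcscape

Replica-averaged RDC-restrained ensembles and interdomain free-energy
landscapes, with a ground-truth synthetic test bed.

## What it is for

Two-domain enzymes can populate low-population ("unlocked") interdomain
states — a few percent of the ensemble — that standard structure
determination never sees but that control steps such as product release.
Residual dipolar couplings (RDCs) measured in weakly aligning media
average over the whole conformational distribution, so such states leave
a quantitative imprint on the data.  `rdcscape` is for structural-NMR
computational work that turns RDC tables into conformational ensembles
and free-energy landscapes, and for validating those ensembles against
independent NMR observables.

The core machinery:

* **RDC back-calculation** from an alignment tensor,
  `D = D_max * sum_ij A_ij cos(phi_i) cos(phi_j)`, with the tensor either
  **predicted from molecular shape and charge** (steric obstruction +
  screened-wall Boltzmann weighting over a spherical Fibonacci
  orientation grid) or **fitted by SVD** as a validation mode.
* **Replica-averaged maximum-entropy restraints**:
  `E_RDC = alpha * sum_i (D_exp_i - D_calc_i)^2` where
  `D_calc = (1/M) * sum_m D_m` over M replicas, added to the
  conformational energy (`E_Tot = E_Pot + E_RDC`) and sampled by
  simulated-annealing Metropolis Monte Carlo with the standard cycle /
  collection bookkeeping (e.g. 16 replicas, 50 cycles between 310 and
  500 K, frames from the final 50 ps of the final 30 cycles = 24,000
  structures).
* **Landscape analysis**: breathing angle theta from three region
  centres of mass, Kabsch-superposed RMSD, free-energy surfaces
  `F = -kB T ln H(theta, RMSD)`, basin populations/centres, and
  hydrogen-bond/contact occupancy per basin.
* **Validation**: per-medium Q factors, 3J(HN-Ha) extraction from HNHA
  cross/diagonal intensity ratios (`I_X/I_D = -tan^2(2 pi xi 3J)`,
  xi = 13.05 ms) with first-order error propagation, Karplus
  back-calculation, and per-structure NOE satisfaction.
* **A synthetic-data generator** producing a two-domain toy protein, a
  two-state ensemble with a known minor-state population, noisy
  population-averaged RDC tables in a steric and a charged medium, HNHA
  intensities from known J values, and NOE bounds — each with stored
  ground truth, so the whole pipeline is verifiable end to end.

## Worked example

Generate a synthetic study with a 13% unlocked population, refine an
ensemble against the noisy RDC tables, and measure the recovered
population:

```r
library(rdcscape)

toy   <- make_toy_protein(generator_spec(minor_population = 0.13))
media <- calibrate_default_media(toy, n_orient = 144)
two   <- make_two_state_ensemble(toy, 200, seed = 1)
rdc   <- make_rdc_tables(two$ensemble, toy, media, seed = 1001,
                         n_orient = 144)

sys   <- build_system(toy, toy_potential(), rdc, media, M = 16)
sched <- annealing_schedule(cycles = 16, sweeps_high = 20, sweeps_low = 40,
                            collect_ps = 12, cycles_retained = 12,
                            equil_sweeps = 60)
run   <- run_annealing(sys, sched, seed = 1)

basin_population(run$ensemble, toy$regions,
                 basin_partition(two$truth$boundary))
#>      basin  fraction mean_theta mode_theta mean_rmsd
#> 1 unlocked 0.1666667   49.16519         49        NA
#> 2   locked 0.8333333   58.12839         58        NA
```

The unlocked fraction (0.167 here; the mean over seeds 1-5 is 0.133)
recovers the generator's 13% truth, and the basin centres sit at the
generator's 49 and 58 degrees.  The same frames feed
`free_energy_surface()` for the `-kB T ln H` landscape and
`build_report()` for Q factors, 3J RMSD and NOE satisfaction.

A thin command-line front end is installed with the package
(`system.file("cli", "rdcscape", package = "rdcscape")`) with
subcommands `simulate`, `sample`, `landscape`, `validate` and `jcouple`,
each accepting `--config` (YAML, validated against
`default_config()`) and `--seed`.

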