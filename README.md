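# qstab

Relative thermal-stability analysis of single-domain antibodies (and other
small protein domains) from trajectory ensembles, via the soft fraction of
native contacts.

## The problem

Single-domain antibodies (VHH/sdAb) vary widely in melting temperature
(roughly 47–85 °C across typical panels), and measuring Tm for every
engineered candidate is slow. Given a reference crystal structure and a set
of replica trajectories (e.g. elevated-temperature MD), qstab computes an
order parameter that ranks systems by relative stability and pinpoints the
residues that lose their native environment first — the natural targets for
stabilizing mutations.

## The statistic

For a frame of a trajectory, the soft fraction of native contacts is

```
Q = (1/N) Σ_(i,j) 1 / (1 + exp[ β (r_ij − λ r0_ij) ])
```

summed over the N *native pairs*: heavy-atom pairs closer than 4.5 Å in the
reference structure whose residues are more than 3 apart in sequence. r0 is
the native distance, r the frame distance, β = 5 Å⁻¹ and λ = 1.8 by default
(all configurable, all echoed into reports). qstab computes Q for the whole
molecule, for residue-group selections (hydrophilic / hydrophobic / small,
e.g. the hydrophilic–all and hydrophobic–small masks), and per residue.
Headline numbers are means over the final 30% of each replica, pooled
across replicas. A residue whose final-window Q drops below 0.6 in a
replica is flagged *unstable*; residues with fewer than 30 native contacts
are *excluded* as unreliable. Per-system Q averages are correlated with
experimental Tm (Pearson), and variant panels are compared side by side
against a wild type.

Because validating this machinery needs ensembles with known ground truth,
the package ships a deterministic synthetic-trajectory generator: compact
toy folds in which chosen residues coherently lose their contacts at a
chosen time, with replica-to-replica variation from seeded substreams and
optional rigid-body drift. `make_benchmark_suite()` builds a 7-system panel
whose designed instability decreases strictly with pseudo-Tm.

## Worked example

Simulate a 60-residue system in which residues 10, 26 and 43 (author
numbering) are designed to unfold halfway through the run, then analyse it:

```r
library(qstab)

spec <- toy_system_spec(seed = 1, n_replicas = 4, n_frames = 60,
                        unstable_residues = c(9L, 25L, 42L))
s   <- make_toy_structure(spec)
ens <- simulate_ensemble(s, spec)
rep <- analyze_system(s, ens)
rep
#> <stability_report> toy060_seed1 (4 replicas)
#>   all-all Q 0.861 (0.012); backbone RMSD 0.334 nm (0.093)
#>   4 unstable residue(s); 9 excluded (<30 contacts)

rep$detection$per_residue
#> # A tibble: 4 x 6
#>   residue_index residue n_contacts in_cdr n_replicas_affected mean_q
#>           <int> <chr>        <int> <lgl>                <int>  <dbl>
#> 1             9 Trp10           55 FALSE                    4 0.0360
#> 2            14 Cys15           31 FALSE                    4 0.486
#> 3            25 Thr26           87 FALSE                    4 0.0469
#> 4            42 Lys43           85 FALSE                    4 0.0341
```

All three designed residues are recovered in all four replicas (mean
final-window Q near 0, far below the 0.6 threshold); residue 15 is a
genuine secondary casualty — roughly half of its 31 native contacts are to
residue 10, so its own Q drops with it. The all–all Q of 0.861 reflects a
system with three unfolding residues; a zero-instability twin of this
system scores ≈ 0.98. `tidy(rep)` returns the ten Q selections as a
tibble, `glance(rep)` a one-row summary, and `autoplot(rep)` the
per-residue Q plot. `run_analysis()` drives the same pipeline from a YAML
config of PDB files and writes CSV/JSON reports;
`inst/scripts/qstab.R` wraps it for the shell.

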