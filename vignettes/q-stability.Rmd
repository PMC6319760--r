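---
title: "Estimating relative thermal stability from native-contact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative thermal stability from native-contact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstab)
```

## The problem

Single-domain antibodies (sdAb, VHH) are attractive scaffolds for
engineering because the heavy-chain variable domain folds and binds antigen
on its own, but candidates vary widely in thermal stability: melting
temperatures across natural and engineered panels commonly span roughly
47–85 °C. Measuring Tm for every design is slow; a computational readout
that ranks candidates by relative stability — and points at the specific
residues responsible for instability — shortens the engineering loop.

qstab implements that readout as a post-processing layer over
molecular-dynamics (or any conformational-ensemble) trajectories. It never
runs dynamics itself: its inputs are a reference crystal structure, replica
trajectories of the same system, and (optionally) experimental Tm values
and CDR-loop annotations.

## The order parameter

The core quantity is the soft fraction of native contacts of a frame,

$$Q = \frac{1}{N} \sum_{(i,j)} \frac{1}{1 + \exp\!\big[\beta\,(r_{ij} -
\lambda\, r^0_{ij})\big]},$$

where the sum runs over the $N$ native pairs: heavy-atom pairs closer than
a cutoff (default 4.5 Å, strict `<`) in the reference structure, with the
two atoms in residues separated by more than 3 positions in sequence.
$r^0_{ij}$ is the pair's native distance, $r_{ij}$ its distance in the
frame, $\beta$ (default 5 Å⁻¹) sets the sharpness of the switching
function, and $\lambda \ge 1$ (default 1.8) the tolerated swelling of a
native distance. $Q$ is 1 for a perfectly native frame and decays towards
0 as contacts break; each pair's contribution is strictly decreasing in
$r_{ij}$, so uniform expansion can never raise $Q$. The logistic is
evaluated through `plogis()`, so fully unfolded frames underflow cleanly
instead of overflowing.

The contact-definition and kernel constants are the established defaults
of this order parameter; because ranking results do depend on them, they
are configurable everywhere and echoed into every report's provenance
block. Tie distances exactly at the cutoff are excluded (strict
comparison) so the contact set is deterministic.

Two exact decompositions underpin everything downstream, and are enforced
in the test suite to 1e-10:

* the six unordered pairings of the residue groups partition the contact
  set, and the pair-count-weighted sum of their $Q$ values rebuilds the
  all–all $Q$ frame by frame;
* the contact-count-weighted mean of per-residue $Q$ (each pair counted in
  both of its residues) also rebuilds the all–all $Q$.

## Residue groups and selections

Residues are partitioned into three physicochemical groups: hydrophilic
(Asp, Glu, Gln, Asn, Arg, Lys, His), hydrophobic (Phe, Tyr, Trp, Leu, Val,
Ile, Met, Cys, Pro) and small (Gly, Ala, Ser, Thr). A residue name outside
the 20 standard amino acids is an explicit error, never a silent default.
Every analysis computes ten standard selections: all–all, the three
group-vs-all masks, and the six disjoint group pairs. Masking is
unordered: a pair belongs to (hydrophobic, small) if either member is
hydrophobic and the other small.

## Windows, unstable residues, and exclusion

All headline numbers are averages over the final analysis window: within
each replica, frames with $t \ge (1 - f)\,t_\mathrm{end}$, with $f = 0.3$
by default — the final-30%-of-run convention (the final 30 ns of a 100 ns
production run), expressed as a fraction so shortened synthetic runs scale
correctly; an absolute-ns mode is available. The headline mean and SD pool
the selected frames across replicas — the pooled SD captures both intra-
and inter-replica spread, which is what makes high-temperature error bars
grow — and per-replica means are retained for alternative summaries.

A residue is *unstable in a replica* when its per-residue final-window
mean $Q$ falls strictly below 0.6. Residues with fewer than 30 native
atomic contacts (strict `<`) have too little signal for a reliable
per-residue $Q$; they are listed separately as *excluded* and are never
flagged. Both thresholds are parameters with those defaults. Flagging is
monotone: raising the $Q$ threshold never unflags a (residue, replica);
raising the contact minimum never adds one.

Composition statistics weight each flagged residue by the number of
replicas it was flagged in; group stability percentages are
$100\,(1 - a_g / (m_g\,R))$ with $a_g$ the affected (residue, replica)
slots in group $g$, $m_g$ the group size after exclusions and $R$ the
replica count. Per-system $Q$ means are correlated with experimental Tm by
the plain Pearson coefficient (at least 3 systems, nonzero variance; no
multiple-testing correction is applied and $n$ is always reported
alongside $r$). For the per-system average of per-residue $Q$ the mean
over residues is unweighted by default, with a contact-weighted option.

## Structure handling

PDB reading is delegated to bio3d. Internal residue indices are 0-based
and contiguous; all user-facing tables print author numbering ("Trp47").
Alternate locations resolve to the highest occupancy (ties keep the first
record). Waters, ions and heteroatoms are dropped at load unless
explicitly retained; ACE/NME capping groups are folded into the adjacent
terminal residue, so cap atoms count for contacts but never appear as
separate rows in per-residue reports. Coordinates are Å throughout; RMSD
is reported in nm to match the convention of stability tables. The
backbone for RMSD is N, Cα, C, O (configurable); superposition is the
least-squares rigid fit (bio3d's Kabsch implementation), with the RMS
deviation recomputed at full precision, and the test suite cross-checks it
against an independently implemented quaternion (Horn) solution to 1e-9.
Trajectories are read from multi-model PDB (always) or DCD; frames must
match the reference atom ordering exactly, and frame times are assigned
from a configurable save interval. No periodic-boundary minimum-image
correction is applied: the analysis assumes a whole, unwrapped solute.

## The synthetic generator

Validating the pipeline requires ensembles whose ground truth is known
exactly, which microsecond MD cannot provide at desk scale. The generator
therefore produces *designed* instability rather than physical dynamics:

* **Structure.** Residues are placed along a boustrophedon path through a
  compact 3-D lattice (spacing 3.9 Å) with five heavy atoms per residue in
  a fixed local geometry plus ±0.15 Å seeded jitter. The spacing was
  chosen once so that, at default contact parameters, the large majority
  of the 60 default residues carry ≥ 30 native contacts while a minority
  near chain termini and lattice turns fall below — so the exclusion rule
  is exercised by construction. Steric clashes (< 1 Å) trigger bounded
  regeneration.
* **Trajectories.** Frame $t$ is the native structure plus isotropic
  Gaussian jitter (σ₀ = 0.3 Å), plus, for each designed unstable residue,
  a coherent displacement of its atoms along a random per-replica
  direction that smooth-steps from zero at onset fraction τ (default 0.5,
  i.e. halfway through the run) to the full amplitude s (default 20 Å) at
  the end; optional rigid-body rotation/translation drift exercises the
  superposition step. Ten replicas of 200 frames spanning a nominal
  100 ns are the default, a scaled stand-in for 10 ps save intervals.
  Replicas draw from independent substreams of one master seed, so every
  ensemble is bitwise reproducible.
* **Benchmark.** `make_benchmark_suite()` emulates a 7-member panel with
  pseudo-Tm values spread 46.75–85 °C and a designed unstable-residue
  count strictly decreasing in pseudo-Tm (9 down to 1, amplitude 20 Å,
  onset 0.5). Running the full pipeline over the suite recovers a strong
  positive Pearson correlation between final-window all–all $Q$ and
  pseudo-Tm, and reversing the gradient flips the sign.

What the generator does *not* emulate — and hence what green tests do not
establish about real data — is everything thermodynamic: there is no force
field, no temperature dependence, no cooperative unfolding pathway, no
solvent, and contact loss is imposed rather than emergent. The generator
validates the *measurement machinery* (contact definitions, kernels,
windows, decision rules, bookkeeping), not the scientific claim that $Q$
from explicit-solvent MD tracks experimental Tm; that claim can only be
probed by feeding real trajectory ensembles through the same interfaces.

## Numerical and design choices

* Contact pairs are stored sorted by atom serial; all set operations are
  deterministic, and two runs from one configuration are byte-identical
  on disk (asserted in the tests).
* The variance convention for headline SDs is the sample SD over pooled
  window frames. This was genuinely open; per-replica means remain
  available for the alternative.
* Mutant/variant comparison refuses to compare reports produced with
  different contact, kernel or window parameters rather than warn.
* Selections with no contacts (possible in tiny systems) yield a warning
  and are dropped pairwise from correlations instead of aborting a run.
* Problem sizes in the shipped tests and the acceptance script — 60-residue
  systems, 10 replicas × 200 frames, 7-system benchmark — were chosen as
  the smallest sizes at which every decision rule (exclusion, flagging,
  ranking, reversal) is exercised with comfortable margins.

## Known limitations

Relative ranking only: nothing here predicts absolute Tm. Results depend
on the reference crystal structure; domains crystallised in complex (with
a partner chain or antigen) can score as artificially unstable once the
partner is removed. Contact parameters are convention, not ground truth,
and are therefore carried in every report. mmCIF input, structure repair,
protonation and mutant side-chain building are out of scope — mutant
structures are consumed ready-made.
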