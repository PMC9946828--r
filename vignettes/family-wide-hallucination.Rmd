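---
title: "Family-wide hallucination: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-wide hallucination: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famhal)
```

## The problem

De novo scaffold generation by *family-wide hallucination* searches sequence
space for proteins that fold into a target family's topology (for example the
NTF2-like superfamily) while leaving loop regions free to be reinvented. The
search is guided by a structure-prediction oracle that maps a sequence to
*distograms*: for every residue pair, categorical distributions over binned
values of six inter-residue coordinates — the C&beta;–C&beta; distance *d*,
the dihedral &omega; (CA–CB–CB–CA), the directional dihedral &theta;
(N–CA–CB–CB) and the directional planar angle &phi; (CA–CB–CB), the latter
two evaluated in both pair directions.

The loss has two components, split by region:

* **Structurally conserved regions (SCRs)** — alignment columns shared across
  the family — are scored by *consistency with family-derived restraints*:
  the cross-entropy of the predicted distributions against per-column-pair
  restraint distributions pooled from an ensemble of experimental family
  structures.
* **Variable regions** (loops) are scored by *confidence*: the negative mean
  KL divergence of predictions from a background distribution, where the
  background is the oracle's mean output over random sequences. Minimizing
  the total therefore pushes loop-pair predictions away from "don't know".

A simulated-annealing Metropolis Monte Carlo search over sequences —
substitutions anywhere except frozen positions, insertions and deletions
confined to variable loops within bounds — minimizes the weighted sum.
Frozen positions stand in for preserved hydrogen-bond-network residues.

## Geometry and discretization

Geometries are computed from backbone atoms with C&beta; reconstructed at
ideal internal coordinates (CA–CB 1.522 &Aring;, N–CA–CB 110.4&deg;,
C–N–CA–CB −122.5&deg;), including glycine. Dihedral signs follow the
standard convention (the canonical four-point example
(0,0,0),(1,0,0),(1,1,0),(1,1,1) gives +90&deg;, matching bio3d and biotite).

The default `bin_spec()` uses 36 distance bins of 0.5 &Aring; over
[2, 20) &Aring; plus one no-contact bin at the 20 &Aring; cutoff; 24 bins of
15&deg; for &omega; and &theta;; 12 bins of 15&deg; for &phi;. Each angular
channel carries a paired no-contact bin so that non-contact pairs occupy a
well-defined category in all channels; restraining those pairs is deliberate
("these columns sit apart" is information). Intervals are half-open
[lower, upper); the seam value +180&deg; belongs to the last angular bin.
All edges are configurable because the discretization used to pool any
particular restraint set may differ; the binning is validated against an
independent linear-search oracle in the tests.

## Family profile

Conserved/variable classification is gap-fraction thresholding on the family
alignment (default threshold 0.3) followed by demotion of conserved runs
shorter than 3 columns; both knobs are exposed since curated families may
warrant different settings. Loop length bounds default to (observed min − 1,
observed max + 1), clamped at zero.

Restraints are stored per *alignment-column* pair, not per residue pair, so
indels in loops never invalidate them. Pooling is a histogram over member
observations plus a pseudocount &epsilon; per bin (default 1/K for a
K-bin channel), which keeps every log term finite while barely moving
well-supported histograms. Whether one should histogram or fit smoothed
densities over a family ensemble is a genuinely open choice; the histogram
is transparent and exactly recountable, which the oracle-equivalence tests
exploit.

## Predictor contract, surrogate and background

Any predictor is a deterministic map from a sequence to normalized per-pair
distributions over the shared bins, with symmetric *d*/&omega; channels
(asymmetric outputs are symmetrized by averaging the two pair orders).
Implementations register by name; trained networks can be adapters later.

The shipped **surrogate** makes the framework testable without weights. For
a query it emits, per pair, the mixture

&nbsp;&nbsp;&nbsp;&nbsp;s &middot; onehot(template geometry) + (1 − s) &middot; uniform,

with s = logistic(&kappa; &middot; m), m the mean per-position compatibility
of the query with a position-specific score matrix over scored template
positions. The diffuse component is the uniform distribution — not the
computed background — because the background is *defined* as the mean
prediction over random sequences and must remain derivable from the
predictor rather than be an input to it. Conserved segments map 1:1 to the
template; loop residues map proportionally into the template loop; residues
of loops grown beyond the template's length are unmapped and their pairs
stay diffuse. Compatibility weights are signed (+1 for the planted residue,
−1 otherwise in planted problems; rows of NA mark unscored loop positions)
so that m spans [−1, 1] and s is not floored at 1/2.

The background pools predictions of `n_sequences = 100` uniformly random
sequences over all ordered pairs, floors every bin at 10<sup>−8</sup> and
renormalizes, guaranteeing finite KL terms. An optional stratification by
sequence-separation bands ({<6, 6–11, &ge;12}) records the open question of
whether backgrounds should be separation-specific; it is off by default.

## Losses

The restraint term is a cross-entropy, −&Sigma; r log p&#770;, rather than
KL(r &parallel; p&#770;): the two differ by the entropy of the fixed
restraints, so minimizers and all move deltas are identical, and
cross-entropy avoids rescoring constants. The confidence term is
−mean KL(p&#770; &parallel; background) over pairs touching at least one
variable position; the KL direction (prediction first) matters and is
pinned by an asymmetric worked example in the tests
(KL((.5,.5) &parallel; (.25,.75)) &asymp; 0.1438 nats).

Both terms are **means** over pairs and channels (weights default to 1, with
the directional &theta;/&phi; slots sharing one weight per channel), so
indel moves that change pair counts do not change the loss scale — a
deliberate bias-removal choice. Default component weights are 1/1; nats
throughout; log floor 10<sup>−8</sup>.

## MCMC

Moves are drawn as substitute/insert/delete with probabilities
(0.85, 0.075, 0.075) by default, renormalized over currently legal kinds;
substitution positions are uniform over non-frozen positions and residues
uniform over the alphabet minus the current letter; insertions pick a
uniform non-maxed loop and slot; deletions a uniform non-minimal loop and
residue. Acceptance is standard Metropolis, min(1, exp(−&Delta;L/T)), with
a geometric temperature schedule. "Best" is the first state attaining the
minimum total loss. A single seeded RNG stream drives every draw in a fixed
order, so identical (seed, config, inputs) reproduce trajectories
byte-for-byte; predictions may be cached by sequence since predictors are
deterministic.

All protocol constants (schedule, move ratios, alphabet — cysteine can be
excluded by config, a common hallucination practice) are package defaults
exposed in the config file; they are choices of this implementation, not
values taken from any particular production campaign.

## The synthetic family generator, and what passing tests do and do not show

`make_toy_family()` builds families from ideal torsion segments (helix
−57/−47, strand −139/135, generic loop −70/140, all trans) with Gaussian
coordinate jitter and per-member loop lengths drawn from a range; the
emitted alignment left-aligns loop residues so its gap pattern encodes the
constructed loop lengths exactly. This emulates the *structure* of a family
— shared segments, variable loops — but not real-family features: no
side-chain packing, no compact tertiary topology, no correlated
evolutionary variation, no alignment error. Tests passing on toy families
show the machinery (pooling, mapping, losses, search bookkeeping) is
correct; they do not show that hallucinated sequences would fold.

`make_planted_problem()` bundles a family, a surrogate whose compatibility
matrix peaks at a planted conserved-region sequence, a background, and a
random start. The bundle uses a geometrically degenerate family (zero
jitter, equal loop lengths) and an *unsmoothed* profile: with any restraint
mass off the template bin, the restraint cross-entropy grows without bound
as the prediction sharpens (the floored log of a vanishing off-bin mass),
so the total-loss optimum moves to an interior confidence value and the
planted sequence would no longer be the exact argmin. With one-hot
restraints the total loss is strictly decreasing in s, hence uniquely
minimized at the planted sequence — which the constructor verifies
empirically against 1,000 random sequences, failing loudly otherwise.

The reference recovery experiment (`planted_18mer_spec()`) plants an
18-residue conserved sequence (9-helix + 3-loop + 9-strand, 21 residues
total) and runs 20 seeds of 2,000 annealed steps each with schedule
T = 0.05 &rarr; 5&times;10<sup>−4</sup> (geometric) and move probabilities
(0.9, 0.05, 0.05). Under these conditions a majority of seeds recover the
planted conserved sequence exactly; the limiting factor is simply whether
the last wrong position is drawn with the right residue within the step
budget (a coupon-collector tail), so exact recovery in every seed is not
expected. Problem sizes throughout the tests (families of 3–8 members,
10–25 residues, hundreds-to-thousands of MCMC steps) were chosen as the
smallest scales at which each property is meaningfully exercised.

## Degenerate inputs and numerical corners

* Pairs with zero family support carry the uniform restraint and support 0.
* An empty variable-pair set makes the confidence term 0 with a notice.
* Distances at or beyond the cutoff, and all channels of non-contact pairs,
  map to no-contact bins; values below the first distance edge clamp into
  bin 1 (sub-2 &Aring; C&beta; pairs are physically implausible and treated
  as closest-bin).
* d(i,i) is exactly zero by construction; &omega; symmetry and
  &theta;/&phi; transposition identities hold to 10<sup>−6</sup> degrees.
* `kappa = 0` is rejected; `kappa` &rarr; 0 yields the fixed half-mixture.
* Proposals are resampled only among legal kinds; a state with all loops at
  their bounds and every position frozen raises a no-legal-move error.

## The synthetic design model

`make_synthetic_design_model()` builds a 117-residue single-chain model with
an arginine at position 65, an explicit guanidinium CZ atom, and a minimal
DTZ-like ligand group whose N1 atom is placed 4.2 &Aring; from that CZ. It
is a synthetic stand-in used to exercise the inspection utilities
(`residue_count()`, `chain_mass()`, `atom_distance()`) end to end — it is
generated by code and is not a published design model. The "centre of the
guanidinium cation" is mapped to the CZ atom, which is the centroid of the
three guanidinium nitrogens by construction; one-decimal reporting absorbs
alternative centre definitions.

## Known limitations

* The surrogate's energy landscape is a single-basin logistic in sequence
  compatibility; it cannot model epistasis, competing folds, or the rugged
  landscapes of trained networks.
* Restraint pooling assumes the supplied alignment is correct; there is no
  structure-based realignment.
* Only single-chain design; no gradient-based search; no auxiliary losses
  (radius of gyration, ligand terms).
* mmCIF input, side-chain building beyond C&beta;, and hydrogen placement
  are out of scope.
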