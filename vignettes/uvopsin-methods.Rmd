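---
title: "Methods: SWS1 spectral tuning, duplication and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWS1 spectral tuning, duplication and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvopsin)
library(dplyr)
```

`uvopsin` implements the analysis chain used to study ultraviolet vision in
damselfishes and related reef fishes: from opsin protein sequences to
tuning-site profiles and λ_max estimates, from trees and copy-number
matrices to ancestral states and duplication events, and from read counts
and spectra to expression profiles and UV-capability calls. This vignette
explains the models and conventions behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Anchored numbering and tuning-site extraction

Opsin residue positions are conventionally reported in the coordinate
space of the 348-residue bovine rhodopsin (UniProt P02699; PDB 1U19),
which ships with the package. `align_to_anchor()` performs a global
Needleman–Wunsch alignment of the query against this anchor and converts
it into a monotone position map. Because the numbering convention is not
tied to any particular aligner, we chose the standard protein scoring that
any practitioner would reach for — BLOSUM62 with affine gaps (open 10,
extend 1) — and a deterministic traceback, so site extraction is
reproducible; any reasonable global aligner recovers the same homologous
sites for true opsins, which is what the round-trip simulation tests
verify. Queries shorter than 50 residues are rejected outright: a fragment
that short cannot establish homologous numbering reliably.

The canonical SWS1 tuning-site list covers the retinal binding pocket and
transmembrane regions I (46, 49, 52), II (86, 90, 91, 93, 97), III (109,
113, 114, 116, 118) and VI (265). Site 125, a binding-pocket position
showing polarity shifts (S125A) across lineages, is extracted and
polarity-flagged but deliberately excluded from λ_max arithmetic: it is a
*putative* tuning site whose spectral effect has not been measured, and
adding an unmeasured effect would contaminate the estimates. Ambiguity
codes (X, and B/Z/J, which are normalised to X) are reported as ambiguous;
sites aligned to gaps are reported missing — neither is ever silently
treated as a residue.

## λ_max estimation

The estimator follows the comparative logic used throughout the visual
pigment literature: find the reference pigment (known λ_max from in-vitro
expression or microspectrophotometry) whose tuning-site profile is closest
to the query, then add or subtract the known spectral effect of each
mismatched site,

λ_max(query) = λ_max(reference) + Σ Δ(site, ref→query),

with effects applied in either direction with the sign flipped
(Δ(B→A) = −Δ(A→B)).

Three conventions matter here:

- **Ranking and ties.** References are ranked by mismatch count over the
  sites observed in both profiles. Ties are broken deterministically:
  damselfish references first (a within-family reference shares more
  genetic background), then in-vitro before MSP (purified-protein
  measurements are cleaner), then lexicographic species id. This makes the
  estimate invariant to panel row order, which is property-tested.
- **Non-additivity guard.** Single-site effects in SWS1 are usually not
  additive, so the estimator refuses to chain across substitutions it has
  no measured effect for: if more than `homology_threshold` (default 0)
  mismatched sites lack a packaged effect, the estimate is UNDETERMINED
  with the offending sites named. Profiles with any ambiguous tuning site
  are likewise UNDETERMINED. Refusing is always preferred to guessing.
- **Chromophore.** All arithmetic assumes an A1 (11-cis retinal)
  chromophore, the norm in marine fishes; no A2 conversion is provided.

The packaged site-effect table carries A118S = +5 nm (an experimentally
established shift) and a default A114S = +5 nm. The A114S magnitude is a
package default, not a measured value: it is chosen so that the joint
A114/A118 short↔long shift equals the ~10 nm split observed between the
damselfish SWS1 classes and so that a single-site duplicate gap falls
inside the 3–9 nm window expected for the *Chromis*-type duplicate pair.
Both entries carry provenance strings and can be replaced wholesale via
`read_site_effects()`.

The packaged reference panel is **synthetic** (and named so in its file):
published panels do not print their reference λ_max values in reusable
form, so the default panel uses the published in-vitro values for the
three standard model species (Nile tilapia 360 nm, zebra mbuna 368 nm,
medaka 356 nm) and damselfish MSP placeholders consistent with the short
(356–362 nm) and long (368–370 nm) classes, with consensus site profiles.
For real analyses, users should supply a curated panel via
`read_reference_panel()`.

`classify_variant()` applies the class boundaries inclusively at their
endpoints; values strictly between 362 and 368 nm are "intermediate", and
anything outside all ranges is "unclassified" — never coerced into the
nearest class.

## Ancestral reconstruction

Two reconstruction methods are provided so claims about ancestral pigments
can be probed under both a parsimony and a probabilistic model; the
default reported method is ML, with parsimony as the cross-check.

**Parsimony.** `fitch_states()` and `count_gain_events()` share one
weighted small-parsimony (Sankoff) engine. For unit costs the per-node
minimum-cost state sets coincide with the classical Fitch bottom-up sets
on binary trees and generalise them to multifurcations; the engine is
verified against brute-force enumeration of all internal assignments on
trees of up to 7 tips (100 seeded instances) and against an independent
library implementation. A concrete labelling is produced by a
deterministic top-down pass: the root takes the alphabetically first
minimum-cost state, and each child keeps its parent's state whenever that
is optimal, otherwise the alphabetically first optimal state. For
presence/absence characters this tie-break defers changes tipward — among
co-optimal histories, gains are reported as late (as close to the tips) as
possible, the conservative convention when inferring duplication events.
Gain and loss costs default to 1/1; because absence from a transcriptome
may reflect expression failure rather than gene loss, a sensitivity
setting of gain 2 / loss 1 is supported, and fully missing tips are
marginalised over rather than coded absent.

**Maximum likelihood.** `ml_marginal_states()` uses the symmetric k-state
Markov (Mk) model with pairwise rate *r* (default 1), for which the
transition probability has the closed form
P(same) = 1/k + (k−1)/k·e^(−k r t). The state alphabet is restricted to
the states observed at the tips plus any explicitly supplied extras,
keeping the state space small. Marginal posteriors are exact: for each
node and state the full-tree likelihood is recomputed with that node
constrained (Felsenstein pruning), and posteriors are the normalised
constrained likelihoods under a flat root prior. This is quadratic in the
number of nodes rather than linear, but exactness is worth more than
speed at the tree sizes this package targets (tens of tips); it is
verified against brute-force summation over all internal assignments to
1e−8. Missing branch lengths default to 1. The reported state is the
posterior argmax with an alphabetical tie-break applied within a 1e−9
tolerance band, so exact symmetries (e.g. a perfectly mirrored quartet,
posterior 0.5/0.5) resolve deterministically rather than by floating-point
noise.

Reconstructions at the two key tuning sites are combined by
`joint_site_label()`, giving the two-letter pigment labels used for
damselfish SWS1: "AA" (short), "SS" (long), "AS" (the intermediate). The
masking control — removing selected tips' states and marginalising over
them — is available simply by setting those states to `NA`.

**Reconstruction fixtures.** `damselfish_copy_number()` encodes the
published copy-number survey (18 taxa: three single-copy genomes, the 11
two-copy anemonefishes, two two-copy *Pomacentrus* species and the
two-copy *Chromis chromis*) on the described subfamily clade topology;
minimum-gain parsimony on it yields exactly two independent gains, one per
expected branch. `damselfish_site_matrix()` is a synthetic schematic of
the described tuning-site history (basal short-variant clades, long
Chrominae, both Pomacentrinae paralogues, two intermediate outgroups);
both methods place the "AS" intermediate at its root. Both fixtures use
uniform placeholder branch lengths — they are rule-level encodings for
testing the reconstruction machinery, not calibrated phylogenies, and
which tree (gene vs species) best supports ancestral-pigment claims is
left to the user's data.

## Proportional expression

Expression is summarised exactly as the ratio estimator used for bulk
retinal RNA-seq: N_i = mapped reads / CDS length, and each gene's
proportion is N_i / Σ N_i over its cone-class group (single cones: SWS1
paralogues and SWS2B; double cones: RH2A, RH2B, LWS). Groups with no reads
in a sample get `NA` proportions — "undefined" and "zero" are different
statements. Rows with missing or non-positive CDS lengths are rejected
loudly rather than imputed. The per-sample SWS1 usage call ("one copy",
"both copies", "none") uses a detection threshold that defaults to a
proportion of 0.01 of group expression, strictly exceeded; published
expression surveys do not state a cutoff, so the threshold is a config
knob and is echoed into every output. The multinomial generator draws
reads with probability ∝ proportion × length, which makes the estimator
unbiased; recovery to ±0.01 at 10^6 reads is property-tested.

## Spectra

**T50.** The ocular-media cutoff is the wavelength at which transmission
reaches 50% of its maximum, interpolated linearly between the bracketing
samples. Two numerical choices: (i) a light 5-point moving average damps
measurement noise in both the maximum and the crossing region — it is
exact for symmetric sigmoids sampled on even grids, so noiseless curves
are unaffected; (ii) when noise produces several crossings, the
longest-wavelength upward crossing is used, because ocular media are
long-pass filters and the biologically meaningful cutoff is the final
rise. Classification follows the strict rule: UV-transmitting iff
T50 < 400 nm (a T50 of exactly 400 nm is UV-blocking). A spectrum that
never falls below half-maximum (e.g. flat 100% transmission) is degenerate;
its T50 is reported at the first sample with an explicit note rather than
failing.

**UV reflectance.** "Reflects in the UV" needs a magnitude criterion to
become a binary call; the definition (reflection below 400 nm) does not
supply one. The package's operationalisation: the peak reflectance inside
the 300–400 nm band must reach at least `criterion_fraction` (default
0.2) of the spectrum's overall peak. The criterion is configurable and
always echoed in the output, and published species-level calls cannot be
exactly replicated without the original spectra — the flag is a tool, not
a reproduction.

**Templates.** `pigment_template()` implements the Govardovskii et al.
(2000) A1 nomogram (α plus β band), normalised to peak 1, and
`coexpression_mixture()` forms the renormalised weighted mean that
describes two opsins co-expressed in one photoreceptor; the mixture peak
always lies between the component peaks. Templates are rendering/plumbing
utilities, not part of the λ_max estimator.

**Averaging.** Replicate spectra are averaged pointwise; mismatched grids
are resampled by linear interpolation onto the shared range (never
extrapolated), and the resampling is flagged on the result.

## Synthetic data: what it does and does not emulate

The generators produce every input type with ground truth recorded in
sidecars (`truth` elements), and all recovery tests read truth only from
those sidecars. A single user seed fans out through fixed per-generator
offsets, so adding a generator never perturbs existing streams, and every
output is bit-for-bit reproducible under a fixed seed.

- `simulate_opsin_tips()` evolves point substitutions along a tree from an
  anchor-backbone root with SWS1-consensus tuning residues. Background
  mutation avoids the tuning sites (unless enabled), so planted clade
  states are exact. It does not simulate indels, codon-level evolution,
  rate heterogeneity or alignment error — so passing its round-trip tests
  shows the numbering and extraction machinery is correct, not that any
  divergent real opsin will align perfectly.
- `simulate_counts()` draws multinomial reads; it does not model
  overdispersion, mapping bias or multi-mapping.
- `simulate_presence()` plants clean gain/loss histories on clades; it
  does not model incomplete lineage sorting or assembly artefacts.
- `simulate_spectrum()` produces logistic long-pass curves with additive
  Gaussian noise on a 300–800 nm grid at 1 nm; real lens spectra have
  asymmetric shoulders and wavelength-dependent noise.

Problem sizes in the test-suite follow the scale at which the brute-force
oracles stay exact and fast: enumeration oracles run on trees of at most
7 tips (parsimony, 100 seeded instances) and 5 tips (ML, 20 instances);
expression recovery uses 10^6 reads; T50 recovery uses ten 501-point
spectra at 1% noise. These sizes were chosen as the smallest at which each
property is sharply testable.

## Known limitations

- λ_max estimation is only as good as the reference panel; the packaged
  panel is a synthetic default, and estimates chain at most
  `homology_threshold` unmeasured substitutions (default none).
- The Mk model is symmetric with a single rate; no rate optimisation, no
  joint (as opposed to marginal) reconstruction, and no gene-tree/
  species-tree reconciliation — duplication placement is cost-based
  parsimony, not a probabilistic DTL model.
- Tree inference itself is out of scope: trees are consumed, rooted on an
  outgroup or at midpoint if needed, never estimated.
- Visual modelling (quantum catches, receptor-noise discrimination) is
  out of scope; the spectra module stops at classification and rendering.
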