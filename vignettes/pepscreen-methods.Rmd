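---
title: "pepscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

pepscreen implements the analysis layer of an in-silico campaign for
ACE-inhibitory oligopeptides from seed-storage proteins: rule-based
gastrointestinal proteolysis, oligopeptide library construction and
bioactive matching, pharmacophore fit scoring, receptor–ligand interaction
fingerprinting, multi-receptor consensus filtering, and dose–response IC50
recovery. This vignette records the models behind each stage, the tunable
parameters with their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Simulated proteolysis

Digestive proteases are modelled as pure functions of local sequence
context: whether the bond between P1 and P1' is cleaved depends only on the
residues at P3..P2'. The rule tables (shipped as a versioned JSON data file
so dialects can be swapped and diffed) follow the ExPASy PeptideCutter
tables in the widely used regular-expression transcription:

* **trypsin** — after K/R, blocked before P except in the WKP and MRP
  contexts; the Keil triplet exceptions (CKD, DKD, CKH, CKY, CRK, RRH,
  RRR) veto otherwise allowed sites.
* **chymotrypsin** — high specificity: after F/Y (not before P) and W (not
  before M/P); low specificity adds L, M (not before P/Y) and H (not
  before D/M/P/W).
* **pepsin** — the two-clause context rule over P3..P2' with the
  hydrophobic set {F, L} at pH 1.3 and {F, L, W, Y} at pH > 2. Context
  positions named by a clause must exist, so bonds within two residues of a
  terminus are never pepsin sites. This matches the regex dialect exactly
  and is the main place where digestion dialects genuinely differ; both
  pepsin variants ship so either can be used.

The default gastrointestinal set is `pepsin_pH1.3 + trypsin +
chymotrypsin_high`, applied **concurrently** (one-pot): sites are unioned
and fragments are the maximal substrings between consecutive sites. A
sequential stomach-then-intestine mode exists behind `mode = "sequential"`;
for context-local rules it differs only where a cut removes the flanking
context of another site. Ambiguity codes (B, Z, X, U) are rejected by
default; `permissive = TRUE` treats them as never-cleavable context.

Digestion output is reported both as total fragment occurrences and as
distinct sequences, since "peptides obtained" is ambiguous between the two;
both counts are always exposed.

## Oligopeptide library and masses

The library keeps fragments of 2–6 residues inclusive — the window with
absorbable molecular weight — deduplicated by sequence with occurrence
counts and parent provenance preserved (singletons and >6-mers stay in the
raw fragment store for reporting). Masses are sums of standard IUPAC
residue masses plus one water, on both the monoisotopic and average scales;
no modifications are modelled. Bioactive annotation is exact full-sequence
matching against a packaged reference table (sequence, bioactivity,
source); a sequence may carry several labels (e.g. AY is both an ACE
inhibitor and an antioxidant). Substring/motif matching is deliberately out
of scope.

## Pharmacophore model and fit value

A model is a set of tolerance spheres: feature type (hydrogen-bond
acceptor, donor, negative ionizable, hydrophobe), center (Å), radius (Å),
weight. Feature perception on a conformer is rule-based on elements and
covalent bonds inferred from interatomic distances (single-bond covalent
radii + 0.45 Å): donors are N/O with an explicit bonded hydrogen; acceptors
are any oxygen and low-coordination (≤ 2 neighbours) nitrogens;
negative-ionizable points are centroids of carboxylate/phosphonate terminal
oxygens; hydrophobes are centroids of connected clusters of ≥ 3 apolar
carbons. Perception therefore expects hydrogens on donors — standard for
minimised conformers; structures without hydrogens will under-report
donors.

The fit of a ligand against a model is

$$\mathrm{fit} = \frac{\sum_f w_f \,\max(0,\, 1 - d_f/r_f)}{\sum_f w_f}$$

maximised over conformers, over injective type-respecting assignments of
model features to perceived points, and over the least-squares rigid
superposition (Kabsch) of the assigned points onto the model centers; an
assignment that leaves any model feature unmatched scores zero. This is
**this package's own fit definition**: it is monotone, rigid-invariant,
equals 1 only at perfect overlap and 0 outside the tolerance spheres, but
it is *not* the proprietary normalized fit of commercial pharmacophore
software, so published fit values from such software are not comparable
numbers. Ties between equal-fit assignments are broken by lexicographic
assignment order. For one and two assigned points the superposition
residuals have closed forms (zero, and half the length mismatch).

The screening threshold defaults to fit > 0.7, the conventional cutoff for
predicted activity. The packaged four-feature ACE model
(`ace_pharmacophore()`) is a synthetic reconstruction of the lisinopril
binding mode at the ACE C-domain active site — carboxylate toward the
catalytic zinc, donor toward the ALA354 backbone, hydrophobe in the VAL518
pocket — shipped for testing and demonstration, not published model
coordinates. Reverse profiling over many targets is supported generically
(`screen_library` takes any model list); no published multi-target model
battery exists to ship.

## Interaction fingerprints

Contacts between a receptor (standard PDB residue/atom-name chemistry) and
a ligand (element + inferred-bond chemistry) are typed with the following
defaults, all configurable and recorded on every fingerprint:

| type | criterion | default |
|---|---|---|
| HBOND | donor–acceptor heavy distance; donor–H–acceptor angle | ≤ 3.5 Å; ≥ 120° |
| HBOND (no H on donor) | heavy antecedent–donor–acceptor angle | ≥ 90° |
| HYDROPHOBIC | apolar carbon pair | ≤ 4.5 Å |
| ELECTROSTATIC | opposite formal-charge group centroids | ≤ 5.5 Å |
| METAL | ligand O/N/S to metal ion | ≤ 3.0 Å |

These are common structural-biology practice (PLIP-like); the diagrams in
commercial packages use their own undisclosed criteria, so parity with such
figures is qualitative (residue identity), not quantitative. Charge
assignment is by residue/atom-name rules (ASP/GLU carboxylates negative;
LYS NZ and the ARG guanidinium positive; histidine positive behind the
`his_charged` flag, on by default because the ACE active-site histidines
participate in the zinc electrostatic network; ligand carboxylates negative
and primary amines positive) — no pKa calculation. Waters are always
excluded; metals are never merged into the ligand. Records are
deduplicated by (type, residue, atom pair). π-stacking and cation-π are out
of scope.

## Structure comparison

`kabsch_superpose` computes the least-squares rigid transform via SVD,
constrained to a proper rotation. `tm_score` evaluates
$TM = \frac{1}{L}\sum_i (1 + (d_i/d_0)^2)^{-1}$ with
$d_0 = 1.24(L-15)^{1/3} - 1.8$ (hence the L ≥ 16 requirement), maximised
over superpositions by seeding Kabsch fits on contiguous residue windows —
every window for chains of ≤ 60 residues, a geometric ladder of window
lengths for longer chains — each refined by iteratively re-fitting on the
residue subset currently within d0. This recovers the TM-optimal
superposition for same-protein structure pairs; full dynamic-programming
alignment of non-identical sequences is out of scope, and residue
correspondence is by residue-number intersection on CA atoms.

## Consensus layer

Docking scores are consumed, never computed: any higher-is-better score
works, which keeps the module engine-agnostic. Per receptor, the screening
threshold is `fraction` (default 0.5) of the initial co-crystallised
ligand's score; a ligand passes if its **best pose** reaches the threshold
(the permissive reading of "docked successfully"; a per-pose mode would
only shrink sets); the final candidate set is the intersection across
receptors, and a ligand missing from a receptor's table fails that
receptor. Residue frequencies count a residue once per pose per interaction
type, over all poses by default (a score-filtered mode is a subset
operation on the input). Top-k ranking includes all residues tied at rank
k, with the expansion flagged. Metals appear as the pseudo-residue "ZN",
kept distinguishable from amino-acid residues. Candidate triage classes
final-pass ligands by which key interactions any pose shows — by default an
H-bond to ALA354 and a hydrophobic contact with VAL518, the two
high-frequency ACE-inhibitor interactions.

## Assay math

Inhibition is the fractional loss of the hippuric-acid product peak,
$100\,(A_{control}-A_{sample})/A_{control}$; a sample above control returns
a negative rate with a warning (apparent activation) rather than an error.
IC50 comes from a logistic fit on log10 concentration via
Levenberg–Marquardt: by default the 2-parameter form with asymptotes fixed
at 0/100 (appropriate for a percent-inhibition readout), with a 4-parameter
variant (`fix_asymptotes = FALSE`, asymptotes bounded to [0, 100], started
strictly inside the bounds because a boundary start can pin a parameter).
For the free-asymptote model the IC50 is where the fitted curve crosses
50%, not the logistic midpoint. The fit refuses data lying entirely on one
side of 50% (the IC50 would be an extrapolation) and zero-concentration
controls (they define A_control, not a fit point). Fewer than 4 points are
rejected.

## Synthetic-data generator

Every stage is tested against generator output whose ground truth is
computed by independent naive implementations, never by the module under
test: digestion manifests come from a per-bond rule interpreter
(`naive_cleavage_sites`) that evaluates each context literally; pose-table
truth is planted by construction; complex fixtures place each contact at
its exact geometry (stations 25 Å apart so contacts cannot interfere, with
a < 1 Å clash check). All randomness flows from a single seed per call,
recorded in each manifest, and the caller's RNG stream is left untouched.

Defaults emulate the campaign the package is designed around: ten
prolamin-like proteins of 120–260 residues with a Q/A/P/S-rich background
composition and cleavage-prone residues planted at density 0.1 — which
yields roughly 220 fragments per proteome under the default enzyme set, the
scale of a real ten-prolamin digestion; a 41-ligand docking table over
three receptors with initial-ligand scores 106.292/102.324/156.907, ten
poses per ligand, planted passing sets of 34/38/24 whose intersection is
exactly 19; planted contact frequencies over 130 positive-control poses
with ALA354 (H-bond, 90) and VAL518 (hydrophobic, 70) on top; and a
dose–response curve with planted IC50 61.88 µM sampled at eight log-spaced
doses two decades either side.

What the generator does **not** emulate: real prolamins have clustered
hydrophobic repeats, so their digests contain a much larger share of
2–6-mers (around 60%) than uniform planting produces (~25%) — passing
tests show the engine agrees with the rule tables, not that the synthetic
length profile matches real coixins; sequences carry no homology structure
across the ten proteins; synthetic complexes are minimal atom arrangements,
not folded receptors; and pose scores are draws around the threshold, not
energies. Conformer generation is likewise out of scope — a conformer here
is whatever 3D coordinates are supplied.

## Problem sizes and numerical tolerances

The test suite runs the engine–interpreter equivalence on 1,000 random
sequences of up to 60 residues over all five enzymes; rigid-motion
invariance of the fit is asserted to 1e-6; the TM-score search is checked
against an exhaustive-window oracle on 50-residue coils to 1e-3; noisy IC50
recovery uses 100 seeded replicates at 5% noise and asserts the median
within 5% of truth. Assignment enumeration in `best_fit` is exhaustive and
intended for models of up to ~6 features with a handful of candidate points
per type — the regime pharmacophore models live in — not for arbitrary
point-set registration.

## Known limitations

* Cleavage dialects differ between public tools; the shipped tables are one
  documented dialect, and counts on real proteins are sensitive to the
  pepsin variant chosen.
* Donor perception requires explicit hydrogens on ligands (receptor donors
  fall back to heavy-atom geometry).
* The fit value is this package's definition; absolute values are not
  comparable across software, only rankings under the same definition.
* `tm_score` assumes matched coordinates (same protein); it does not align
  different sequences.
* The 50%-of-initial-ligand score threshold inherits the scale of whatever
  scoring function produced the input; mixing engines across receptors is
  the caller's responsibility.
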