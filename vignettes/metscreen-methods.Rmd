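---
title: "Methods: screening candidate substrates of uncharacterized methyltransferases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening candidate substrates of uncharacterized methyltransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

# The problem

SET- and PR-domain lysine methyltransferases transfer the methyl group of
S-adenosyl-L-methionine (SAM) to the ε-amino nitrogen (NZ) of a substrate
lysine. For many family members — PRDM15 is the motivating example shipped
with this package — neither the substrates nor the number of methylation
states the enzyme can produce are known. `metscreen` operationalizes a
triage strategy that combines four sources of evidence, each implemented
as an independently testable module:

1. a **candidate repertoire** of lysine-centered peptide windows;
2. a **geometric filter** keeping only complex models whose active site is
   arranged for catalysis;
3. a **simplified LRA electrostatic score** to rank candidates;
4. a **catalytic-tyrosine conservation profile** predicting methylation
   capacity, plus a **co-dependency correlation screen** for orthogonal
   functional evidence.

A synthetic-data module generates every input with known ground truth, so
the whole pipeline can be validated without external databases.

# Candidate repertoires

`extract_windows()` scans protein sequences with the pattern xxxKxxx
(x = any residue): every lysine with at least three residues on each side
yields one 7-mer window with the lysine at position 4. Window length and
center are parameters (default 7/4) so the same machinery applies to
enzymes with longer recognition footprints. Windows containing
non-standard codes (X, U, B, Z) are dropped with a warning rather than
failing the record — FASTA files in the wild contain them. Deduplication
is on exact 7-mer identity, first occurrence canonical, with all source
annotations retained; this matches how a peptide-modeling campaign would
treat identical windows from paralogous histones.

The packaged repertoire (`load_fixture_table1()`) contains 64 unique
histone-derived heptapeptides (H1.2, H2B, H3.1, H4 and related isoforms)
with precomputed binding energies in kcal/mol. These energies come from a
full semi-macroscopic PDLD/S-LRA protocol with molecular-dynamics sampling
and are **not** reproducible by the simplified scorer below; the package
treats them as an ordinal ranking surface. The fixture also carries the
positive control: the PRDM9–H3K4 peptide ARTKQTA at −2.73 kcal/mol
(`prdm9_reference()`).

Site labels follow two conventions that coexist in the literature:
counting from the initiator methionine ("H3K5") and classical histone
nomenclature that drops it ("H3K4" for the same residue). `label_site()`
implements both because published tables mix them; the fixture keeps its
source labels verbatim.

# Geometric filtering

## Criteria and their defaults

The SN2 methyl transfer requires an in-line arrangement: NZ attacks the
methyl carbon (CE) opposite the sulfonium sulfur (SD). Before transfer,
the lysine must be deprotonated by an active-site tyrosine hydroxyl. The
filter therefore measures, per model:

| quantity | atoms | target | window (default) |
|---|---|---|---|
| d_mt | SD–NZ | 4.4 Å | ± 0.5 Å |
| d_pt | OH–NZ, per Tyr | 3.0 Å | ± 0.5 Å |
| attack angle | NZ–CE–SD | 180° | ± 30° (optional) |
| Arg–cofactor contact | min heavy-atom | — | ≤ 4.0 Å (optional) |

The 4.4 Å and 3.0 Å targets are the catalytically competent distances for
methyl and proton transfer; they are stated as "around" in the structural
literature, so the windows must be made explicit to be testable. The
defaults of ±0.5 Å are our choice: wide enough to admit thermal
fluctuation around the ideal geometry, narrow enough to exclude models
where the cofactor or tyrosine has drifted a bond length away. The angle
and arginine checks default to off: the distance pair is the primary
selection surface, and the auxiliary criteria are enzyme-specific (the
arginine contact encodes a family-specific replacement of the canonical
cofactor-binding asparagine motif). `pass_pt` requires only one tyrosine
in window because a single conserved tyrosine suffices for a single
deprotonation.

Mapping of chemical groups to PDB atoms: sulfonium → SD of residue SAM,
ε-amino group → NZ of LYS, tyrosine hydroxyl oxygen → OH, methyl carbon →
CE (absent in SAH, whose methyl has already been transferred — such
complexes report no attack angle). Coordinates are read as-is in the PDB
orthogonal frame; the first alternate location is kept and hydrogens are
ignored for contact distances.

## Numerical behaviour

All quantities are Euclidean and therefore exactly invariant under rigid
transforms; the tests assert this to 1e−6 Å/degree under random rotations
and translations. The filter's pass count is monotone non-decreasing in
every tolerance, which the tests verify on noisy ensembles — a useful
sanity property when tightening criteria on real model sets.

# The simplified LRA score

## Model

The binding free energy of the peptide (solute) is estimated as

$$\Delta G_{bind} = \tfrac12\left(\langle U\rangle_{on} +
\langle U\rangle_{off}\right),$$

the linear-response average over configurations with the solute charges on
and off. U is a screened Coulomb sum over peptide × (enzyme + cofactor)
atom pairs, $U = \sum 332.0637\, q_i q_j / (\varepsilon_{ij} r_{ij})$
kcal/mol, with $\varepsilon_{ij} = 60$ when both atoms belong to ionizable
groups (Lys NZ, Arg CZ, Asp OD1/OD2, Glu OE1/OE2, the SAM sulfonium SD)
and $\varepsilon = 4$ otherwise. The Coulomb constant 332.0637
kcal·Å/(mol·e²) is stated explicitly since conventions differ across
packages. Charges are formal: +1 on Lys NZ and Arg CZ, −0.5 on each
carboxylate oxygen, +1 on SD; a user charge table can refine the neutral
atoms. Four configurations per state (the default) are generated by
Gaussian positional perturbation with σ = 0.3 Å — a stand-in for the short
MD sampling a full protocol would use, chosen at the scale of thermal
atomic displacement. With the solute charges off the cross-group energy is
identically zero, so $\Delta G = \tfrac12\langle U\rangle_{on}$; the
⟨U⟩_off term is retained in the implementation so that refined charge
models (where the uncharged state keeps polar partial charges) drop in
without code changes.

Design choices worth recording: the ½ prefactor is the literature-standard
LRA form (the alternative — a plain mean over all configurations — differs
only by a constant factor under our zero-off-state charges and would not
change any ranking); the sign convention is "more negative = stronger
binding"; the uncharged state zeroes *solute* (peptide) charges only.

## What this scorer is not

It contains no Langevin-dipole or explicit solvent, no long-range
treatment, no molecular dynamics, no entropy or solvation terms. It is a
self-consistent, deterministic (per seed) *ranking* device whose
correctness surface is algebraic: the LRA identity holds to 1e−9, a
zero-charge solute scores exactly 0, two-atom systems match the
closed-form Coulomb expression to 1e−9, and complexes constructed with
complementary charges score strictly below neutral ones, which score
strictly below like-charge decoys, across seeds. Absolute energies
printed alongside the packaged repertoire originate from the full
protocol and are deliberately out of reach.

# Catalytic profile and motifs

`profile_query()` aligns the query enzyme to an annotated reference
(global Needleman–Wunsch with affine gaps, BLOSUM62, gap open 10 /
extend 0.5) and counts how many of the reference's annotated active-site
tyrosines align to a tyrosine in the query. Pairwise global alignment
replaces the multiple alignment a manual analysis would use: the
conservation call depends only on Y-versus-not-Y at three columns and is
robust to the scoring set. Tie-breaking among equal-scoring alignments
follows the alignment engine's documented preference; the tests check the
returned *score* equals an exhaustive dynamic-programming optimum on short
sequences, which is the property the profile depends on.

The capacity rule: each conserved tyrosine supports one deprotonation,
hence one methylation step. Three conserved → the full me0→me3 cascade;
two → either pair of consecutive steps; one → exactly one of
{me0→me1, me1→me2, me2→me3}, returned as three alternative hypotheses —
sequence conservation alone cannot decide which, so the profile reports
all three rather than guessing. The biological reading (capacity =
conserved-tyrosine count) is a hypothesis inherited from the reference
enzyme family, not something these tests can establish.

`scan_motifs()` searches the two SET-domain signature motifs with the
slash notation interpreted as alternatives at a single position:
ELxF/YDY = E-L-x-(F|Y)-D-Y and NHS/CxxPN = N-H-(S|C)-x-x-P-N. Overlapping
hits are all reported. The reference annotation (tyrosine positions
276/341/357 for a PRDM9-like reference) is user-editable configuration;
sequences are inputs, not hard-coded data.

# Co-dependency screen

`pearson_with_p()` uses the sample Pearson coefficient on
pairwise-complete observations and a two-sided p-value from the t
transform $t = r\sqrt{(n-2)/(1-r^2)}$ with n − 2 degrees of freedom —
the standard parametric test, adopted because dependency-portal matrices
are ragged and a per-pair n is the natural unit. The screen's filters are
strict inequalities: |r| > 0.4, p < 0.05, n > 10 (so n = 10 exactly
fails). No multiple-testing correction is applied by default, matching
how such screens are usually reported; a Benjamini–Hochberg option exists
and is off by default. `top_codependent()` ranks partners of an anchor
gene by |r| with ties broken by p-value then identifier, excluding the
anchor itself.

# Synthetic data: what it emulates and what it does not

`gen_complex()` places the atoms the pipeline reads — and only those,
plus minimal backbone stubs — at *exactly* the requested geometry:
NZ at the origin, SD at d_mt on the x-axis, CE on the S–C bond circle so
the NZ–CE–SD angle is exact (solved numerically for non-collinear
angles), the tyrosine OH at d_pt, an optional arginine whose closest
heavy atom sits at the requested cofactor distance, and an optional
charged "binder" residue near the peptide lysine implementing the
strong-binder (Glu), null (none) and decoy (Arg) charge schemes. Gaussian
coordinate noise is applied after exact placement, so ground truth is
known by construction. Specs that cannot be realized (d_mt below the S–C
bond length; unreachable angles) are errors, not silent distortions.

`gen_ensemble()` mixes competent and far-off decoy models in a seeded
shuffle and returns the labels, enabling exact validation of the filter.
`gen_planted_matrix()` uses the bivariate-Gaussian construction
b = r·a + √(1−r²)·e, whose expected Pearson correlation is r_true.

These generators emulate controlled geometry, charge complementarity and
planted correlation — not real comparative-model ensembles (no loop
diversity, no packing artifacts, no correlated coordinate error), not
chemically complete residues, and not the lineage structure, batch
effects or heavy missingness of real dependency matrices. Passing tests
therefore demonstrate that the *measurement, filtering, scoring and
screening machinery* is correct, not that any particular enzyme's
substrates have been found.

# Pipeline and reproducibility

`run_screen()` executes repertoire → geometry filter → LRA scoring →
ranking → profile, writing each stage's output as CSV/JSON plus a
manifest with parameters, per-stage summaries and MD5 checksums. All
randomness funnels through one master seed expanded per stage with fixed
offsets, so a rerun of the same configuration is byte-identical — the
tests compare manifests literally. A failing stage aborts with the stage
name and leaves a `FAILED` marker next to any partial outputs.

Problem sizes used in the shipped tests and acceptance script — ensembles
of 100 models, 2000 null correlation pairs at n = 50, 200 planted
replicates at n = 500 — were chosen as the smallest sizes at which the
calibration claims (type-I fraction 0.05 ± 0.02; recovery of r = 0.8
within ±0.05 in ≥95% of replicates) are statistically stable.

# Known limitations

- The geometric filter judges static models; it cannot rescue a model
  whose competence appears only along a dynamical path.
- The LRA scorer's absolute values are not transferable energies; only
  orderings within one run are meaningful.
- Capacity prediction rests on the conserved-tyrosine correspondence
  observed in a handful of characterized SET-domain enzymes; with one
  conserved tyrosine the specific transition remains undetermined.
- The correlation screen reports raw p-values by design; genome-scale
  applications should enable the BH option.
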