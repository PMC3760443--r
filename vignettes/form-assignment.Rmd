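---
title: "Molecular-form assignment for acylated ghrelin mass lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-form assignment for acylated ghrelin mass lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylforms)
```

## The problem

Ghrelin, the gastric hunger hormone, is post-translationally esterified
with a medium-chain fatty acid (usually octanoate) on the hydroxyl of
its third residue, and this acyl group is required for receptor
activity. When ghrelin is purified from stomach extracts, MALDI-TOF
mass spectrometry reports one [M+H]+ value per species, and the
biological question — *which* processed, acylated form is this? — must
be answered by arithmetic: each candidate form has a computable
theoretical mass, and the observed mass selects among them. In the
barfin flounder (*Verasper moseri*), whose cDNA-deduced mature peptide
is the 20-residue GSSFLSPSHKPPNKGKPPRA, stomach extracts yield a family
of coexisting species: C-terminally trimmed (19-residue) free acids,
glycine-extended (21-residue) free acids, amidated 20-residue peptides,
and acyl chains from C8 to C10 with zero to two double bonds. Feeding
the fish medium-chain fatty acids (C7, C8, C9) shifts which species
dominates.

`acylforms` packages that inference: it enumerates the candidate form
space from a precursor *processing context*, computes theoretical
masses, assigns observed masses under an absolute tolerance, estimates
the instrument's global calibration offset, checks Edman (N-terminal
sequencing) reads against modified sites, and simulates synthetic mass
lists so the whole pipeline can be validated without instrument data.

## The model

A candidate **molecular form** is a tuple (backbone length $L$,
C-terminal state, acyl group, adduct). Its theoretical singly
protonated mass is

$$ m_{theo} = \sum_{i=1}^{L} r_i \;+\; m_{H_2O} \;+\;
   \Delta_{cterm} \;+\; \Delta_{acyl} \;+\; \Delta_{adduct} \;+\; m_{H^+} $$

with residue masses $r_i$ from CODATA monoisotopic element masses,
$\Delta_{cterm} = -0.98402$ Da for a C-terminal amide (replacing
–OH with –NH$_2$), $\Delta_{acyl} = m(\mathrm{C}_n\mathrm{H}_{2n-2-2m}\mathrm{O})$
for a fatty-acyl chain C$n$:$m$ (the fatty acid minus water), and
$m_{H^+} = 1.007276$ Da. Two biochemical constraints prune the space:

* **Glycine-donor rule.** C-terminal amidation proceeds through a
  glycine-extended intermediate, so a length-$L$ amide is enumerated
  only when residue $L+1$ of core+extension is glycine. For the
  flounder context (core of 20, extension "G") only the 20-residue
  amide exists; the 21-residue species can only be glycine-extended
  free acids.
* **Acyl-site presence.** The acyl site (default residue 3, a serine)
  must lie inside every enumerated backbone; only C-terminal
  variation is modelled, since N-terminal trimming would delete the
  acyl site that receptor activity (the purification readout) requires.

An observed mass is assigned to the candidate minimizing
$|m_{obs} - m_{theo}|$, accepted when that minimum is at most the
tolerance; candidates within a tie window of the best distance are
reported as ties, never silently broken.

## Why monoisotopic masses, and the 0.25 Da tolerance

Recomputing the published flounder mass list shows every unambiguous
entry lying 0.06–0.23 Da *below* the monoisotopic theoretical value —
a consistent, one-sided instrument offset — whereas average-mass
theory deviates by more than 1 Da at this peptide size. Monoisotopic
mode is therefore the default (average mode is available). The default
absolute tolerance of 0.25 Da covers the observed offset band with
margin; ties at 0.05 Da flag genuinely ambiguous calls. Because the
offset is shared across a run, `assign_all(..., offset_correction =
TRUE)` does a two-pass assignment: provisional matching, a median
offset estimate over confident matches (median absolute deviation as
dispersion; the median resists the occasional aberrant row), then
re-matching of offset-corrected masses.

```{r}
ctx <- flounder_ghrelin_context()
cands <- enumerate_forms(ctx, enum_config())
a <- assign_all(table1_masses("cont"), cands)
estimate_offset(a)
```

## The chain-range default and near-isobaric degeneracy

Backbone/chain combinations are not all mass-distinguishable at
MALDI-TOF accuracy. Two exact arithmetic families matter (masses
below from the package's own constants):

* a length-$L$ amide with chain C$n$:$m$ lies **0.0255 Da below** the
  length-$(L-1)$ free acid with chain C$(n+5)$:$m$ (five CH$_2$ minus
  Gly minus amide);
* the same amide lies **0.0728 Da above** the length-$(L+1)$ free acid
  with chain C$(n-4)$:$(m+1)$.

Any chain range spanning five or more carbons therefore contains pairs
~0.025 Da apart, and an unconstrained range makes assignment
ill-posed. The default `enum_config()` range is **C7–C12**: it covers
every chain the feeding experiment probes (C7 must be enumerable
precisely so that its *absence* among assignments is a result, not an
artifact) and every form reported in flounder stomach extracts
(C8–C10), while excluding C6 and below — with C6 enumerated, the
21-residue C6:1/C6:2 free acids sit 0.073 Da below the 20-residue
C10:0/C10:1 amides and capture their observed masses, which lie
~0.17 Da below theory. Within the default space the *observed* forms
are all >0.9 Da from every other candidate, which is what justifies
the 0.25 Da tolerance; `min_mass_gap()` reports the global gap
(~0.025 Da, from the C7-amide/C12-acid pair) so users widening the
range see the degeneracy they are buying.

```{r}
min_mass_gap(cands)
```

Des-acyl backbones are enumerated by default — des-acyl ghrelin is a
real secretory product — although none falls within tolerance of the
published acylated masses. Adducts default to off; a registry supplies
the Na-for-H replacement (+21.98194 Da), the empirical "+24"
sodium-like satellite (+23.98 Da — chemically ambiguous: a formal
Na−H replacement is +21.98, but the printed satellite spacings are
≈ +23.9, so the registry carries the empirical value and the user may
override it), and a +0.98402 Da "+1" satellite. The published "+17"
satellite and one anomalous row (2146.02, ~1.8 Da from its label's
theory while every sibling deviates ≤0.23 Da) are treated as
documented irregularities, excluded from reproduction checks rather
than modelled or corrected. Likewise a published "21-amide" label
contradicts the glycine-donor rule (no donor residue exists at
position 22) and shares its mass with the 20-residue C10:0 amide; the
engine reports the mechanistically consistent label.

## Edman consistency

Edman degradation reads one residue per cycle; a cycle blocked by a
covalent modification yields no signal (written `X`). The published
flounder read, GSXFLSPSHKPPNKGKP, is consistent in strict mode with an
acylated form (the blank cycle 3 *is* the acyl site) and inconsistent
with the des-acyl form (nothing explains the blank); a read with a
*detected* Ser3 would conversely refute acylation. Strict mode is the
default because site inference is the point; lenient mode (X matches
anything) suits noisy reads.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a feeding
group's purified mass list: forms drawn i.i.d. from a mixture over the
candidate space, exact theoretical masses, a global calibration offset,
Gaussian noise in Da (not ppm — MALDI-TOF reflectron error at 2 kDa is
well approximated as additive), and optional adduct replacement. The
scenario presets encode the feeding experiment qualitatively: control
and C7 dominated by the 19-residue C10:0 peptide, C8 by 19-C8:0, C9 by
19-C9:0, the C7 scenario assigning zero weight to any C7-acylated form
(none was ever isolated) and carrying a reduced-abundance flag. The
published record gives only yield *ranks* per group, so the preset
weights (0.45–0.5 on the dominant form, the published second/third
forms next, the remainder spread over the group's other detected
forms) are configuration, not estimates, and cannot be validated
against printed proportions. Default noise is $\sigma = 0.05$ Da and
the default offset 0; the study-like offset is −0.16 Da.

What the simulation does *not* emulate: chromatographic elution,
intensity/abundance of peaks (every draw is one observation),
isotope envelopes, correlated calibration drift across a plate, or the
biology of acyl-substrate incorporation. Passing recovery tests
therefore validate the *assignment arithmetic* under the stated
measurement model, not instrument realism.

Under that model the geometry does the work: observed forms are
≥0.9 Da apart, so with $\sigma = 0.05$ a misassignment needs a ≥9σ
noise excursion and top-1 recovery at tolerance 0.25 Da is ≈ 1; the
median offset estimate from $n = 30$ masses has standard error
≈ $1.25\sigma/\sqrt{n} \approx 0.011$ Da and recovers −0.16 Da within
±0.05 Da on essentially every seed. The test suite measures these at
$n = 1000$ (recovery), a 3-point σ grid × 20 seeds (monotone
degradation), and 100 seeds × $n = 30$ (offset recovery).

## Numerical and design choices

* All randomness is seed-scoped (`withr::with_seed`): the generator
  never touches the global RNG stream, and the seed is echoed in the
  JSON run summaries.
* Enumeration order is deterministic (sorted by mass, ties by label);
  the matcher uses `findInterval` bisection on the sorted table and is
  tested against an exhaustive linear scan.
* Ties are ordered by |delta| then lexical label; duplicate input
  masses are assigned independently (the published table itself prints
  duplicates), with de-duplication an explicit CLI flag.
* Degenerate-primer arithmetic uses an embedded IUPAC table;
  `degeneracy_count()` is closed-form and cross-checked against brute
  force. `U` is normalized to `T`; translation uses the standard
  genetic code only.
* 1-based residue indices everywhere user-facing (biochemistry
  convention); internally R's 1-based `substr` arithmetic is used
  directly.
* Test and simulation problem sizes (n = 1000 recovery runs, 100-seed
  offset sweeps, 20-seed σ grids) were chosen as the smallest sizes at
  which the binomial/standard-error bounds above are decisive.

## Limitations

* Single acylation at one configured site; no N-terminal truncation
  series; charge state +1 only; no isotope-envelope or MS/MS modelling.
* Absolute (Da) tolerance by default; ppm-style matching would be
  preferable for instruments with mass-dependent error.
* The scenario weights are qualitative stand-ins, so simulated
  feeding-group comparisons demonstrate pipeline behaviour, not
  effect-size claims about the organism.
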