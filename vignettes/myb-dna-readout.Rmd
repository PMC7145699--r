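---
title: "Methods: motif census, interface readout and the one-site isotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif census, interface readout and the one-site isotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybdna)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The package covers three layers of the question
"how does an R2R3-MYB transcription factor read its target element, and how
do 5mC/6mA marks interfere": a genome-scale census of the degenerate binding
element against a methylome, a geometric analysis of a protein–DNA complex,
and the one-site ITC binding isotherm. A fourth layer — seeded synthetic-data
generation with recorded ground truth — exists so that the first three can
be tested end to end without any external data.

## 1. Promoter motif–methylome census

### Model

The binding element is a degenerate IUPAC pattern, by default `AACNDN`
(`D` = A/G/T, `N` = any): the `AAC` core read by the R3 repeat, plus the
downstream positions read more permissively by R2. The census asks, for a
genome and an annotation: how many instances of the element fall in promoter
regions, and how many of those carry 5mC on the position-3 cytosine or 6mA
on the position-1/2 adenines of the core, on the motif strand.

Conventions, chosen once and used everywhere:

* **Coordinates** are 0-based half-open internally and on disk (BED
  semantics); GFF3 input is converted on read. Nothing upstream of the
  package fixes a convention, so the BED one was chosen because the
  methylation calls and instance outputs are BED-like.
* **TSS** is the annotated 5' end of the *gene* feature; the promoter
  window is `[TSS - L, TSS)` on `+` genes and `[TSS, TSS + L)` on `-`
  genes with `L = 3000` bp by default, clipped at chromosome bounds, and
  empty windows are dropped with a warning.
* **Both strands** are scanned by default (a `strands` flag restricts to
  one for sensitivity analysis). Whether a one- or two-strand census is
  "correct" is not decidable from the element definition alone; scanning
  both is the conservative superset and the flag makes the choice explicit.
* An instance counts when it lies **entirely inside** at least one promoter
  window — the window's sequence is what is scanned, conceptually — and it
  counts **once** even when overlapping windows share it, while being
  credited to every gene whose window overlaps it.
* Genomic `N` matches **no** pattern symbol, including pattern `N`: unknown
  sequence must not create phantom motifs.
* Methylation calls are **strand-specific** and must match the motif
  strand; 5mC and 6mA are per-strand chemical marks. Calls are
  deduplicated on `(chrom, pos, strand, type)`, and an optional score
  threshold (default: none) filters low-confidence calls.

The three flags per instance define eight disjoint categories
(`unmethylated`, `5mC-only`, ..., `5mC+6mA1+6mA2`); the census reports the
category counts, the marginals, and the number of distinct genes with at
least one instance. Category counts always sum to the instance total.

### Two independent routes

`scan_motifs()` (Biostrings `matchPattern` with IUPAC interpretation, plus
an explicit post-filter so genomic `N` never matches) is the production
path. `scan_motifs_naive()` / `census_naive()` re-derive the same answers
from plain character strings with a Perl lookahead regex and per-instance
interval arithmetic. The two share no matching machinery, so their exact
agreement — asserted over random sequence/pattern cases and over the full
synthetic census — is a genuine cross-check, and it is how the synthetic
truth is scored even when background sequence happens to spell out extra
motif instances or background calls land on a motif core.

## 2. Interface readout and methylation-sensitivity rules

### Contact model

From ATOM/HETATM coordinates (bio3d parser; first alternate location kept;
occupancy ignored for contact logic) the package classifies chains by
residue content and enumerates:

* **direct hydrogen bonds**: protein donor vs DNA acceptor or vice versa
  (His ND1/NE2 treated as both, protonation being unresolved in crystal
  models), within `d_hb = 3.5` Å. No donor–acceptor angle criterion is
  applied: crystal structures carry no hydrogens, and the distance window
  comfortably covers the 2.7–3.0 Å bonds typical of major-groove readout.
* **apolar proximities**: protein carbon/sulfur against the exposed
  CH/methyl carbons of the bases (purine C8, adenine C2, pyrimidine C5/C6,
  thymine C7), within `d_ap = 4.5` Å. Because only base carbons carry the
  apolar role, apolar contacts are base readout by construction.
* **water bridges**: a water oxygen within `d_hb` of one polar protein atom
  and one polar DNA atom, one record per (protein atom, water, DNA atom)
  triple; complementarity is not enforced through the water.

Each contact is labelled `base`, `phosphate` or `sugar` on the DNA side;
`readout_map()` reduces this to base-specific vs backbone-only residues and
lists the base-contacting protein residues per recognition helix (defaults:
the two major-groove helices of the WER R2R3 domain, residues 54–65 and
105–116; the ranges are parameters because deposited numbering can differ
from a paper's).

### Methylation-sensitivity rules

* **5mC / steric clash.** For each cytosine with at least one base contact,
  a virtual 5-methyl carbon is placed in the base plane along the exocyclic
  C4→C5 direction at 1.50 Å from C5 — an idealized planar placement with no
  rotamer search, because the argument being modelled is geometric
  proximity, not energetics. The site is flagged if any protein atom comes
  closer to that virtual carbon than the van der Waals sum minus a 0.4 Å
  tolerance (radii: C 1.70, N 1.55, O 1.52, S/P 1.80 Å — the standard
  steric-screen convention), *or* if an apolar contact to C5 itself exists
  at ≤ 4.0 Å: a hydrophobic probe packed against the C5 edge leaves no room
  for the methyl regardless of the virtual-atom geometry.
* **6mA / donor occlusion.** Any adenine whose N6 donates at least one
  direct base hydrogen bond is flagged; N6 methylation compromises exactly
  that donation. An adenine contacted only through N7 is deliberately not
  flagged: N7 is an acceptor and methylation at N6 does not remove it.

### Fixtures instead of depositions

Validation uses constructed interfaces, not downloaded ones:
`build_fixture()` assembles idealized planar nucleobases (template bond
lengths verified against standard values to well under 0.1 Å) and places
single probe atoms at exact distances. The composite
`wer_interface_fixture()` mirrors the canonical R2R3 readout geometry — Asn
carboxamides on the N7/N6 edge of both core adenines (2.9/3.0 Å), a Leu
methyl packed on the cytosine C5 (3.7 Å), Lys ammonium groups on the two
read-out guanine O6 atoms (2.9 and 2.7 Å) — and the tests assert that the
contact engine recovers exactly the planted list and flags exactly one 5mC
site and both 6mA sites. Checking the same five distances against a
deposited structure would additionally require the deposition itself; that
step needs network access and is out of scope for the test suite.

## 3. One-site ITC isotherm

### Forward model

For cumulative injected volume `v` into a cell of volume `V0 = 200` µl (the
nominal iTC200 working volume; configurable), the displaced-cell
concentrations are

* `Mt = M0 (1 − v/2V0) / (1 + v/2V0)` (macromolecule, the DNA duplex,
  default `M0 = 20` µM),
* `Xt = X0 (v/V0) / (1 + v/2V0)` (titrant, the protein, default
  `X0 = 400` µM),

the symmetric instrument-manual convention; the `Xt` form follows the same
convention (injected amount over the effective displaced volume). The
cumulative heat `Q` is the closed-form one-set-of-sites (Wiseman)
expression in `(n, Kd, ΔH)`, and the observable per-injection heat is
`ΔQ_i = Q_i − Q_{i−1} + (dV_i/V0)(Q_i + Q_{i−1})/2 + q0`, with `q0` a
per-injection baseline (dilution) heat and optional Gaussian noise. Units:
µM, µl, cal/mol, µcal. The default protocol (24 × 1.6 µl, 25 °C) is the
standard design this family of measurements uses.

### Fitting

`fit_one_site()` is nonlinear least squares over `(n, Kd, dH, q0)` with
Levenberg–Marquardt (minpack.lm). Numerical choices:

* The optimizer works in `(n, log Kd, ΔH/1000, q0)`: the log keeps `Kd`
  positive across its four-decade plausible range, and the rescaling of
  `ΔH` equalizes Jacobian column norms, without which the Gauss–Newton
  step is numerically singular at sensible starting values.
* Default starts: `n = 1`, `Kd = M0/10`, `ΔH = ±5000` cal/mol with the
  sign of the largest-magnitude heat, `q0 =` mean of the last three heats
  (the saturated tail). Bounds: `n ∈ [10⁻³, 10³]`, `Kd ∈ [10⁻³ nM, 1 M]`.
* Standard errors and the covariance matrix are mapped back to natural
  units by the delta method. Non-convergence is reported explicitly
  (`$converged`, with best-effort parameters), and `$identifiable` is
  `FALSE` whenever SEs are undefined or `SE(Kd) > Kd` — the all-zero
  thermogram, for instance, pins `ΔH ≈ 0` but leaves `Kd` unidentified.
* An optional `drop_first` discards the first injection (the usual
  first-injection artifact handling); the default keeps it, since
  simulated data have no such artifact.

`c_value()` reports `c = n·M0/Kd` with the usual `1 ≤ c ≤ 1000` fittable
window; the default protocol puts a 51 nM binder at `c ≈ 392`, well inside
it. Tests assert: exact noiseless recovery (within 1% for the 51 nM
reference affinity); median relative `Kd` error ≤ 10% over a grid
`Kd ∈ {0.02, 0.05, 0.5, 2.5}` µM × `n ∈ {0.8, 1, 1.2}` at 1% noise with
100 replicates per cell, with ±2·SE coverage ≥ 80%; heat-sum agreement
with the tight-binding closed form up to the O(v/V0) displacement term;
sign symmetry in `ΔH`; and refit idempotence.

## 4. What the synthetic generators emulate — and what they do not

`gen_genome()` draws i.i.d. background sequence at a set GC fraction
(default 0.36, a plant-genome-like value) and overwrites planted motif
instances — degenerate positions sampled uniformly from their allowed
sets — at recorded loci inside promoter windows, on random strands.
Background is deliberately memoryless: the census logic is position-exact,
not composition-sensitive, so Markov structure would add realism without
adding discriminating power. Spurious background matches are *allowed* and
handled by scoring against the naive reference scanner rather than against
the planted list alone — a collision policy that keeps the tests honest.

`gen_methylome()` draws per-motif flags with defaults
`p(5mC@3) = 0.10`, `p(6mA@1) = 0.005`, `p(6mA@2) = 0.015` — chosen once to
echo the strongly skewed ordering observed in plant methylomes (5mC far
more common than 6mA; position 2 more often modified than position 1)
while keeping expected counts large enough for binomial calibration checks
at 2,000 planted motifs — plus background calls at `10⁻³` per chemically
valid base (C for 5mC, A for 6mA, either strand).

Problem sizes used by the tests and the acceptance script — 1 Mb, 500
genes, 2,000 planted motifs for the census; 200 random scanner cases up to
5 kb; 1,200 simulated titrations — were chosen as the smallest scales at
which every statistical check is well-powered.

What passing these tests does *not* show: that a real genome census at a
particular annotation release reproduces any particular published count
(annotation and methylome versions dominate those numbers); that the
contact rules reproduce a particular deposition's geometry (no depositions
are read here); or that real baseline drift, first-injection artifacts and
concentration errors — none of which the thermogram generator emulates —
leave `Kd` recovery inside the simulated tolerances.

## 5. Known limitations

* The hydrogen-bond screen is distance-and-chemistry only; without an
  angle term, closely packed polar atoms can be over-counted as bonds.
* The 5mC rule's virtual methyl is planar-idealized; no rotamer search or
  energy model. It answers "is there room", not "what does it cost".
* Water bridges do not enforce donor/acceptor complementarity through the
  water, and multi-water relays are out of scope.
* The census treats the motif core positions 1–3 as the only methylatable
  readout positions; context classes of 5mC (CpG/CHG/CHH) are not
  distinguished.
* The isotherm is strictly one-set-of-sites; multi-site or sequential
  binding, and integration of raw power traces into injection heats, are
  out of scope.
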