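# mybdna

Tools for asking how an R2R3-MYB transcription factor reads its DNA target,
and how DNA methylation interferes with that readout. R2R3-MYB proteins —
the largest transcription-factor family in plants, exemplified by the
Arabidopsis root-hair regulator WEREWOLF (WER) — insert the third helices of
their two helix-turn-helix repeats into the DNA major groove and recognize a
degenerate element whose core is `5'-AACNDN-3'` (IUPAC `D` = A/G/T). Two
epigenetic marks sit directly on the read-out edge of that element:

* **5mC** (5-methylcytosine) adds a methyl group at the cytosine C5
  position, which can clash sterically with a hydrophobic side chain packed
  against the base;
* **6mA** (N6-methyladenine) compromises the adenine N6 amino group, whose
  hydrogen-bond *donation* to Asn carboxamides is how the two core adenines
  are recognized.

The package implements the three computational layers this kind of study
rests on, plus seeded synthetic-data generators so every layer can be
validated against recorded ground truth without any external downloads.

## What it computes

**1. Promoter motif–methylome census** — scan a genome for a degenerate
IUPAC motif restricted to promoter windows (default: 0–3 kb upstream of each
TSS), intersect instances with strand-specific single-base 5mC/6mA calls at
motif positions 1–3 (the `AAC` core), and tally the 8 methylation-category
combinations:

```
load_genome() -> derive_promoters() -> scan_motifs()
load_methylation() -> attach_methylation() -> tally_census()
```

A deliberately independent reference implementation
(`scan_motifs_naive()`, `census_naive()`: plain-string regex enumeration and
direct coordinate lookups) cross-validates the production
(Biostrings-based) path.

**2. Structure readout** — from PDB-format coordinates of a protein–DNA
complex: direct hydrogen bonds (donor/acceptor complementarity within
3.5 Å; no angle term, since crystal models carry no hydrogens), apolar
proximities (protein C/S against exposed base carbons within 4.5 Å),
single-water bridges, a per-residue base-specific vs backbone-only readout
map, and two methylation-sensitivity rules:

* *5mC steric clash*: place a virtual methyl carbon in the base plane along
  C4→C5 at 1.5 Å from C5 of every contacted cytosine; flag if it penetrates
  any protein atom's van der Waals envelope (tolerance 0.4 Å), or if an
  apolar contact to C5 itself exists at ≤ 4.0 Å.
* *6mA donor occlusion*: flag every adenine whose N6 donates at least one
  direct base hydrogen bond.

**3. One-site ITC isotherm** — forward simulation and Levenberg–Marquardt
fitting of the Wiseman one-set-of-sites model. With cumulative titrant and
macromolecule concentrations `Xt`, `Mt` (displacement-corrected), the
cumulative heat is

```
Q = (n·Mt·ΔH·V0/2) · [ 1 + Xt/(n·Mt) + Kd/(n·Mt)
                       − sqrt( (1 + Xt/(n·Mt) + Kd/(n·Mt))² − 4·Xt/(n·Mt) ) ]
```

and per-injection heats are differences of `Q` with the standard
injection-volume correction. `fit_one_site()` returns a classed `itc_fit`
object with `print`, `summary`, `coef`, `vcov`, `predict`, `residuals`,
`plot` and `simulate` methods. `fold_change()` and `c_value()` summarize
affinity ratios and the `c = n·M0/Kd` design diagnostic.

**4. Synthetic data** — `gen_genome()` (planted motif instances at recorded
loci inside promoter windows), `gen_methylome()` (per-motif flags plus
background calls on chemically valid bases only), `build_fixture()` /
`wer_interface_fixture()` (idealized planar nucleobases with probe atoms at
exact distances, written as PDB), `gen_thermograms()`. All are
deterministic under a seed and serialize their ground truth as JSON.

`run_census()`, `run_readout()` and `run_demo()` chain the stages;
`inst/cli/myb.R` is a thin Rscript dispatcher over the same functions.

## Worked example

```r
library(mybdna)

# The EMSA/ITC probe duplex carries exactly one AACNDN site:
g <- Biostrings::DNAStringSet(c(probe = "AAATTCTCCAACCGCATTTTC"))
scan_motifs(g, "AACNDN")
#>   chrom start end strand matched_seq gene_ids
#> 1 probe     9  15      +      AACCGC     <NA>

# Composite interface fixture: Asn pairs on both adenines, Leu on the
# cytosine C5, Lys on the two read-out guanines
fx <- wer_interface_fixture()
model <- parse_structure(fx$path)
contacts <- find_contacts(model)
predict_methyl_sensitivity(model, contacts)[, c("dna_res", "modification", "mechanism")]
#>   dna_res modification       mechanism
#> 1      DC          5mC    steric-clash
#> 2      DA          6mA donor-occlusion
#> 3      DA          6mA donor-occlusion

# Simulate and refit a 51 nM binder under the default iTC200-style protocol
prot <- itc_protocol()                      # 24 x 1.6 ul, 400 uM into 20 uM
tg  <- simulate_titration(binding_params(1, Kd = 0.051, dH = -8000), prot)
fit <- fit_one_site(tg, prot)
fit
#> One-site ITC fit
#>   n  = 1.000
#>   Kd = 0.051 uM (51.0 nM)
#>   dH = -8000 cal/mol
#>   q0 = 0.000 ucal;  RSS = 1.907e-21 ucal^2;  converged

fold_change(2.336, 0.051)   # 5mC-modified site vs unmodified: 45.8-fold
c_value(binding_params(1, 0.051, -8000), prot)$c   # 392, fittable window
```

The one-shot demo generates a synthetic genome + methylome + fixture +
thermograms, runs every stage against its recorded truth and writes a JSON
report:

```r
run_demo(seed = 1, out_dir = "demo-out")
```

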