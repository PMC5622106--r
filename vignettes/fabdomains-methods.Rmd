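---
title: "Methods: sequence composition, electrostatics and surface burial of Fab domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence composition, electrostatics and surface burial of Fab domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabdomains)
```

# Scope

`fabdomains` analyses the four domains of antibody Fab fragments (VH,
CH1, VL, CL) and, by extension, immunoglobulin-superfamily (IgSF)
domains, from two directions:

* **sequence-based**: amino-acid composition, Shannon sequence
  entropy, lysine-minus-arginine (K−R), isoelectric point, aromatic
  content, and a charge/hydropathy folding propensity, each optionally
  expressed as a z-score against a reference population;
* **structure-based**: the contribution of ionisable groups to
  folded-state stability and to dimerisation at pH 7 under a
  Debye-Hückel continuum model with Monte Carlo protonation-state
  sampling, and solvent-accessible surface area (SASA) with interface
  burial.

A curation pipeline assembles Fab datasets from PDB-format files, and
a scan identifies IgSF domains whose composition deviates from CL in
the same direction as CH1 does. The scientific motivation is that CH1
behaves as an atypical intrinsically disordered domain until it pairs
with CL, and that its composition signature (not its sequence
identity) may mark other IgSF domains with the same behaviour.

# Sequence-based properties

**Composition and entropy.** A sequence's composition vector holds the
fraction of each of the 20 amino acids. Its Shannon entropy
$S = -\sum_a f_a \log_2 f_a$ ranges from 0 bits for a homopolymer to
$\log_2 20 \approx 4.32$ bits for equal use of all amino acids. Base-2
logarithms are used so that the theoretical maximum is 4.32. Ambiguity
codes (X, B, Z, U, O, J) are dropped with a warning before any
composition statistic: their composition contribution is undefined.

**K−R and aromatic content** are linear functionals of the composition
(percentage points); lysine is associated with higher solubility than
arginine, so K−R acts as a solubility correlate.

**Isoelectric point.** The net charge
$Q(\mathrm{pH}) = \sum_{\mathrm{basic}} \frac{1}{1+10^{\mathrm{pH}-pK_a}}
 - \sum_{\mathrm{acidic}} \frac{1}{1+10^{pK_a-\mathrm{pH}}}$
(side chains plus both termini) is monotone in pH; the pI is its zero,
found by bisection to $|Q| < 10^{-6}$. The pKa table defaults to the
EMBOSS values and is fully configurable, since no single table is
canonical. Histidine is treated as a (weak) base here. Sequences with
only basic or only acidic groups have no crossing; the declared caps
14 and 0 are returned with a `capped` attribute rather than an error,
so tabular workflows keep the row.

**Folding propensity.** A boundary-line discriminant in the
charge/hydropathy plane:
$FP = c_1 \langle H \rangle - |\langle R \rangle| - c_0$, with
$\langle H \rangle$ the Kyte–Doolittle hydropathy rescaled to $[0,1]$
and $\langle R \rangle$ the mean net charge per residue at neutral pH
(D, E = −1; K, R = +1; H = 0 by default). $FP > 0$ predicts a folded
protein. The defaults $c_1 = 2.785$, $c_0 = 1.151$ are the classic
charge/hydropathy boundary; both are arguments because variants of
this discriminant differ in their constants, and we prefer an explicit
knob over a hidden choice.

**z-scores.** `fit_reference_population()` computes per-property mean
and SD over any sequence set (a FASTA file is accepted), and
`zscore()` reports $(x-\mu)/\sigma$. The shipped default population is
synthetic (below); a real proteome-scale set, e.g. an *E. coli*
solubility panel, can be dropped in without code changes.

# Fab curation

Structures are read with **bio3d**; only chains named `H` and `L` are
retained, and sequences are taken from the observed `ATOM` residues in
author order rather than SEQRES, because every residue the
structure-based calculations count must have coordinates. Records
missing either chain are rejected with a reason; a chain id whose atom
records appear in non-contiguous blocks is ambiguous and an error.
Non-standard residues with a clear parent (MSE, SEP, ...) are mapped
to it; anything else becomes X and is excluded from composition
statistics (but still counts for positions).

The pipeline applies, in order:

1. **chain-length quartile filter** — keep records whose heavy and
   light chain lengths both lie within the (linear-interpolation)
   lower and upper quartiles of the input, bounds inclusive;
2. **motif split** — the constant domain starts at the first match of
   `VS[SA]` with first residue in positions 110–130 (heavy), and of
   `E[LIV]KR` — falling back to `TVL[GSA]` — in positions 100–115
   (light). Both windows are 1-based indices into the observed-residue
   sequence. The motif is assigned to the constant domain; this
   ownership, the windows, and the patterns are configurable because
   the convention could reasonably be flipped;
3. **domain length filter** — recompute each domain class's mean
   length and keep records whose four domains all lie within ±10
   residues of their class means.

Stage counts are monotonically non-increasing and every exclusion
carries a reason code, so reports from the same inputs are
byte-identical. CDR annotations (a TSV of `pdb_id, chain, cdr_name,
start, end` in observed-sequence coordinates) can be concatenated, in
table order, into one combined CDR sequence per Fab.

# Ionisable-group electrostatics

Sites are one per ionisable residue (Asp, Glu, His, Lys, Arg, Tyr,
Cys) plus both termini of every chain, positioned at the centroid of
the charged-group atoms, with a residue-centroid fallback (and
warning) when those atoms are missing. Cys pairs with SG–SG < 2.5 Å
are taken as disulphides and removed from titration.

The pairwise interaction is a screened Coulomb term with the
dielectric of bulk water:
$W_{ij} = \frac{C\, e^{-\kappa r_{ij}}}{\varepsilon_r\, r_{ij}}$,
$C = \frac{e^2 N_A}{4\pi\varepsilon_0} \approx 1389.35$ kJ Å/mol,
with $\kappa$ from the standard Debye expression (defaults
$\varepsilon_r = 78.4$, $I = 0.15$ M, $T = 298.15$ K, no ion-exclusion
radius). There is no dielectric boundary, desolvation or Born term:
the model treats all sites as solvent-exposed, which is the regime
where a uniform-dielectric Debye-Hückel description works well.
Distances below 2 Å are clamped with a warning — a point-charge
continuum is meaningless at sub-contact separations.

A protonation microstate $x$ assigns 0/1 protons to each site; its
energy is
$E(x) = \sum_i \ln(10)\, RT\, (\mathrm{pH} - pK_{a,i})\,\mathrm{prot}_i
 + \sum_{i<j} W_{ij} q_i q_j$
with $q_i = \mathrm{prot}_i - [\text{acid}]$, so an isolated site
recovers Henderson–Hasselbalch exactly. Model pKas (Asp 4.0, Glu 4.4,
His 6.3, Lys 10.4, Arg 12.0, Tyr 9.6, Cys 8.3, N-term 7.5, C-term
3.8) are a configurable table. The ionisable-group interaction free
energy is
$\Delta G_{\mathrm{charge}}(\mathrm{pH}) = -RT \ln (Z / Z_{\mathrm{free}})$,
where $Z_{\mathrm{free}}$ sets all $W_{ij}=0$; the unfolded state is
thus the non-interacting sites at their model pKas, so the
folded/unfolded difference is purely the interaction term. Negative
values mean the charge network stabilises the fold. Dimerisation
contributions are the subtraction
$\Delta\Delta G = \Delta G(AB) - \Delta G(A) - \Delta G(B)$.

**Exact vs Monte Carlo.** Up to 20 sites, $Z$ is summed over all
$2^N$ microstates (log-sum-exp stabilised). Beyond that, Metropolis
sampling over single-site flips (plus paired flips for site pairs with
$|W_{ij}|$ above 2 kJ/mol, which de-traps tight salt bridges) gives
mean protonations with batch-means standard errors, and
$\Delta G_{\mathrm{charge}}$ comes from thermodynamic integration of
$\langle E_{\mathrm{int}} \rangle_\lambda$ over a coupling parameter
$\lambda$ scaling all $W_{ij}$, on a uniform 5-point ladder with the
trapezoidal rule. Direct perturbation from the non-interacting
reference has poor overlap for large charged systems; the λ-path does
not. Defaults are 8000 sweeps with 1000 discarded, 20 batches; with
these settings Monte Carlo agrees with exact enumeration within 3
standard errors across randomised systems of up to 12 sites (this is a
tested invariant). Runs are reproducible for a fixed seed; the sampler
uses R's RNG. A ΔG standard error above 1 kJ/mol flags
non-convergence with a warning rather than failing silently.

Apparent pKas are read off the titration curve (pH grid 0–14, step
0.25 by default) as the interpolated pH of half-protonation;
$\Delta G_{\mathrm{charge}}$ is always evaluated at exactly pH 7.0.

# Solvent-accessible surface area

A Shrake–Rupley implementation: each atom's sphere is expanded by the
probe radius (1.4 Å), sampled with quasi-uniform golden-spiral points
(960 per atom by default), and the accessible fraction is the share of
points not inside any neighbouring expanded sphere. Radii come from a
standard per-element table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å,
configurable); an element without a radius is an error naming the
atom, not a silent guess. Totals are partitioned into polar (N, O) and
non-polar contributions; sulphur counts as non-polar by default. The
implementation reproduces the isolated-sphere and two-sphere
spherical-cap closed forms to well under 1% at the default point
count, and totals are rotation/translation invariant to sampling
noise. Interface burial is the subtraction
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$, checked
against an atom-count match between the dimer and its subunits. The
accessible surface (not the molecular/Connolly surface) is what is
computed and reported.

# The IgSF scan

For a query composition $X$ and representative CH1 and CL
compositions, the score is the cosine between the differenced vectors
$X - CL_{\mathrm{REF}}$ and $CH1_{\mathrm{REF}} - CL_{\mathrm{REF}}$
over the 20 raw composition components (raw fractions, not z-scores:
z-scoring rescales axes per-property and would change the geometry the
threshold was defined on). A domain is called CH1-like when cosine
> 0.3 **and** entropy < 3.83 bits, both strict; results are ranked by
cosine with the id as a deterministic tie-break. Either reference can
be swapped in from FASTA; degenerate configurations (query equal to
the CL reference, or identical references) are errors rather than
NaNs.

# Synthetic data: what it emulates and what it does not

All fixtures are generated in code, deterministically from a seed.

* **Fab-like chain pairs** carry exactly one interdomain motif inside
  the search window, at a requested position; in-window sampling
  excludes the letters that could seed a spurious match, so split
  positions are known ground truth. Chain lengths default to the
  quartile bands typical of real Fab datasets (heavy 219–228, light
  213–218).
* **Coarse-grained Fab structures** place one CA per residue on a
  compact lattice, one block per domain, plus the charged-group atoms
  of ionisable residues. The layout encodes two features of real Fabs
  that the interface analyses need: the CL:CH1 blocks sit closer than
  the VL:VH blocks (so the constant interface buries more surface),
  and basic CH1 residues face acidic CL residues across the constant
  interface (salt bridging). Because the generator concentrates each
  constant domain's charged residues on one face, the *isolated*
  constant-domain folding energies are dominated by that designed face
  and are not realistic; only the interface subtraction and the
  CL:CH1 vs VL:VH orderings are meaningful for these structures. No
  attempt is made to mimic the Ig fold itself.
* **Reference populations**: each sequence's K−R is realised by
  construction from a normal draw (so the population mean and SD match
  their targets); other properties take the values the background
  composition implies. An entropy target, when given, is met in the
  mean by calibrating the background Dirichlet concentration with a
  monotone search; a target above $\log_2 20$ is rejected as
  infeasible. SDs other than K−R's are realised, not controlled —
  controlling all five property SDs of one sequence set simultaneously
  is over-constrained.
* **IgSF cohorts**: background domains draw their compositions around
  a near-uniform profile (Dirichlet concentration 200), giving high
  entropy and a composition deviation from CL pointing away from the
  CH1 direction; planted domains draw around a CH1-like profile
  (enriched P, S, T, V, G; depleted D, E, F, I, Q, R, Y; profile
  entropy ≈ 3.55 bits), placed along the CL→CH1 direction. The
  planted class is therefore constructed to satisfy the scan's
  double threshold, and the recovery test checks the scan's geometry,
  not a discovery claim. Real IgSF domains spread continuously in the
  (cosine, entropy) plane; this cohort is deliberately bimodal, so a
  passing recovery test says the scan separates what is separable, not
  that real cohorts are this clean.

# Problem sizes and numerical choices

The shipped analyses and tests use 50 synthetic Fabs for curation, 4
for the structure-based interface analyses, 205-domain IgSF cohorts,
a 1000-sequence reference population, 50 randomised ≤12-site systems
for the exact-vs-Monte-Carlo cross-check, and 240–960 SASA points —
sizes chosen so the full pipeline re-runs from scratch in a few
minutes while keeping every statistical check comfortably powered.
Other conventions: quartiles are `stats::quantile` type 7; motif ties
break leftmost; entropy uses only non-zero fractions (0·log 0 = 0);
cosine values are clipped to [−1, 1] against rounding; exact
enumeration is capped at 20 sites (beyond which `mc_titration()` is
directed); JSON/TSV outputs are plain text.

# Known limitations

* The electrostatic model has no desolvation, dielectric boundary or
  conformational sampling; buried charges are treated as if exposed.
  Absolute ΔG values are therefore model-scale numbers, most useful
  comparatively (between domains or interfaces).
* pI and folding-propensity constants are table-driven conventions;
  alternative tables shift absolute values.
* The curation pipeline assumes the H/L chain-naming convention and
  one Fab per file; non-standard naming is out of scope by design.
* The synthetic structures are lattice toys: right for exercising
  subtraction schemes, round-trips and orderings, wrong for any
  absolute structural quantity.
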