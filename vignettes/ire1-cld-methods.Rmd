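---
title: "Methods: quantifying unfolded-protein sensing by the IRE1alpha core lumenal domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying unfolded-protein sensing by the IRE1alpha core lumenal domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ire1cld)
```

## Scope

The endoplasmic-reticulum stress sensor IRE1alpha decides whether to fire
the unfolded-protein response by directly binding unfolded polypeptides
with its core lumenal domain (cLD) and oligomerizing.  This package
implements the quantitative methods used to characterize that mechanism:

1. **Peptide tiling arrays** — which amino acids does the cLD prefer?
2. **Equilibrium binding fits** — how tight is binding, and does tandem
   repetition of a binding element produce avidity?
3. **Chemical-shift perturbation (CSP) and PRE mapping** — where on the
   cLD does the peptide land?
4. **Cross-link distance restraints and groove geometry** — how do cLD
   protomers arrange into oligomers, and how long a peptide fits the
   binding groove?

Every method is paired with a synthetic-data generator that produces its
input with known ground truth, so each analysis can be validated end to
end against what was injected.

## The binding model

All titrations are modeled with the log-dose Hill-type isotherm

$$ y(x) = y_\mathrm{free} + \frac{y_\mathrm{max} - y_\mathrm{free}}
   {1 + 10^{\,(\log_{10} K_{1/2} - x)\, n_H}}, $$

where $x = \log_{10}$ of concentration in uM, $K_{1/2}$ is the apparent
half-saturation constant, and $n_H$ the Hill slope.  $K_{1/2}$ is an
*apparent* midpoint, not a thermodynamic $K_d$: for a tandem-repeat
ligand binding a partially oligomeric receptor the isotherm is an
effective description, which is exactly why it is the right quantity to
compare across constructs (for example, the roughly 35-fold drop in
$K_{1/2}$ from MPZ1-N to its tandem repeat MPZ1-N-2X is the avidity
signature).

### Fitting choices

`fit_binding()` minimizes least squares with `minpack.lm::nls.lm`
(Levenberg-Marquardt), with:

* **Multistart over the midpoint.**  Five starts spread across the
  concentration window guard against the local minima that plague
  sigmoid fits when the plateau is poorly sampled.
* **Box constraints.**  $n_H \in [0.3, 5]$, and plateaus constrained to
  the data range padded by 50% of its span.  These are physical-range
  guards, not tuning: slopes outside that range do not occur for
  single-site or modestly cooperative binding.
* **Standard errors** from the inverse Hessian at the optimum; the SE of
  $K_{1/2}$ follows from the SE of $\log_{10} K_{1/2}$ by the delta
  method.
* **Diagnostics, not silent answers.**  A midpoint more than 10-fold
  outside the titrated range is flagged `extrapolated`; a response with
  no dose trend is an error ("no binding signal"), never a number.

Thermophoresis (MST) traces are first normalized to fraction bound with
`normalize_mst()`; the same isotherm and fitter then apply.

### Accuracy of recovery

With the default generator noise (responses 0.05–0.25, sd 0.005, 16
points over a 3.7-decade window) the median fitted $K_{1/2}$ over 100
replicates is within 2% of truth across the 0.456–29.2 uM range used in
this work, and the nominal 95% confidence interval covers truth 88–98%
of the time.  These properties are asserted in the test suite.

## Peptide tiling arrays

`array_design()` fixes the experimental layout: 18-mer tiles stepped by
3 residues, per-replicate max normalization, and a top decile (ceiling)
of spots selected per replicate.  Amino-acid enrichment for residue $a$
is

$$ E(a) = \log_2 \frac{f_\mathrm{top}(a)}{f_\mathrm{all}(a)}, $$

the frequency of $a$ among top-spot residues over its frequency in the
whole array.  Numerical choices:

* **0.5 pseudo-count** when an amino acid is absent from the top set
  (flagged in the output), so depletion is reported as a finite,
  conservative value instead of $-\infty$.
* **Per-replicate selection.**  The top set is chosen within each
  replicate and $E(a)$ computed per replicate; a one-sample *t*-test of
  the replicate values against 0 gives the p-value.  This treats
  replicates as the unit of independence, which they are — spots within
  one replicate share the normalization and the spot-level noise model.
* **Calibration.**  Under a null generator with equal weights the
  per-amino-acid test fires at slightly below its nominal 5% level
  (measured 3–4% over 200 null arrays).  The deficit is expected:
  residue counts within an array are correlated (neighboring tiles share
  15 of 18 residues) and the counts are discrete, both of which make the
  *t*-test conservative here.  The test suite asserts the empirical rate
  lies in [0.02, 0.08].

`compare_probes()` contrasts the spot intensities of two probes by an
unpaired two-sample *t*-test.

## NMR: CSP classification and PRE profiles

Peaks between two lists are paired by **mutual nearest neighbors** in a
scaled (1H, 13C) space (tolerances 0.03 and 0.15 ppm); a peak present in
the reference with no partner is *vanished*, the converse *appeared*.
Assignment-by-disappearance is only reported when it is unambiguous: one
vanished peak and nothing appeared.

The combined perturbation is

$$ \Delta\nu = \sqrt{\Delta\delta_H^2 + (0.25\,\Delta\delta_C)^2}, $$

classified with strict thresholds: none $\le$ 0.005 < slight $\le$ 0.010
< moderate $\le$ 0.020 < significant (ppm).  Boundaries are **strict**
(a value exactly at a threshold takes the lower class) so the
classification is a deterministic function of $\Delta\nu$ with no
floating-point ambiguity about which side "equal" falls on.

PRE broadening is the intensity ratio $I_\mathrm{PRE}/I_0$ (an
`invert` flag accepts data tabulated the other way); vanished peaks get
ratio 0.  Because a surface-buried probe cannot report on an external
spin label, ratios are normalized by the residue's solvent-accessible
surface fraction and sorted ascending — the top of the list is the part
of the protein closest to the label.

### SASA

Solvent accessibility uses a hand-implemented Shrake-Rupley: 960
golden-spiral test points per atom on the sphere of radius
$r_\mathrm{vdW} + 1.4$ Å.  No installed package exposes a plain SASA
primitive on arbitrary coordinates, and the algorithm is small enough
that implementing it buys an exact, testable specification: the test
suite checks an isolated sphere against the closed form to <0.5% and a
two-sphere overlap against the analytic spherical-cap area to <2%, plus
a Monte-Carlo rejection oracle.

## Cross-links, restraints and groove geometry

The BS3 lysine-lysine cross-link abundance table (six pairs, quantified
per oligomer band with and without peptide) ships as package data
(`ire1_xlink_table()`).  `classify_xlinks()` labels a pair
**inter-molecular** when it has signal only in oligomer bands (any
monomer-band abundance disqualifies it), and **abundant** at a 1%
threshold in the dominant band — which leaves the five links that
nominate the oligomer interface.

`check_restraints()` evaluates Cα–Cα distances against the BS3 limits:
satisfied < 28 Å, **[28, 33] Å marginal (closed interval)**, violated
> 33 Å.  The closed interval means the published limit values
themselves are reported as marginal rather than silently promoted or
demoted.  On multi-chain models the distance is minimized over all
allowed chain assignments (intra-chain always; inter-chain when
requested), so a self-pair such as K121–K121 is only measurable across
protomers; residues absent from the model are reported `unmappable`,
never dropped.

`peptide_fits_groove()` encodes the extended-chain argument: at 3.4 Å
per residue-residue step, an $n$-mer spans $(n-1)\times 3.4$ Å, so a
12-mer (37.4 Å) fits the 39 Å groove and a 13-mer (40.8 Å) does not.

## The synthetic-data layer

Generators are deliberately simple but structured like the experiments:

* **Arrays** (`gen_array()`): log-intensity is the sum of per-residue
  weights plus Gaussian noise, one draw per (spot, replicate), each
  seeded individually so any subset of the array is reproducible in
  isolation.
* **Titrations** (`gen_titration()`): the isotherm plus i.i.d. Gaussian
  noise at experimentally typical amplitude.
* **Peak lists** (`gen_peaklists()`): designated peaks shifted by
  specified (1H, 13C) amounts, vanished or appeared on request, with
  small common jitter.
* **Structures** (`gen_helix()`): parametric Cα helices
  (radius 2.3 Å, rise 1.5 Å per residue, 100° twist), enough to give
  restraint and SASA code nontrivial geometry with known answers.

Defaults reproduce study conditions (three 300-residue proteins, three
replicates, 16-point titrations, 0.005 noise) and are fixed independent
of any downstream check.

All randomness flows from integer seeds through `derive_seed()`, a
Lehmer-style hash that maps a master seed plus arbitrary labels to a
stream-specific seed below $2^{31}$, so pipelines are deterministic and
individual entities re-simulable.

## Limitations

* The isotherm is an apparent-affinity description; it does not model
  linked oligomerization equilibria, depletion of the labeled species,
  or MST-specific artifacts beyond rescaling.
* Array noise is i.i.d. per spot; real arrays have spatial and
  synthesis-quality artifacts the null calibration does not cover.
* Peak matching is geometric; heavily overlapped spectra need manual
  assignment, and the matcher will report such peaks as unmatched rather
  than guess.
* SASA uses a fixed per-element radius table and treats all atoms as
  spheres; for Cα-only models the per-residue values are coarse and are
  used only as relative exposure weights.
* The helix generator produces ideal geometry; it is a test fixture, not
  a structural model of the cLD.
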