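---
title: "Decoding liquid glycan array experiments: models and methods"
author: "ligar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding liquid glycan array experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligar)
```

# The platform and what the package computes

A liquid glycan array (LiGA) is a mixture of M13 phage clones, each
displaying one glycan structure at a controlled mean density on its major
coat protein pVIII (about 2700 copies per virion) and each carrying a
distinct DNA barcode in its genome. Panning the mixture against a
glycan-binding protein (GBP), a receptor-bearing cell line, or an organ in
vivo, followed by deep sequencing of the recovered phage, turns a binding
experiment into a counting experiment: clones whose glycan (structure,
density) combination engages the target are enriched relative to a control
condition.

`ligar` implements the complete dry-lab side of such experiments:

1. **dictionary** — the lookup table from silent double barcodes (SDBs) to
   glycan structure and display density, with genetic-code validation;
2. **demux** — demultiplexing paired-end amplicon reads into a clone ×
   sample count matrix;
3. **enrichment** — normalization, negative-binomial testing, and
   Benjamini–Hochberg FDR control for clone-level fold changes;
4. **maldi** — quantification of pVIII modification from MALDI-TOF spectra
   (display density, enzymatic conversion time courses);
5. **affinity** — dissociation constants from direct native-MS titrations;
6. **synth** — seeded generators for every input, with ground truth, so the
   entire pipeline is testable without external data.

# Silent double barcodes

The barcode region is *silent*: every variant encodes the same peptide
(default `SVEKY`) in the phage genome, so clones are genetically
distinguishable without altering the coat protein. `validate_silent_coding()`
translates each concatenated barcode in the dictionary's reading frame with
the standard genetic code and flags any entry whose peptide deviates (a stop
codon or frame problem is a flagged violation, not an error). Fixture
dictionaries built by `build_fixture()` draw barcodes from the synonymous
codon spellings of the expected peptide — 6 × 4 × 2 × 2 × 2 = 192 distinct
spellings for `SVEKY` — so they pass validation by construction. The first
three codons form SDB1 and the last two SDB2; lookups use the concatenated
string as a single key.

Three designs are provided, mirroring the library architectures the
platform is used with: `liga6x5` (six N-glycan structures × five densities
{50, 150, 500, 750, 1000} glycans/phage, plus 10 azidoethanol-capped
invariant clones), `msdb_man3` (paucimannose at five densities × seven
barcodes each, for multi-barcode confirmation of density effects), and
`invivo` (the 6×5 clones plus 16 unmodified and 10 azidoethanol blanks, the
invariant baseline for organ-homing experiments).

Display density converts to pVIII occupancy as `100 × density / 2700`;
`density_to_occupancy(1000)` is 37.04%, conventionally rounded to one
significant figure as 40%.

# Demultiplexing model

Each forward read carries both SDB regions, each bracketed by constant
flanks. Extraction scans for the upstream flank — exact match first, then a
Hamming scan tolerating up to `max_flank_mismatch` substitutions; the
leftmost qualifying position wins and the scan never extends past the first
exact hit — and takes
the fixed-length barcode immediately after it; the downstream flank is
verified when it fully fits on the read. Dictionary lookup is exact by
default (`max_mismatch = 0`; no error correction is assumed), with an
optional rescue of barcodes having a *unique* Hamming-1 neighbour.
Ambiguous or unlocatable reads are discarded and counted as unmapped;
`mapped + unmapped = total` holds per sample by construction.

Only the forward read is searched; the mate is a pass-through. The
simulator (`simulate_fastq()`) writes both mates with the same per-base
substitution error model, so the round trip at error rate 0 reproduces the
intended counts exactly, and at error rate ε the mapped fraction is
approximately (1−ε)^15 for the 15-nt barcode.

# Differential enrichment model

Counts for clone *i* in sample *s* are modelled as negative binomial with
mean μ_is and dispersion φ (variance μ + φμ²).

**Normalization.** The default assumes a designated set of clones —
azidoethanol-capped phage in vitro, unmodified phage in vivo — is invariant
between conditions. Per-sample factors are the median, over invariant
clones, of the ratio of the clone's count to its geometric-mean
pseudo-reference across samples (median-of-ratios, the same estimator
DESeq-style size factors use, restricted to the invariant set), rescaled to
geometric mean 1. The median was chosen over the mean for robustness to a
single aberrant invariant clone; invariant clones with a zero count in any
sample carry no usable ratio and are excluded with a warning. Trimmed mean
of M-values (TMM; 30% M-trim, 5% A-trim, precision weights, reference =
sample with median library size) and plain library-size factors
("naive-composition" scaling) are provided for datasets where invariant
reads are too shallow.

**Dispersion.** A common dispersion is estimated by maximizing the
conditional likelihood of the replicate-group counts given their group
totals — a function of φ only, free of the clone means — on counts adjusted
to a common scale (divided by size factors and rounded to the nearest
integer; rounding keeps the conditional distribution well defined, at the
cost of a small sub-integer perturbation that is negligible at the count
depths of these experiments). Per-clone estimates can be shrunk toward the
common value with a configurable weight (default 0.8); the default test
uses the common dispersion, which at 3-vs-3 replication is substantially
more stable than per-clone estimates. With no replicated group anywhere the
estimator returns a configured floor (0.05) and raises a warning flag.

**Testing.** For a two-group contrast the adjusted counts are summed within
groups; conditional on the grand total, the first group's sum follows a
negative-hypergeometric law under the null (the conditional distribution of
independent NB sums with a common dispersion), and the two-sided p-value is
the total probability of outcomes no more probable than the observed one.
At dispersion 0 this reduces *exactly* to the conditional binomial test,
which is verified against `binom.test` for every total up to 50. Fold
changes are reported as log2 of the ratio of normalized group means with a
prior count of 0.5 added to both (finite at zero counts); their standard
deviation is propagated by the delta method from the NB variance of the
normalized counts. Benjamini–Hochberg adjustment controls the FDR at
α = 0.05.

The package deliberately re-implements this machinery rather than calling
edgeR (which the field uses): the exact-test construction is the scientific
core of the readout, and owning it makes its assumptions explicit and
testable. Agreement with edgeR is asserted at the level of statistical
behaviour (rank agreement of p-values on simulated data), not bit-for-bit.
Simulation at the study conditions (40 clones, 3v3, dispersion 0.1, 20% of
glycan clones enriched 8-fold) shows a mean false-discovery proportion at
the nominal 0.05 within Monte-Carlo error, and full power for 8-fold
enrichment at typical depths.

Secondary comparisons of fold changes between clone groups (e.g. glycan
classes across organs) use the standard tools: a two-sided Mann–Whitney U
test, exact when both groups have ≤ 10 observations without ties, and a
standard one-way ANOVA F-test; both are delegated to base R.

# MALDI-TOF quantification

Glycophage spectra show unmodified pVIII, DBCO-functionalized pVIII, and
glycoconjugate peaks. The processing chain is:

1. **Preprocess** — baseline as a rolling minimum followed by a rolling mean
   of the same window (150 Da default), subtracted and clipped at zero,
   then a narrow (3-point) moving average. The narrow smoother keeps
   preprocessing nearly idempotent (< 1% intensity change on a second
   pass).
2. **Predict species** — conjugate mass = pVIII base + DBCO adduct + linker
   + Σ residue masses (Hex 162.0528, HexNAc 203.0794, Neu5Ac 291.0954,
   dHex 146.0579 Da). The pVIII base (5238.4 Da) and adduct masses are
   configuration constants to be matched to the instrument calibration.
   Each species carrying k ≥ 1 sialic acids emits ghost companions at
   −291.0954·j Da (j = 1..k): in-source sialic-acid loss produces artifact
   peaks that do not correspond to reaction products.
3. **Fit** — per species, a Gaussian is least-squares fit in the window
   expected mass ± tolerance (40 Da default); overlapping windows are fit
   jointly as a Gaussian sum (bounded: σ ∈ [0.5, 20] Da, amplitude ≥ 0,
   center within the window). The noise level is estimated robustly from
   first differences (`mad(diff(y))/√2`, blind to smooth peaks); species
   whose local maximum is below 8× that level get area 0. If the joint fit
   fails to converge, moment estimates over the window are used as a
   fallback.
4. **Quantify** — fractions are areas over total; with ghost correction each
   ghost's area is reassigned to its parent before normalizing, which
   changes attribution but never the total.
5. **Density** — the modified fraction (sum of non-pVIII fractions) times
   the 2700 available pVIII copies, rounded to the nearest integer. Density
   is best estimated at the DBCO stage (pVIII vs DBCO-pVIII): sialylated
   conjugates ionize less efficiently, so conjugate-stage fractions are
   biased; the simulator exposes this bias through its
   `sialyl_suppression` parameter.

`conversion_timecourse()` applies the same quantification per timepoint of
an enzymatic series and reports percent composition (rows sum to 100).

On synthetic spectra, density recovery error decreases monotonically with
SNR and is within ±25 glycans/virion at SNR 100 for mid-range densities. A
known limit: at 50 glycans/virion the DBCO peak is ~2% of the base peak and
sits near the detection threshold at realistic noise, so low-density
estimates are noise-dominated — as they are for the real measurement.

# Affinity from direct native-MS titrations

The abundance ratio R of ligand-bound to free protein — summed over charge
states of charge-state-normalized peak areas — is taken equal to the
solution concentration ratio [PL]/[P]. The fraction bound follows the 1:1
equilibrium closed form

$$\frac{R}{R+1} \;=\; \frac{[P]_0 + [L]_0 + K_d -
\sqrt{(K_d - [L]_0 + [P]_0)^2 + 4 K_d [L]_0}}{2\,[P]_0},$$

monotone in [L]0 and K_d and bounded in [0, 1]. `fit_kd()` fits this curve
to the observed fraction bound by nonlinear least squares with uniform
weights (the measurement protocol gives no per-point variances), K_d
parameterized on the log scale for positivity, initialized by a log-grid
search over [1e-3, 1e4] µM so the single-parameter fit cannot be trapped at
an interior local minimum. The standard error uses the Jacobian at the
solution with a heteroscedasticity-robust (HC3) sandwich: abundance noise
is multiplicative in R, so residual variance in fraction-bound space varies
systematically along the curve and the plain least-squares variance
understates uncertainty mid-titration. Noiseless curves are recovered to
optimizer tolerance at both the weak (75 µM) and tight (0.77 µM) scales;
under 5% multiplicative noise the median relative error is ~2% and Wald
interval coverage ~0.87–0.95 for a 9-point design.

Non-convergence returns the best grid value with `converged = FALSE` rather
than an error.

# The synthetic-data generators

Every generator takes a mandatory seed, uses a private RNG stream (the
caller's `.Random.seed` is restored), and returns ground truth beside the
data. What they emulate, and what they do not:

* `simulate_counts()` — NB counts with log-normal clone baselines (the
  titer-matched mixing of real libraries does not give uniform barcode
  abundances; default meanlog log(300), sdlog 0.8 puts clone means across
  roughly an order of magnitude at realistic sequencing depth), log-uniform
  per-sample depth factors in [0.7, 1.4], group fold changes applied to
  test samples, invariant clones pinned at FC 1. Not emulated: phage
  amplification kinetics, PCR chimeras, barcode cross-talk. Passing tests
  therefore demonstrate statistical correctness of the readout under the NB
  model, not robustness to amplification artifacts.
* `simulate_fastq()` — 75-cycle forward reads with both flanked SDB regions
  after a 0–5 nt pad, uniform random bases elsewhere, iid substitution
  errors; mates are reverse complements. Not emulated: quality-score
  structure, indels, adapter read-through.
* `simulate_spectrum()` — Gaussian peaks (areas ∝ fraction, suppressed for
  sialylated species), sequential-loss ghost satellites (a parent loses its
  j-th sialic acid with probability `ghost_fraction` per level, conserving
  total area), linear baseline drift, additive Gaussian noise. Not
  emulated: isotopic fine structure, multiply-charged ions, detector
  saturation.
* `simulate_titration()` — inverts the isotherm to R = f/(1−f) and applies
  log-normal multiplicative noise; saturated points (f = 1) are clipped
  with a warning.

# Numerical choices and degenerate inputs

* Exact-test tail: outcomes with probability ≤ p(observed)·(1+1e-9) are
  summed; the epsilon guards against floating-point ties at the mode. A
  grand total of 0 gives p = 1.
* Dispersion optimization: `optimize()` on [0, 5]; the boundary value 0 is
  compared explicitly so Poisson data return exactly 0.
* Adjusted counts are rounded to integers before conditioning (documented
  above); size factors are always rescaled to geometric mean 1 so "factor"
  has a fixed meaning across methods.
* Peak fitting tie-breaks: flank search is leftmost-first; overlapping fit
  windows are merged transitively in mass order.
* `fraction_bound` clamps tiny negative/overshoot values from floating
  point into [0, 1].
* Degenerate inputs are contracts, not crashes: empty dictionaries validate
  vacuously; empty FASTQ files count as zero reads; all-zero peak areas,
  all-identical ANOVA groups, and non-convergent Kd fits are flagged
  explicitly.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 200 simulated screens of 40 clones × 6 samples for FDR
calibration, exhaustive exact-test oracles to totals of 50, 200
Monte-Carlo titrations, and spectra of a few thousand points — a few
minutes end to end on one core. These sizes were chosen to make the
Monte-Carlo error of each calibration quantity small relative to its
acceptance margin.

# Known limitations

* The exact test treats size factors and dispersion as known; their
  estimation error makes the realized FDR sit at the nominal level rather
  than strictly below it (the same is true of the standard edgeR readout).
* Fraction-to-density conversion assumes modified and unmodified pVIII
  ionize equally; this linearity is an assumption of the measurement, not
  something the package can verify.
* The in-source ghost model and ionization suppression are simplified
  single-parameter descriptions, adequate for testing the correction logic
  but not instrument-calibrated.
* Barcode geometry (flank sequences, which mate carries the regions) is
  configurable because real amplicon designs vary; the defaults are the
  simulator's synthetic design, not a published primer set.
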