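---
title: "Methods: pulse-15N turnover quantification and ubiquitylome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse-15N turnover quantification and ubiquitylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseN15)
```

# The measurement model

In a pulse-¹⁵N design, animals are raised on fully ¹⁵N-labeled food and
switched to a ¹⁴N diet at chase start $t_0$ (day 5 here). Proteins made
before the switch populate a heavy pool; synthesis after the switch is
light. For each peptide, the paired heavy/light extracted ion chromatograms
(XICs) at age $t$ carry the protein's surviving old fraction:

$$ \text{¹⁵N\%} \;=\; \frac{H}{H + L} \;\approx\; f_{old}(t)\cdot\pi, $$

where $\pi$ is the heavy-channel label purity. The package models old-pool
decay as first order, $f_{old}(t) = e^{-k (t - t_0)}$, the minimal kinetic
model consistent with a single proportional readout per age; nothing
downstream depends on this choice except the synthetic generator's truth
tables, since the classification rules operate on observed proportions, not
on fitted rates.

## Ratio estimation

A clean co-eluting isotopologue pair has proportional scan intensities, so
the H/L ratio is estimated as the least-squares slope through the origin of
heavy on light across scans,

$$ \hat r = \frac{\sum_s H_s L_s}{\sum_s L_s^2},\qquad
   \text{¹⁵N\%} = \frac{\hat r}{1+\hat r}, $$

with the squared Pearson correlation of the two traces as the fit quality
(anti-correlated traces are clamped to $r^2 = 0$: they cannot be a
co-eluting pair). Pairs under the threshold (default $r^2 < 0.5$) are
rejected; a plain area-ratio estimator is available as a fallback. An
all-zero light trace maps to proportion 1.0 rather than an infinite ratio,
keeping all downstream arithmetic inside $[0,1]$. The slope estimator and
the r² filter are this package's own design; the fit threshold is exposed
because reasonable pipelines differ on how aggressively to filter.

Peptide proportions aggregate to proteins by the **median** (robust to a
single aberrant peptide; the mean is not exposed). Evidence rules: a
protein is reported only with ≥ 2 quantified peptides in total-proteome
mode, ≥ 1 in ubiquitylome mode. By default the day-60 proportion is **not**
renormalized to the day-5 baseline: at chase start the observed proportion
is $\approx \pi \approx 0.995$, a ≤ 0.5 % bias that is far below the
classification margins; renormalization can be done by the caller by
dividing trajectories by their day-5 column.

# Turnover classification

* **LLP** (long-lived protein): day-60 ¹⁵N% ≥ 0.10, *inclusive* at the
  boundary. The rule is monotone in the threshold.
* **ELLP** (extremely long-lived): proteins hard-assigned to the
  slowest-turnover fuzzy c-means cluster (the one whose center has maximal
  day-60 ¹⁵N%) *and* individually retaining > 0.70 at day 60 (strict).

Summary percentages use half-up rounding to one decimal, matching how such
tables are conventionally printed (base R's `round()` would round half to
even).

## Fuzzy c-means

Trajectories (rows = proteins, columns = ages, values in $[0,1]$) are
clustered with standard fuzzy c-means: memberships
$u_{ij} = 1/\sum_k (d_{ij}/d_{ik})^{2/(m-1)}$, centers as
$u^m$-weighted means, objective $J = \sum_{ij} u_{ij}^m d_{ij}^2$
non-increasing by construction. Implementation choices:

* fuzzifier $m = 2$, default $c = 4$ clusters — $c$ is deliberately a
  parameter, and recovery tests against the generator use $c = 3$, the
  generative class count, because that is the meaningful
  recovery comparison; with $c$ larger than the number of true classes the
  slow class can split, which probes granularity rather than recovery;
* random membership initialization from a seeded RNG, 5 restarts keeping
  the lowest final objective, so a given seed is bit-reproducible;
* hard assignment is argmax membership with ties to the lowest cluster
  index; a point coincident with a center receives full membership there;
* no z-scoring: all dimensions already share the $[0,1]$ scale, and scaling
  would inflate the (nearly constant) day-5 column's noise.

The suite cross-checks this implementation against `e1071::cmeans` (same
optimum up to label permutation and the reference's objective scaling) and
against a k-means oracle on well-separated data.

# Ubiquitylome statistics

DiGly (K-GG, +114.04293 Da) PSMs define the ubiquitylome subset. Channel
proportions are pure PSM counts — no floating point beyond the final
percentage. The old-protein ubiquitylation bias is tested per protein:
among proteins quantified in both the total proteome and the ubiquitylome,
the fraction with higher ubiquitylome ¹⁵N% is reported together with a
two-sided Mann–Whitney–Wilcoxon rank-sum p (normal approximation with tie
correction). Because it is genuinely ambiguous whether such comparisons
should treat the matched sets as paired, the paired signed-rank p is
emitted alongside; the unpaired rank-sum is primary.

Site bookkeeping maps a peptide-level modification position to protein
coordinates as `start + pos − 1` (1-based inclusive throughout, so
"lysine 118" means what it says). Site records are deduplicated on
(protein, position); histogram bins are *exactly one site*, *more than
one*, and *more than ten* (a sub-bin of *more than one*). A diGly on a
peptide's C-terminal residue is chemically implausible — trypsin does not
cleave after a modified lysine — and is flagged for audit but never
silently dropped.

# Chemistry layer

Monoisotopic residue masses are derived at full precision from elemental
compositions (IUPAC/CODATA isotope masses) rather than stored as rounded
per-residue constants: with 5-decimal residue masses the monkey H2A peptide
m/z lands on 838.5107, one ten-thousandth off the correct 838.5108.
Proton mass is 1.007276 Da; I and L are distinct residue codes of identical
mass. Modifications carry a monoisotopic shift and, where registered
(diGly = C₄H₆N₂O₂, carbamidomethyl = C₂H₃NO, oxidation = O), an elemental
formula so they participate in isotope envelopes; shift-only modifications
affect masses but not compositions.

Isotope envelopes convolve per-element isotope distributions across all
atoms, with the nitrogen channel at an arbitrary ¹⁵N abundance (natural
0.003642 reproduces the unlabeled envelope; the default heavy-channel
enrichment elsewhere in the package is 0.995). Isotopologues are aggregated
by their integer nominal-mass shift — summed integer shifts are associative,
so pre-aggregated element distributions convolve exactly and no fine
structure is resolved; within a nominal peak the reported mass is the
abundance-weighted mean. Envelopes truncate at cumulative abundance 0.999
and renormalize. The tests verify them at 1e-9 against a brute-force
polynomial-expansion oracle on small molecules. Note the textbook caveat:
the monoisotopic peak is only the most abundant one up to roughly 90
carbons; beyond that M+1 overtakes it.

For PRM targets the diGly site must be given explicitly: the precursor m/z
is invariant to which lysine carries the remnant, but y-ion identities
shift by 114.04293 Da when the modified lysine falls inside the fragment,
so guessing would silently corrupt the target table. The shipped examples
place it on the first lysine of the C-terminal KK motif. Fragment charge is
fixed at 1+ for y3–y7, the typical state for short y ions; quantification
is the plain sum of the five fragment intensities with no normalization,
which presumes equal total protein input per sample — a documented pipeline
precondition, not a default the code can check. Group comparison uses an
equal-variance Student t by default (Welch by flag).

# The synthetic generator

The generator emulates a three-tissue pulse-chase design — ages 5/30/60 d,
chase start day 5 — with everything seeded and ground truth
retained:

* **turnover-class mixture**: three log-normal rate classes
  (`extreme`: median $k = 0.0025$/d, `slow`: 0.02/d, `fast`: 0.10/d,
  log-sd 0.25–0.35), chosen once so that over the 55-day chase the extreme
  class retains > 0.7, the slow class 0.15–0.5 and the fast class < 0.05 of
  its heavy pool — i.e. the classes respect the LLP/ELLP decision
  boundaries with realistic margins rather than straddling them. Tissue
  presets set the weights so the LLP share lands near the observed values
  (head 55 %, muscle 79 %, testis 31 %).
* **label purity** 0.995, applied as a per-molecule misassignment
  probability (a heavy-pool molecule observed light with probability
  $1-\pi$) and as the heavy-share factor of XIC pairs.
* **noise**: independent multiplicative log-normal noise (log-sd 0.1) per
  scan per channel on a shared Gaussian elution profile of ≥ 7 scans.
* **PSM depth**: Poisson with mean proportional to protein abundance
  (log-normal across proteins), so aggregate channel shares converge to
  abundance-weighted mean old fractions.
* **ubiquitylation bias**: a diGly PSM on a protein with (purity-adjusted)
  old fraction $f$ is heavy with probability
  $\beta f / (\beta f + 1 - f)$; $\beta = 1$ is unbiased, and the default
  $\beta = 3.72$ is the odds multiplier that turns an old fraction of 0.28
  into a heavy share of 0.59 — the magnitude of bias the analysis is
  designed to detect. The degenerate case $f = 1, \beta = 0$ is defined
  as probability 0.
* **RNG**: one seeded stream consumed in a fixed iteration order. A
  per-protein sub-stream scheme would only matter under parallel
  generation, which the generator does not do; the single stream gives the
  same reproducibility contract (same seed ⇒ byte-identical fixtures) with
  less machinery.

What the generator does **not** emulate: retention-time drift, chimeric or
mis-identified spectra, decoy/FDR structure, peptide-specific ionization
efficiency, missing channels, or non-exponential (e.g. biphasic) turnover.
Passing recovery tests therefore demonstrates the correctness of the
estimation and classification chain under the stated noise model — not
robustness to identification errors or chromatographic pathology in real
data.

# Numerical and I/O choices

* Envelope pruning threshold 1e-15 per convolution; peaks below it are
  dropped before renormalization.
* FCM convergence: maximum center shift < 1e-6, cap 200 iterations;
  squared distances floored at 0 to absorb negative round-off.
* Tables are tab-separated UTF-8 with '.' decimals and a mandatory header;
  `#` lines are provenance comments (package version, a 32-bit FNV-1a hash
  of the analysis parameters — I/O paths excluded so reruns into another
  directory stay byte-identical — and the seed). Writes go to a temp file
  renamed into place, so failures never leave partial outputs.
* Channel labels normalize case-insensitively (`15n`, `n15` → `15N`);
  malformed rows abort with line numbers unless explicitly skipped.

# Problem sizes used in the tests

Recovery tests run at 500 proteins × ~4 peptides × 3 ages (≈ 6,000 XIC
pairs) with the default noise model, a size at which class-recovery
statistics are stable while the full suite stays interactive; Monte-Carlo
calibration checks use 500–1,000 replicates. These sizes are the package's
testing choices and can be scaled up freely through `generator_config()`.

# Known limitations

* Protein inference is taken as given (PSMs arrive with protein ids); no
  parsimony or razor-peptide logic.
* The regression estimator assumes the pair is already correctly extracted;
  there is no peak detection, deisotoping, or interference modeling.
* ELLP identification depends on the cluster count: with many clusters the
  slow class can split and the floor rule then governs which fragment wins.
* The rank-sum comparison treats proteins as independent; shared peptides
  between proteins would violate that silently.
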