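---
title: "Differential pull-down interactomics with pseudocounted NSAF and a hyperbolic volcano threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential pull-down interactomics with pseudocounted NSAF and a hyperbolic volcano threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsafvolcano)
```

## The problem

Affinity pull-down followed by LC-MS/MS (AP-MS) recovers the proteins bound
to an immobilized bait. Comparing two bait states — here a phosphorylated
bait ("P") against a mock-treated control ("NP"), each in three biological
replicates — asks which prey proteins *prefer* one state. The raw evidence
per protein and run is its spectral count (SpC), the number of MS/MS spectra
assigned to its peptides: a noisy, discrete, depth-dependent proxy for
abundance, with frequent zeros. This package implements the label-free
quantitative route from a protein-identification table to a classified list
of differential interactors.

## Model and procedure

**Identification filters.** Before any statistics, the table is reduced to
confidently identified, non-redundant proteins: at least two matched
peptides (`min_total_peptides = 2`), at least one unique peptide, and
collapse of cross-species duplicates that arise when spectra are searched
against a merged two-species library. The search engine's 1% FDR is an
upstream property of the input table and is not recomputed here. The
deduplication key is the gene symbol (case-insensitive): it is the only
cross-species identifier available in an identification table. Within a
duplicate group the record with the highest summed spectral count is kept;
exact ties go to the lexicographically smallest accession so the rule is
deterministic. Records without a gene symbol are never grouped.

**Normalization.** For protein $k$ with length $L_k$ amino acids in sample
$s$:

$$\mathrm{NSAF}_{k,s} =
  \frac{(\mathrm{SpC}_{k,s} + 1)/L_k}
       {\sum_i (\mathrm{SpC}_{i,s} + 1)/L_i}.$$

The $1/L_k$ factor corrects the length bias of spectral counting (longer
proteins yield more peptides), the per-sample denominator corrects for
run-to-run differences in sampling depth, and the +1 pseudocount keeps a
protein that was not observed in a run at a finite positive abundance, so
ratios between conditions are always defined. By default the denominator
runs over the **union** of all filtered proteins, imputing SpC = 0 where a
protein was not observed; this makes the values comparable across samples
and gives exact column sums of 1 (asserted to 1e-9 in the tests). The
alternative reading — normalizing over only the proteins detected in that
sample — is selectable with `normalization = "detected"` and documented as
such; under it, every protein still receives a value but column sums exceed
1 by the pseudocount mass of the undetected proteins. Values are kept in
full double precision; nothing is rounded before statistics.

**Statistics.** Mean NSAF is taken over the replicates of each condition,
and each protein is tested with Welch's two-tailed unequal-variance
$t$-test on the *untransformed* replicate NSAF values — the test follows
normalization directly, with no log transform and no moderated-variance
shrinkage. The volcano coordinates are

$$a = \log_2 \frac{\overline{\mathrm{NSAF}}_P}{\overline{\mathrm{NSAF}}_{NP}},
\qquad b = -10 \log_{10}(p).$$

The log base of $b$ is 10 by convention for volcano significance axes (and
is configurable via `log_base`); on that scale the default significance
asymptote $m = 5$ corresponds to $p \approx 0.316$ — deliberately
permissive, because calling is controlled jointly with the fold-change
requirement, not by the significance axis alone. No multiple-testing
correction is applied: the calling procedure controls false positives
through the threshold curve below, not through an FDR adjustment, and the
reported $p$ values should be read in that light.

**Classification.** The significance boundary is the hyperbola

$$f(x) = \frac{1}{x^2 - n} + m, \qquad n = 1.35,\; m = 5,$$

defined only outside the fold-change gate ($x^2 > n$, i.e.
$|a| > \sqrt{n} \approx 1.162$). A protein is a P-side interactor iff
$a > \sqrt{n}$ **and** $b > f(a)$; an NP-side interactor iff
$a < -\sqrt{n}$ **and** $b > f(a)$; otherwise non-significant. All
inequalities are strict, exactly as the criteria are stated: boundary
points, including the vertical asymptotes where $f$ is undefined, are
non-significant. Near the gate the curve diverges (only overwhelming
significance rescues a marginal fold change); far from it the requirement
relaxes toward $b > m$. Raising either $n$ or $m$ can only remove calls,
never add them — a monotonicity the tests assert. The curve's interior
($|a| \le \sqrt{n}$) is reported as `NA` by `threshold_curve()`; points
there fail the gate regardless of $b$.

```{r curve, fig.width = 5, fig.height = 3.5}
x <- seq(1.25, 5, length.out = 300)
plot(x, threshold_curve(x), type = "l", ylim = c(5, 12),
     xlab = "a (log2 ratio)", ylab = "f(a)")
abline(v = sqrt(1.35), lty = 2); abline(h = 5, lty = 3)
```

## Numerical choices

* `a` is computed as $\log_2 \overline{\mathrm{NSAF}}_P -
  \log_2 \overline{\mathrm{NSAF}}_{NP}$. This is mathematically the log
  ratio, and makes the P/NP label-swap symmetry *exact* in floating point:
  negating a difference is exact, whereas `log2(x/y)` and `-log2(y/x)` can
  differ in the last bit.
* $p$ values are clamped below at `p_floor` (default 1e-300) before
  computing $b$, so $b$ is always finite; clamped rows carry a
  `p_floored` flag.
* Zero-variance degenerate groups are resolved rather than rejected: equal
  means give $t = 0, p = 1$; unequal means with both variances zero give
  $p = $ `p_floor` with the flag set. With a pseudocount and per-sample
  depths this case is rare but possible.
* Welch's statistic and the Welch–Satterthwaite degrees of freedom are
  computed from the standard formulas, with `stats::pt()` supplying the
  $t$ CDF; the test suite checks them against `stats::t.test()` and
  against an independent numerical-integration oracle to 1e-10 relative
  error.
* The drawn threshold-curve branches are sampled from the point where
  $f$ meets the plot's y ceiling out to the axis maximum — a purely
  cosmetic clip of the divergence at the gate.

## The synthetic experiment

`simulate_pulldown()` generates identification tables with the structure
the analysis assumes, with known ground truth. Defaults describe the study
conditions exercised throughout the tests and the analysis scripts:

| parameter | default | meaning |
|---|---|---|
| `n_background` | 500 | non-differential proteins |
| `n_spiked_P`, `n_spiked_NP` | 15, 15 | true interactors per side |
| `fold_change` | 8 | true enrichment of spikes |
| `replicates_per_condition` | 3 | biological replicates |
| `depth_mean`, `depth_cv` | 3000, 0.15 | log-normal total counts/sample |
| `abundance_sigma` | 1.5 | log-normal spread of protein abundance |
| `length_range` | 80–2000 aa | log-uniform protein lengths |
| `length_exponent` | 0.7 | count yield scales as $L^{0.7}$ |
| `count_dispersion` | 0.2 | NB overdispersion ($\phi$; 0 = Poisson) |
| `spike_quantile` | 0.75 | spikes drawn from the upper abundance quartile |

Counts are negative-binomial around `depth × share`, where a protein's
share is proportional to abundance × fold change × $L^{0.7}$, renormalized
within each condition. The sub-linear length exponent means expected counts
grow with length while NSAF's $1/L$ correction still matters — a simulator
with counts exactly proportional to $L$ would make the correction
untestable. Spikes sit in the upper abundance quartile so that triplicate
power is high but not trivial, mimicking the clear positive-control
separation the assay is validated against. Dispersion is configurable down
to Poisson for closed-form checks.

What the simulator does **not** emulate: peptide-level identification
errors, shared/razor peptide ambiguity, co-complex correlation between
preys, batch structure beyond per-sample depth, and the fact that real
identification lists only contain proteins observed in at least one run.
Passing tests therefore demonstrate correctness and calibration of the
computation under the stated count model, not performance guarantees on
any particular instrument's output.

## Calibration and its limits

Under a null simulation (no spiked proteins) the pipeline is well
controlled: at the default study conditions fewer than 5% of proteins are
called significant on either side, and the package's calibration study
(`analysis/03_evaluate.R`) reports ~2%.

Uniformity of the null $p$ values deserves honesty. A protein with zero
counts in *every* sample has NSAF values $(1/L_k) \cdot (1/d_s)$ with
$d_s$ the per-sample denominator; the protein-specific factor $1/L_k$
cancels from the $t$ statistic, so **all** never-observed proteins share
one identical $p$ value. At very shallow per-protein coverage (e.g. 2,000
proteins at 3,000 expected counts per sample, ~1.5 counts/protein) roughly
a fifth of simulated proteins are never observed, and this point mass
alone forces a Kolmogorov–Smirnov distance from uniform of at least half
its mass, regardless of implementation or seed (measured: 0.23). The
uniformity property test therefore runs the null at the per-protein
coverage of real identification lists (2,000 proteins, 30,000 expected
counts per sample, ~15 counts/protein — real lists only report proteins
that were actually observed), where the KS distance is 0.03–0.06 across
seeds, comfortably within the 0.1 tolerance that reflects the remaining
count discreteness and the small replicate number. The shallow-coverage
KS figure is still computed and reported by the calibration script so the
behaviour is visible, not hidden.

Problem sizes used throughout (chosen as the package's study conditions):
the default 530-protein experiment for end-to-end runs and the 20-seed
power study; 2,000 proteins for the null calibration; 1,000 random
instances for the Welch oracle; 10,000 random points for the
classification oracle.

## Known limitations

* Three replicates give the $t$-test little power and unstable variance
  estimates; the hyperbolic threshold compensates by demanding large fold
  changes near the significance floor, but moderated-variance approaches
  (e.g. empirical-Bayes shrinkage) are deliberately out of scope.
* The test is applied to untransformed NSAF values, whose distribution is
  right-skewed; calibration is approximate, as quantified above.
* Reported $p$ values are per-protein and uncorrected; only the
  curve-gated calls are designed to be interpreted.
* Cross-species deduplication by gene symbol can, in principle, collapse
  genuine distinct proteins that share a symbol, and cannot merge records
  whose symbols are missing.
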