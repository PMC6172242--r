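---
title: "Designing antisense probe panels and quantifying in vivo RNA accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing antisense probe panels and quantifying in vivo RNA accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asaccess)
```

## The problem

Bacterial small RNAs (sRNAs) regulate mRNAs through short, imperfect base
pairing. Which stretches of an sRNA are actually available for such pairing
inside a living cell is poorly predicted by folding algorithms alone, because
the intracellular milieu (chaperones such as Hfq, ongoing transcription and
translation, competing partners) reshapes the accessible surface.
A transcription anti-termination reporter assay measures this directly: each
candidate region gets an antisense RNA (asRNA) probe embedded in a reporter
transcript; when the probe hybridizes its target in vivo, ribosome stalling
on a tnaC leader occludes a Rho utilization (rut) site and transcription
reads through, so hybridization shows up as *longer* reporter transcripts in
RNA-seq. `asaccess` implements the computational side of that assay
end-to-end: probe panel design, read processing, accessibility
quantification, chaperone-dependency classification, and the use of
accessibility maps to filter computational sRNA:mRNA target predictions.

## Probe scoring: the biophysical hybridization model

A candidate region $[i, j]$ on a target RNA is scored by

$$\nu = \bar\theta \,(\Delta G_{tf} - \Delta G_{asT}) + \Delta G_{asF}$$

* $\bar\theta$ — the *pseudo-frequency factor*: the sum over the region of
  each nucleotide's equilibrium unpaired probability, computed from the
  partition function of the target. It rewards regions that are already
  single-stranded in the ensemble. Range: 0 to region length.
* $\Delta G_{tf}$ (kcal/mol, $\ge 0$) — the cost of opening the target
  region, defined here as the constrained-vs-unconstrained ensemble
  free-energy difference $-RT\,\ln(Z_{\text{open}}/Z)$, where
  $Z_{\text{open}}$ sums only structures that leave the whole region
  unpaired. (The assay's original description delegates folding to an
  external program and never writes this formula; the constrained-ensemble
  definition is the standard thermodynamic reading.)
* $\Delta G_{asT}$ ($\le 0$) — the probe:target duplex energy. Probes are
  exact reverse complements, so this is a sum of pair energies.
* $\Delta G_{asF}$ ($\le 0$) — the probe's own folding (MFE); self-structured
  probes are penalized.

### The energy model and its engine

`energy_model()` scores a nested (pseudoknot-free) structure as the sum of
its base-pair energies: GC $-3$, AU $-2$, GU $-1$ kcal/mol, minimum hairpin
loop 3 nt, $RT = 0.616$ kcal/mol (37 °C). There are no stacking or loop
terms. This is deliberate: the per-pair model keeps the entire structure
space exactly enumerable, so every quantity the package reports
(partition function, pair probabilities, opening energies, MFE) can be
verified against the brute-force oracle `enumerate_structures()` — which the
test suite does, to $10^{-9}$ relative, on hundreds of random sequences.
Absolute $\nu$ values are therefore model-dependent by construction; only
their ranking within an RNA is used downstream, and a nearest-neighbor
engine can be substituted behind the same interface.

`fold_ensemble()` runs McCaskill-style inside/outside recursions
($O(n^3)$ inside; the outside pass iterates enclosing pairs directly, which
is worst-case $O(n^4)$ but fast at sRNA lengths of 50–400 nt). Recursions
are computed with a per-base scaling factor
$\sigma = \exp(-E_{\min}/(4RT))$ so the scaled partition function stays
$O(1)$; this keeps plain doubles exact up to ~500 nt, and the engine
refuses longer inputs rather than silently losing precision.

## Panel selection: knowledge gradient + weighted set cover

Scoring every window of length 9–16 gives thousands of candidates per RNA;
probing all of them is not feasible. Panel selection maximizes
$\sum_k v_k x_k - \lambda \sum_k x_k$ subject to the selected intervals
covering $[1, L]$ — a weighted set cover, solved greedily: at each step
pick the candidate minimizing $\alpha_k = (\lambda - v_k)/|[i_k,j_k]
\setminus C|$, the penalty-minus-value per newly covered nucleotide.

* $v_k$ is the *knowledge-gradient* value of measuring region $k$: the
  expected improvement of the posterior maximum from one noisy measurement,
  under independent normal beliefs
  ($\tilde\sigma_k = \sigma^2_k/\sqrt{\sigma^2_k + \sigma^2_\epsilon}$,
  $\zeta_k = -|\mu_k - \max_{j \ne k}\mu_j|/\tilde\sigma_k$,
  $v_k = \tilde\sigma_k(\zeta_k\Phi(\zeta_k) + \phi(\zeta_k))$).
  The original assay used a sparse-linear-belief variant whose covariance
  update was never published; the independent-normal closed form used here
  is the standard ranking-and-selection form, is cross-checked against a
  Monte-Carlo estimate in the tests, and accepts user-supplied $v_k$
  vectors so the set-cover step is unchanged if a different belief model is
  preferred. Belief means default to min-max-normalized $\nu$ with unit
  prior and noise variance.
* $\lambda$ (default 1.0) trades off panel size against value; large
  $\lambda$ degenerates to plain coverage minimization.
* Ties in $\arg\min \alpha_k$ break to the smallest start index, then the
  shortest region (the published algorithm is silent on ties; this rule is
  deterministic and reproducible). Fully covered candidates leave the pool
  (their denominator would be zero).

Two baselines support benchmarking: *exploration* tiles seeded random
12-mers until covered; *exploitation* runs the same greedy cover on
normalized $\nu$ directly. `experimental_effort()` scores a selection by the
gap between the best true accessibility and the best selected one, rescaled
to $[0,1]$ across algorithms.

## From reads to accessibility

`build_reference_library()` concatenates, per probe: leader, asRNA probe,
RSE, RBS, elongation switch, reporter. Read filtering follows the assay's
rules exactly: the 5' read must match the TSS-anchored reference prefix,
overlap the probe segment by **at least 7 nt** (inclusive), and match a
unique reference (multi-mapped reads are discarded); the mate is then
exact-matched within the same reference to fix the transcript end.
Transcript length is end − TSS + 1. Every input pair is accounted for in
the run log (assigned plus each discard class sums to the total). The
built-in matcher is exact by design — synthetic reads are error-free — and
externally aligned BED6 input goes through the same filtering contract with
0-based half-open coordinates converted at the boundary.

Accessibility is computed per probe from the length histogram:

1. weighted-average transcript length, $\sum \ell\,c_\ell / \sum c_\ell$;
2. baseline adjustment (floored at 0) — 85 nt in overexpression mode and
   164 nt in native mode, the published constants, both derived as the
   minimum observed reporter transcript size; `baseline = "auto"` applies
   that *rule* (minimum observed length in the run) and should be used
   whenever the scaffold geometry differs from the published one, as it
   does for the synthetic scaffold bundled here;
3. min-max normalization within each sRNA × replicate ("raw"
   accessibility);
4. replicate mean, a second within-sRNA min-max normalization
   ("reported"), and standard errors propagated through that second
   normalization treating its min and max as constants (a linear-map
   approximation).

Because of the min-max steps, reported accessibility is invariant to
uniform shifts of all transcript lengths within an sRNA, and the baseline
only matters through its floor. Values are comparable within an sRNA, not
across sRNAs. Negative adjusted lengths are floored at 0; degenerate groups
(single region, or zero range) report 0.5 with a warning rather than NaN.

## Hfq dependency and functional regions

Strain comparisons use a paired two-tailed t-test per region on the
normalized accessibility replicates (dof $= n - 1$, typically 2). An sRNA
is *Hfq-dependent* when any region has $p < 0.05$ — strictly below, so a
region at exactly 0.05 does not count. No multiple-testing correction is
applied, matching the assay's reporting; a Benjamini-Hochberg flag can be
layered on by the caller via `p.adjust`. Extreme-accessibility enrichment
between region groups uses the N−1 χ² test (Pearson χ² scaled by
$(N-1)/N$) with strict extremeness thresholds, 0.125/0.875 by default and
0.25/0.75 as the preset for functional-region calling.

Likely functional regions are called from a profile as regions that (i)
start or end within the 5' or 3' end window (20 % of the sRNA length each)
and (ii) have reported accessibility $> 0.75$ or $< 0.25$; up to three are
returned, ranked by distance from 0.5 with ties to the 5'-most. When the 3'
window is empty the 5' window extends to 40 %. When the windows cluster
mid-scale (no extreme candidate at all), the YUNR tie-break selects the
5'-most extreme region of the 5' half containing a significant
pyrimidine–U–N–purine motif. The motif p-value is computed by exact
enumeration (a random 4-mer matches with probability 1/16 under a uniform
background — FIMO's machinery is overkill at motif length 4). Note that
1/16 = 0.0625 can never clear the 0.05 significance bar under a uniform
background; the tie-break therefore scans against the sequence's own
composition (FIMO's 0-order background), under which a perfect match in an
AU-rich sRNA is rarer than 1/16 and the 0.05 threshold is attainable. This
choice is a documented interpretation, not a claim about the original
pipeline's internals.

Predicted sRNA:mRNA interactions (IntaRNA-style tables, read through header
aliases) are kept when their sRNA interval overlaps a functional region by
at least 5 nt (inclusive). Tested candidates partition into
informed / top-ranked / both, with PPV counting weak binders as positive —
the counting convention of the published benchmark, whose printed table is
bundled (`load_validated_targets()`) and reproduced by `tally_validation()`:
13 confirmed targets, 6 informed-only, 1 top-ranked-only, 6 shared, maximum
confirmed rank 76/100.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions: termination landmarks at 80,
140 and 200 nt (premature termination within the elongation switch, at its
end, and full-length read-through), Gaussian length jitter with sd 3 nt,
read-through weight equal to the true accessibility $a$ with the remaining
mass split 0.7 : 0.3 between the two termination peaks (the published
traces show the early peak dominating; the exact split is not quantified,
so 0.7 is a fixed choice here), $10^4$ reads per probe, 3 replicates, and
replicate noise of sd 0.02 on the accessibility scale. True accessibilities
are Beta(2, 2) draws. Planted Hfq effects shift a region's accessibility by
±0.4 in the mutant strain.

Under these conditions the full pipeline — simulate, emit paired 75 × 2
reads, re-process, quantify — recovers the truth with Spearman ≥ 0.99 over
50 probes, and planted ±0.4 effects are detected with essentially complete
sensitivity at $p < 0.05$. The generator does **not** emulate sequencing
errors (an optional uniform substitution rate exists purely to document
that the exact matcher is not error-tolerant), quality scores, adapter
contamination, transcript-abundance differences between probes, or
position-dependent Rho efficiency. Passing tests therefore demonstrate the
correctness of the estimator chain, not robustness to real-library noise —
real data should enter through the BED pathway after external alignment.

## Numerical and design choices

* Coordinates are 1-based closed everywhere internally and in TSV/CSV
  output; BED I/O stays 0-based half-open.
* T is normalized to U on input; FASTQ output is written as DNA.
* The per-base scaling factor in the folding recursions bounds sequences at
  500 nt; beyond that the engine errors instead of degrading.
* Problem sizes in the test suite (50 probes × $10^4$ reads × 3 replicates
  for the end-to-end check; 200 random sequences ≤ 15 nt against the
  enumeration oracle; 1000 random set-cover instances ≤ 12 candidates) were
  chosen so the whole suite runs in about a minute while still exercising
  each contract at its specified scale.
* Degenerate statistical cases are defined, not errors: zero-variance
  paired differences give $t = 0, p = 1$ (zero mean) or $p = 0$ flagged
  degenerate (nonzero mean); empty χ² margins return NA with a warning.

## Limitations

* The energy model omits stacking, loop entropies and temperature
  dependence beyond $RT$; $\nu$ rankings are meaningful, absolute values
  are not calibrated.
* The knowledge-gradient values assume independent beliefs across regions;
  overlapping windows are clearly correlated, so the value-of-information
  ranking is an approximation (the set-cover constraint is what enforces
  spatial coverage).
* Accessibility is relative within an sRNA; cross-sRNA comparisons of raw
  values are not supported by the normalization.
* The built-in matcher requires error-free reads; real libraries should be
  aligned externally and imported as BED.
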