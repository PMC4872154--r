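---
title: "Models and methods behind smflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smflow simulates and analyses single-molecule targeted flow sequencing: an
amplification-free platform in which 70-nt single-stranded DNA targets
hybridize to surface-anchored capture probes, a polymerase adds exactly one
dye-labelled reversible terminator per cycle under the fixed flow order
G, C, T, A, and a two-channel TIRF microscope records one anchor image (the
Cy3 label on each template) and one incorporation image (the terminator
dye) per cycle. This vignette documents the generative models, the
estimators, and the numerical decisions — in particular every place where
the underlying method left a genuine design choice open.

## The reference panel

`make_references()` draws, for each of `n_templates` (default 8), a random
70-nt wild-type template, a mutant version carrying one variant, and a
60-nt capture probe (50 specific bases plus a dT10 surface linker). The
default variant panel mirrors a cancer drug-response panel: six point
mutations and two short deletions of 15 and 21 nt — five- and seven-codon
exon-19-style deletions. The residue spans pin down the deletion lengths
only up to the reading frame, so both lengths are configurable.

**Probe geometry.** The probe's 3′ end primes synthesis, so the sequenced
region is the template portion 5′ of the probe's footprint, read out as its
reverse complement ("read space"). The probe anchors the template's 3′-most
25 nt; its remaining 25 specific bases complement simulated gene context
beyond the synthetic 70-mer, exactly as probes designed against a gene
overhang a shorter synthetic insert. This leaves a 45-nt read-space
reference per template — long enough that a 21-nt deletion plus flanks is
spanned by reads. Had the probe consumed a full 50 nt of the template, only
20 nt would remain readable and the longer deletion could never be
observed; variant positions default to 2–6 read bases from the primer, so
every variant is reached within the platform's ~10-bp reads.

Templates are drawn with no two consecutive identical bases over the first
12 read-space positions. Under a 4-base flow order a repeated base costs a
full extra flow cycle, so this constraint reflects probe designs that avoid
early homopolymer stalls and keeps read lengths near the platform's
characteristic ~10 bp at the default 25 cycles.

`check_probe()` applies the design rules: GC fraction within 20–80% and
melting temperature above 65 °C. The method names only the constraint, not
a formula; the basic GC-content estimate
$T_m = 64.9 + 41\,(\#GC - 16.4)/L$ is used and documented here.

## The incorporation and error model

At each cycle, a molecule whose next due base equals the flowed base
incorporates it correctly with probability $1 - p_{sub} - p_{del}$, records
a wrong base with probability $p_{sub}$, or misses the incorporation with
probability $p_{del}$; a missed base is skipped permanently, producing a
clean deletion in the read (no re-incorporation mechanism is modelled). At
non-matching cycles a spurious signal — an insertion recording the flowed
base — occurs with probability $p_{ins}$.

Defaults: $p_{sub} = 0.0052$ per incorporated base (the platform's printed
substitution rate), $p_{del} = 0.040$ and $p_{ins} = 0.005$, chosen so
deletions dominate the error budget and total raw error sits near 5%,
consistent with ~95% single-coverage consensus accuracy. All three are
configuration keys. One consequence of the bookkeeping deserves note: the
5% total counts insertions, but insertions never occupy a reference
position in a pileup, so the per-position error visible to a
depth-1 consensus is $p_{sub} + p_{del} \approx 4.5\%$ before alignment
end-effects; measured depth-1 accuracy therefore lands at 95–96% rather
than exactly 95%.

**The coverage cliff.** Because waiting times between incorporations are a
deterministic function of the template sequence and flow order, every
error-free read of a given template ends at the same reference position
when the cycle budget runs out. Positions past that cliff are reached
*only* by deletion-carrying reads (skipping a base shortens the remaining
wait). This is a real feature of fixed-budget flow sequencing, and it
drives two estimator choices below.

## Imaging model

`render_cycle_stack()` renders each site as an isotropic 2-D Gaussian of
sigma 1.0 px — approximately diffraction-limited for far-red emission at
the 54.6 µm / 512 px scale — with peak amplitude proportional to site
occupancy; pixel values are Poisson shot noise on signal plus background,
plus Gaussian read noise. Electron-multiplying gain excess noise is not
modelled (no camera statistics are available to calibrate it). Stage drift
is a per-cycle rigid translation, cumulative across cycles; rotation is not
modelled. The four exposures per field are collapsed into one averaged
frame per channel. `render_bleach_movie()` bleaches each fluorophore at an
independent geometric time, so a site with occupancy $k$ shows $k$ downward
steps unless two fluorophores bleach in the same frame — an irreducible
misclassification mode that is accepted and quantified rather than hidden.

Site occupancy defaults (38% single, 36% pairs, 26% clusters of three or
more) reproduce the composition observed on the physical instrument; the
simulator treats them as the generative ground truth that the
photobleaching classifier must recover.

## Image processing

* **Drift correction** uses phase-only correlation: the peak of the inverse
  transform of the unit-normalised cross-power spectrum. It is exact for
  circular integer shifts; estimated shifts are applied as integer
  translations (vacated pixels take the image median), with optional
  quadratic sub-pixel refinement of the estimate.
* **Spot detection** thresholds the Gaussian-smoothed image at the median
  plus `threshold_k` (default 5) times the robust noise scale
  (1.4826 × MAD). The method description says only "a threshold determined
  by a noise measurement"; thresholding on the *smoothed* image is this
  package's stated interpretation. When the image is essentially
  noise-free (MAD vanishing relative to the signal excursion) the threshold
  falls back to a fixed fraction of the peak excursion so that spots remain
  compact components. Components use 8-connectivity; candidates are fitted
  with a single isotropic 2-D Gaussian plus constant background
  (Levenberg–Marquardt least squares).
* **Cluster filtering** rejects fits with sigma above 1.8× the expected
  point-spread sigma or component areas above a configurable maximum —
  an operationalisation of "filter out clusters of three or more
  molecules", which the method states as intent without a criterion.
  Unresolved pairs are deliberately localized as single spots.
* **Coincidence calling** matches each incorporation-channel spot to the
  nearest anchor within 1.6 px (the track radius doubles as the
  colocalization radius, which the method leaves unstated); each anchor
  accepts at most one spot per cycle, ties break to the lower spot index.

## Base calling

Tracks are anchored at template-channel positions rather than chained
spot-to-spot: the anchor image exists precisely to mark template positions,
which resolves the ambiguity in "centroids falling within a 1.6 pixel
radius in subsequent images". Anchors closer than twice the radius could
capture each other's events, so both are flagged ambiguous and excluded.
Decoding maps event cycles through the flow order:
`base = flow_order[(cycle - 1) mod 4 + 1]`; cycle indices are 1-based
everywhere. On noise-free, drift-free fields restricted to isolated
single-occupancy sites, the image path reproduces the read-level
simulator's reads exactly — the suite asserts string equality.

## Photobleaching classification

`count_steps()` segments a trace into piecewise-constant levels by binary
change-point search with penalty $10\,\hat\sigma^2 \log n$
($\hat\sigma$ = MAD of first differences / $\sqrt2$), counts downward level
changes larger than $3\hat\sigma$, and labels one step "single", two or
more "aggregated". "Irregular" curves — any significant upward step,
residual noise above 2.5× the frame-noise estimate, or more than five
steps — are unclassified; no quantitative irregularity criterion exists in
the method, so these thresholds are stated decisions, all exposed as
arguments. Composition recovery is validated on sparse fields where
distinct sites are optically resolvable, isolating the classifier from
spatial overlap; at instrument densities overlap itself contributes to the
aggregated class.

## Alignment, QC, consensus, error rates

`smith_waterman()` implements local alignment with linear scores
+2 match / −2 substitution / −1 deletion / −1 insertion. Under this scoring
a substitution (−2) ties a deletion-plus-insertion pair (−1 −1); among
score-optimal paths the traceback prefers the one with the most diagonal
columns, then diagonal > read-gap > reference-gap per cell, and the first
best cell in read order. Without the path-level rule a genuine substitution
is occasionally reported as a spurious gap pair, which visibly depresses
the measured substitution rate. The score itself is unaffected, and the
suite verifies it exactly against an independent dynamic program, an
exhaustive substring-enumeration oracle, and `Biostrings::pairwiseAlignment`.

Read QC applies three sequential rules: length ≥ 5; exact-string
multiplicity ≥ 4 (counted globally across the run, after the length rule);
and an alignability floor — best score below 2 × 5 (a perfect 5-mer)
against every reference marks a read unalignable. Each read is then
assigned to its single best-scoring template; cross-template ties are
dropped as ambiguous origin.

**Consensus.** Per-position tallies over {A, C, G, T, deletion} feed a
majority vote; ties break toward the reference base (then a fixed symbol
order), which biases identity slightly upward and is switchable to strict
lexicographic. Insertions do not enter position tallies. Identity is scored
over the *well-covered zone* — positions with at least half the maximum
coverage — with the literal all-covered-positions value also reported.
The restriction exists because of the coverage cliff: positions past it are
covered exclusively by deletion-class reads, carry no usable consensus
evidence at any simulation scale, and at full instrument scale every
reported position is deeply mapped anyway.

**Error rates.** The per-position error rate is the fraction of covering
reads disagreeing with the reference, and overall rates are means of
per-position rates. Two estimator refinements make the profile unbiased for
the generative parameters: (1) *edge masking* — the first and last two
reference-consuming columns of each alignment are excluded from rate
estimation, because a local alignment keeps a terminal error only when
enough matches follow it, so read-end columns systematically under-report
errors; (2) the overall means run over the well-covered zone (at least half
the maximum masked coverage), because past the cliff a handful of stray
alignments would otherwise dominate the position mean with coverage-1
noise. Insertion events are tallied per read and reported per aligned base,
separately, since they are invisible in the pileup.

**Accuracy versus depth.** `subsample_accuracy()` performs
sampling-subsampling: for each target depth it draws read subsets whose own
mean coverage equals that depth, recomputes the consensus, and scores
accuracy over position-replicate instances whose *realized* coverage equals
the target. Conditioning on realized per-position coverage is essential
here: reads all start at the capture probe, so a subsample's coverage
profile is front-loaded and a nominal mean depth mixes very different
per-position depths. Majority voting with reference-preferring ties is
slightly parity-dependent (a 1–1 split at depth 2 falls back to the
reference), so the monotonicity of accuracy in depth is asserted along odd
depths.

## Low-frequency mutation detection

Each QC-passing read is aligned to the wild-type and mutant references of
its best template; wild type iff the wild score is strictly higher,
otherwise mutant. The literal "otherwise" sends ties to mutant — including
reads that never reach the variant site — which makes the estimated mutant
frequency an upper bound on the true fraction. That upward bias is a
documented property of the procedure, not corrected (a span filter
requiring the alignment to cover the variant locus is available but off by
default, matching the literal rule; a `tie = "drop"` policy is also
provided). Open points resolved here: mixing ratios are treated as
molecule-count ratios (97:3 → mutant fraction 0.03, 10:1 → 1/11); the
~2×10⁵ "effective reads" are taken as the total per group; batches for the
two-sample Student t-test (equal variances; Welch by flag) are fields of
view, the natural replicate unit of an imaging run.

## Problem sizes and validation scope

The test suite and the acceptance script run the pipeline at reduced but
faithful scale, chosen as the smallest sizes at which the statistical
claims are well-resolved: ~1500 reads per template for full-depth consensus
(instrument runs average ~1954-fold coverage; the conclusions are
scale-free once coverage is deep), 2×10⁵ reads per group in 300 batches
for the mixture scan (the instrument's operating point), ≥10⁵ aligned bases
for error-rate recovery, and six 27-µm fields for photobleaching
composition. Determinism is guaranteed per seed throughout; every
stochastic assertion is made at explicitly computed binomial or
Monte-Carlo tolerances.

What the simulator does *not* emulate — and what passing tests therefore do
not certify about real data: sequence-dependent hybridization efficiency
(observed as uneven template coverage on the instrument), secondary
structure, camera gain statistics, fluorophore blinking, rotational drift,
chromatic offsets between channels, and any base-quality information (the
platform emits none). Error rates are homogeneous per molecule; real
instruments show position- and sequence-dependent structure.
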