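---
title: "Models and methods behind dualcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualcut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcut)
```

## The experimental system

`dualcut` models transient dual-gRNA CRISPR/Cas9 experiments in plant
protoplasts: a single construct delivers Cas9 together with a *fixed*
(internal-reference) gRNA and a *variable* gRNA cutting the same chromosome at
a configurable distance. When both double-strand breaks (DSBs) occur on the
same chromatid, the intervening segment can be re-ligated in place (perfectly
or with small indels at the junctions), re-inserted in inverted orientation
(a chromosomal inversion), or lost (a large deletion). Three measurement
processes read this out:

* **crystal digital PCR (cdPCR)** — the sample is partitioned into ~0.59 nL
  droplets; two TaqMan probes target the two borders of the inversion
  junction, so a droplet fluorescing above threshold in *both* channels is
  scored as containing one inversion-junction genome;
* **short amplicon sequencing** — reads over each cut site quantify indel
  frequencies, i.e. per-site cutting efficiency;
* **long amplicon sequencing** — full-interval reads confirm complete
  inversions and reveal large deletions.

The package implements both the generative side (a simulator of all three
data types with known ground truth) and the estimation side (one quantifier
per data type plus the reference-gRNA normalisation that puts samples with
different transfection efficiencies on a shared scale).

## The generative outcome model

Each allele (2 per cell by default — tomato is diploid) is processed
independently:

1. with probability `p_transfect` the allele's cell received the construct;
   untransfected alleles stay wild type;
2. conditional on delivery, each site is cut independently
   (`p_cut_fixed`, `p_cut_var`);
3. alleles cut at **both** sites draw an outcome: inversion (`p_inv`),
   deletion (`p_del`), perfect re-ligation (`p_perfect`), or re-ligation with
   indels at one or both junctions (the remainder);
4. alleles cut at a **single** site repair either perfectly or with an indel
   (`p_indel`, default 0.9 — after 48 h of exposure most repaired cuts carry
   a scar, and a perfectly repaired site is indistinguishable from wild
   type).

Allele independence is the simplest model consistent with per-genome
frequencies; it ignores within-cell correlation of cutting (shared Cas9
dosage), which would widen replicate-to-replicate spread but not shift any
expectation the estimators target. The key structural property — inversions
and deletions require *both* gRNAs active, so their expected frequency is
`p_transfect * p_cut_fixed * p_cut_var * p_inv` (resp. `p_del`) — holds by
construction and is what makes the internal-reference normalisation work:
every edited-class frequency is proportional to the sample's delivery
efficiency.

Indel sizes default to point masses at −3/−6/−9 bp (the deletion classes
recurrently seen in Sanger traces at such junctions) plus a geometric tail of
insertions up to +80 bp. Rearrangement junctions receive 0–80 bp of random
inserted sequence (mass 0.6 on a clean junction). Both distributions are
plain named vectors and fully user-configurable; we cap the default junction
insert at 80 bp because that is the insert range the flank-matching junction
scan tolerates — larger inserts (a 193 bp insertion class has been observed
at such repair sites) can be configured but are then, correctly, not
recovered by flank matching.

## Droplet panels and cdPCR quantification

Loaded genome copies are computed from DNA mass as

copies = mass(g) × N_A / (genome size (bp) × mean bp weight (Da)),

with tomato defaults 1.179 × 10⁹ bp and 659.928 Da; 1 ng ≈ 774 genomes.

The simulator partitions the (integer) copies **multinomially** over the
loaded volume: each copy lands in droplet *j* with probability
v_droplet / V_loaded. At the usual volume fractions this is indistinguishable
from independent Poisson occupancy per droplet, but it is the exact physical
model and makes degenerate configurations behave correctly (one droplet
covering the whole loaded volume captures every copy with certainty).
Junction-carrier copies are drawn binomially from the truth's carrier
fraction; droplets holding ≥1 carrier emit Gaussian high signal in both
channels, all others background. A configurable droplet fraction is flagged
volume-invalid, mimicking the reader's droplet-matrix QC.

The estimator mirrors the standard workflow: volume-invalid droplets are
excluded outright (even if bright); the *analysed fraction* is
`n_valid × 0.59 nL / 25 µL`; analysed genomes = loaded copies × analysed
fraction; the inversion frequency is double positives / analysed genomes.
Samples with fewer than 18,000 valid partitions fail QC (the frequency is
still computed for diagnostics). Two estimator modes exist:

* **direct counting** (default) — divides the double-positive count as is.
  Unbiased when junction copies rarely co-occupy a droplet.
* **Poisson-corrected** — replaces the count with
  `−ln(1 − p̂) × n_valid`, the maximum-likelihood event count under Poisson
  occupancy. At a realistic operating point (5 × 10⁵ copies in 25 µL →
  ~12 genomes per droplet; carrier fraction ~1% → junction occupancy
  λ ≈ 0.13) direct counting underestimates the frequency by ~6%, and the
  corrected mode removes that bias. Our parameter-recovery runs therefore use
  the corrected mode; the default stays direct to mirror the standard
  division.

## Windowed indel quantification

Reads are globally aligned to their reference amplicon (Needleman–Wunsch
with affine gaps via `Biostrings::pairwiseAlignment`; match +2, mismatch −2,
gap open −6, gap extend −1). A read is *mutated* iff it carries ≥1 insertion
or deletion whose reference span intersects the closed interval
`[cut − 4, cut + 1 + 4]`: the two nucleotides flanking the blunt cut
(between protospacer positions 17/18, 3 bp 5′ of the PAM) extended by a 4 bp
buffer. Substitutions never count — they are dominated by sequencing error.
The window rule is monotone by construction: growing the buffer can only add
qualifying reads.

Negative-control subtraction works on *event classes* (type, reference
position, signed size): a class whose pooled control frequency reaches 50%
(configurable) of its sample frequency is treated as background and removed
before the mutated-read fraction is recomputed; the result is clamped to
[0, 1]. This is a deliberately explicit surrogate for the shifted-frequency
normalisation some amplicon pipelines apply internally; we chose the
event-class filter because its behaviour is fully specified and testable.
Identical reads are aligned once and weighted by multiplicity, which keeps
the quantifier fast at high coverage, and alignment determinism makes event
keys reproducible between sample and control.

## Junction classification of long reads

For each DSB the scan targets two 16 bp flanks spaced 60 bp apart
outer-edge to outer-edge, with the cut centred in the 28 bp between them.
Five queries are built from the reference: the two wild-type junctions, the
two inversion junctions (outer flank joined to the reverse complement of the
interval-side flank at each border), and the single fused deletion junction.
A read matches a query when the left flank is followed by the right flank
separated by 0 to (28 + `max_insert`) arbitrary bases: deletions at the cut
of up to 28 bp shrink the gap without touching the flanks, and an insertion
of exactly `max_insert` (default 80 bp) is still matched while 81 bp is not.
Both the read and its reverse complement are scanned, because long-read
orientation is random — without this, frequencies would halve.

Label precedence is fixed: `complete_inversion` (both inversion junctions) >
`inversion` (one junction) > `deletion` > `wild_type` (both wild-type
junctions) > `other`; reads matching inversion *and* deletion queries are
chimeric and labelled `other`. Unique events are deduplicated by the exact
inter-flank sequence per junction, so two reads with the same junction
insert count as one event. Flank matching is exact; with per-base error *e*
the chance an inversion read keeps both 16 bp flanks of one junction intact
is (1 − e)³², which for HiFi-like error rates (≤10⁻³) stays above 0.97 —
the zero-error oracle-equivalence tests plus this bound describe the
caller's recall envelope.

## Reference-gRNA normalisation

The normalisation factor of sample *s* is
mean(fixed-site frequency over all non-control samples) / fixed frequency of
*s*, applied multiplicatively to the variable-site and inversion
frequencies. Algebraic consequences (all tested exactly):

* **fixpoint** — every normalised fixed-site frequency equals the raw mean;
* **ratio preservation** — within-sample ratios are untouched;
* **scale invariance** — per-sample multiplicative perturbations c_s
  (transfection variation) cancel exactly whenever they preserve the mean
  fixed frequency, and up to one overall rescaling otherwise;
* **variance reduction** — across replicates with heterogeneous
  transfection efficiency the CV of normalised variable-site frequencies
  cannot exceed the raw CV in expectation; we assert it across ≥20 simulated
  replicates.

The mean is taken per replicate (equal weighting) over non-control samples,
across constructs. Samples whose fixed-site frequency is 0 (inactive
reference) are non-normalisable: excluded from the mean and flagged, never
silently dropped. Normalised values above 1 are reported unclamped with a
warning — the scale is relative. `experiment_report()` assembles the
standard panels: frequency vs interval size, frequency vs variable-site
efficiency with the reference mean marked as the saturation threshold (above
it the fixed site becomes limiting), the deletion:inversion ratio, and
droplet-count vs long-read concordance as per-construct ratios and absolute
differences (paired comparison; no regression fit is implied by the design).

## Numerical choices and problem sizes

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; identical seeds give byte-identical outputs. Alignment gap
placement at ties follows the aligner's deterministic convention, so event
coordinates are reproducible run to run. The sequencing error model is
per-base substitutions plus rare 1 bp indels — no homopolymer or quality
model — which suffices to exercise an exact-flank caller and a windowed
aligner; it understates error clustering in real instruments, so recall
estimates on simulated data are upper bounds for real long reads.

The shipped tests and the acceptance script size their simulations for
statistical resolution rather than realism of throughput: droplet-recovery
runs use ~25,500 droplets × 5 × 10⁵ copies × 10 seeds (Monte-Carlo standard
error ≈ 0.01 percentage points at a 1% frequency), long-read recovery uses
10 × 50,000 reads at a 0.41% inversion channel (~2,000 expected events),
and property checks run at thousands of alleles. The synthetic generator
emulates the statistical structure of the real assays — proportional
delivery effects, dual-channel droplet counting, junction insert spectra —
but not organellar DNA contamination, spectral spillover between dyes,
primer-efficiency differences, or chimeric PCR artefacts; passing tests
demonstrate estimator correctness under the stated model, not freedom from
those real-data biases.

## Known limitations

* cdPCR thresholds are fixed numbers; interactive thresholding and
  spillover-compensation matrices of instrument software are out of scope
  (the simulator emits spectrally clean channels).
* The junction caller detects no duplications or translocations and does no
  alignment-based SV calling; amplicon long reads above a configurable
  interval ceiling (default 5 kb) are refused rather than approximated.
* Whether rearranged alleles amplify in the indel assay is exposed as the
  `rearrangement_dropout` switch (default: they drop out, and the mutation
  frequency is computed over amplifiable alleles) rather than asserted.
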