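---
title: "Measuring RNA polymerase and reverse transcriptase fidelity from rolling-circle concatemers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring RNA polymerase and reverse transcriptase fidelity from rolling-circle concatemers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollseq)
```

## The measurement problem

When an RNA molecule is reverse-transcribed and sequenced, every
observed mismatch against the DNA template is the sum of three error
sources: the RNA polymerase that made the transcript, the reverse
transcriptase (RT) that copied it into cDNA, and the sequencing
process. A linear protocol cannot tell these apart — every error looks
the same in the final read.

Rolling-circle reverse transcription of a *circular* RNA template
breaks the degeneracy. An RT with strand-displacement activity travels
around the circle several times, producing one long cDNA composed of
tandem full-length copies of the template (concatemers). An error that
the RNA polymerase made is part of the RNA molecule itself, so it
reappears at the same template position in *every* concatemer of that
read. An error the RT made during one pass is private to a *single*
concatemer. High-accuracy single-molecule consensus reads (pass count
and read-quality metadata per read) make individual base calls reliable
enough that this support pattern can be read off directly.

This package implements the computational side of that design:

1. **Segmentation** (`segment_read()`): locate full template copies in
   each long read, in either orientation, with the rotation offset at
   which each copy begins on the circle.
2. **Filtering** (`filter_read()`): at least 15 passes, read quality
   1.0, between 3 and 10 concatemers, every copy fully mapping within a
   length tolerance and below a divergence cap.
3. **Variant calling** (`align_segment()`, `call_variants()`):
   end-to-end affine-gap alignment of every copy against the rotated
   template; substitution columns become single calls and adjacent gap
   columns one indel event, left-normalized to canonical coordinates.
4. **Attribution** (`attribute_variants()`): calls with identical keys
   (type, position, ref, alt) are grouped within a read; support equal
   to the concatemer count means RNA polymerase, support of exactly one
   means RT, anything in between is `AMBIGUOUS` and excluded from both
   numerators.
5. **Rates** (`compute_rates()` and friends): counts over denominators,
   substitution spectra, transition/transversion classes, positional
   and homopolymer profiles.

`roll_seq()` runs stages 1–5 and returns a classed fit with `print`,
`summary`, `coef`, `plot` and `simulate` methods. A companion module
measures second-strand synthesis fidelity by aligning strand-specific
consensus pairs (`compare_strands()`), and a seeded simulator
(`simulate_run()`) generates reads with planted, labelled errors so
every stage can be tested against ground truth.

## The attribution model and its denominators

The origin rule is deliberately discrete. For a read with $k$
concatemers and a grouped variant supported by $s$ of them:

$$\text{origin} = \begin{cases}
\text{RNAP} & s = k\\
\text{RT} & s = 1\\
\text{AMBIGUOUS} & 1 < s < k
\end{cases}$$

With at least three concatemers per read the two hypotheses are well
separated: an RT error cannot mimic a polymerase error without the same
mistake recurring independently at the same position in every other
copy (probability of order $r^{k-1}$ at per-base error rate $r$).
Intermediate support arises only from coincident RT errors, collisions
with polymerase errors, or segmentation artifacts; classifying it
`AMBIGUOUS` and reporting it separately keeps both rate estimates
conservative. The paper-style rule defines only the two clean cases;
the `AMBIGUOUS` class is this package's explicit handling of the rest.

Denominators differ by origin, and this is what makes the estimator
unbiased under the generative model:

* **RT**: every aligned concatemer base was synthesised once by the RT,
  so the denominator is (number of segments) × (template length).
* **RNA polymerase**: each eligible read represents exactly one RNA
  molecule, observed $k$ times. An RNAP error is a property of the
  molecule, counted once, so the denominator is (number of eligible
  reads) × (template length).

Uncertainty is the binomial standard error $\sqrt{p(1-p)/n}$ by
default; when replicate labels are supplied, the standard error of the
mean across replicates is reported instead (matching how benchmark
tables report ±).

Residual sequencing noise is single-concatemer by construction and
therefore lands in the RT bucket. Rates are reported uncorrected by
default — at the Q40 consensus accuracy this method operates at, noise
(≈1e-4/base) is well below typical RT substitution rates but not always
negligible; passing `noise_rate` to `roll_seq()` adds a
`rate_noise_corrected` column (rate − noise for RT substitutions and
totals), clearly flagged as a model-based correction.

## Substitution frames

All calls are made in the sense frame of the template. The reporting
frame depends on the enzyme:

* The RNA polymerase synthesises the transcript, so its misincorporated
  nucleotide is the sense-frame alternative base, reported as a
  ribonucleotide (U for T). Spectra carry `frame = "RNA"`.
* The RT synthesises the cDNA (the complement of the sense strand), so
  its misincorporated dNMP is the *complement* of the sense-frame
  alternative. Spectra carry `frame = "DNA"` and report template bases
  in DNA letters.

`classify_mutation()` applies the same logic to
transition/transversion classes: transitions are frame-invariant
(`A<->G`, `C<->T/U`), while transversions are subdivided by the
physical template:incorporated pair the enzyme formed (purine–purine
versus pyrimidine-involving), using the RT's own template strand (the
sense RNA) or the RNA polymerase's (the antisense DNA) as appropriate.

Spectrum fractions are fractions of *error events*, not
composition-normalised per-base rates; `composition_normalized = TRUE`
adds the per-base variant. Indel rates are per *event* by default (a
length-2 deletion counts once); `per_base = TRUE` in
`tabulate_variants()` switches to per-base accounting, since published
pipelines do not always state which convention they use.

## What the simulator states about the world

`simulate_run()` is first-class, tested code, and its defaults are the
measurement regime the method was designed for:

| parameter | default | why |
|---|---|---|
| template length | ~1 kb, user-supplied | the concatemer window below assumes it |
| concatemer count | uniform on 3..10 | the eligibility window; the true distribution of a real run is instrument-dependent and unpublished, so uniform is a neutral stand-in |
| start offset | fixed at template position 0 | primer-defined start; `"uniform"` available to stress segmentation |
| sequencing noise | 1e-4 substitutions/base | the Q40-or-better consensus accuracy regime (80%–95% of eligible reads) |
| passes / read quality | 20 / 1.0 | above the ≥15 / 1.0 filters; configurable to emit failing reads for filter tests |
| error model rates | 0 unless set; presets from `reported_error_rates()` | benchmark values for T7, Induro, L1-RT and FBu |
| indel length | 1 base | indel length spectra are not quantified in the benchmarks; longer events sit behind `indel_length` |

Reads are emitted in cDNA orientation (reverse complement of the RNA)
because the sequenced strand is the cDNA; segmentation must therefore
recover orientation, and does.

Every planted error carries a truth record (origin, type, template
position, ref, alt, concatemer index). When two planted errors land on
the same or adjacent positions of the same synthesis product, or the
same error recurs across concatemers, the records are flagged
`collision`: such sites admit equal-scoring alternative alignment
representations or break the support rule, so no caller can attribute
them identifiably. Accuracy accounting excludes them.

What the simulator deliberately does **not** model: raw subread/ZMW
physics and quality-by-pass curves (a scalar noise rate stands in),
chimeric or adapter artifacts, RT template switching, multi-base indel
spectra, and any dependence of error rate on sequence context beyond
what the planted positions imply. A green recovery test therefore
establishes that the pipeline inverts *this* generative model — reads
composed of full tandem copies with independent per-base errors — not
that it is robust to every artifact of real instrument data.

## Numerical and algorithmic choices

**Alignment.** Global affine-gap alignment (Gotoh) with scores
match 1, mismatch −2, gap open −4, gap extend −1 (a length-$k$ gap
scores $-4 - (k-1)$). The published analysis does not state scoring;
these defaults are chosen so a substitution (−2) is strictly preferred
over an adjacent insertion-plus-deletion (−8), which the caller relies
on, and `align_params()` rejects parameter sets violating that
ordering. The implementation is in C++ with a deterministic traceback;
tests verify optimality against an independently coded gap-function
dynamic program and, exhaustively on small binary templates, that
emitted calls reconstruct the read at the optimal score.

**Left-normalization.** Tie-breaking among equal-scoring alignments is
not delegated to the aligner's traceback (which is
implementation-defined) but enforced afterwards: every indel is shifted
to its 5′-most equivalent placement, so the same physical slippage
event receives identical coordinates in every concatemer — essential
for the support rule inside homopolymer tracts. Two refinements matter:
a shift is an equivalence only across match columns, so shifting stops
at any position occupied by another call of the same alignment; and the
template is circular, so an insertion whose equivalent placements reach
5′ of base 1 is labelled at position $L$ (its circular 5′ neighbour).
Deletions never cross the linear origin, and a homopolymer run split by
a read's rotation point can normalize differently in differently
rotated reads — a known, rare limitation.

**Segmentation.** In place of an external long-read mapper, copies are
located by seed-and-extend against the doubled template on both
strands: 24-mer probes vote for orientation and rotation phase (each
vote scored by exact prefix identity over a small drift neighbourhood,
because probes downstream of an indel drift by the cumulative indel
count), then an exact 20-mer anchor at the copy start tiles the read.
Anchors match by content, so indel drift does not accumulate; anchors
corrupted by an error are recovered by template-length interpolation
plus an edit-distance snap, and a leading chunk of approximately one
template length is recognised as a full first copy. Partial copies at
the ends are excluded; reads with substantial probe support on both
strands are rejected as `mixed_orientation` chimeras. Boundary
placement is still ambiguous by ±1 base when an indel falls within one
anchor length of a copy junction; such events (≈ 2 × 20/L of indels)
can surface as equivalent alternative call pairs at positions 1 and
$L$, which the collision flagging and acceptance tolerances account
for.

**"Fully mapped"** is operationalised as segment length within ±2% of
the template length and per-segment alignment divergence ≤5% (both in
`filter_policy()`); the published description gives no numeric
tolerance. The "highest mapping quality" filter of the original
pipeline maps onto the divergence cap; no separate mapping quality is
computed.

**Coordinates.** All user-facing positions are 1-based inclusive;
`rotation_offset` is 0-based in `[0, L)`, matching the rotation
semantics of `rotate_template()`. Insertions are anchored at the
template base immediately 5′ of the inserted bases.

## Second-strand synthesis

`simulate_strand_pairs()` and `compare_strands()` implement the
strand-versus-strand comparison: the second strand is copied from the
cDNA, so errors made during cDNA synthesis appear on both strands and
are invisible (concordant), while second-strand errors appear as
discordances. Every discordance is charged to second-strand synthesis —
the same single-direction assumption the published analysis makes
implicitly; a two-sided Poisson decomposition is out of scope. Pair
eligibility mirrors the published filters: ≥15 passes, read quality
1.0, length within 10 bp of the expected reference (inclusive), and
the expected sequences at both ends (default: the first and last 8
reference bases, each strand checked in its own orientation; the
published description names no motif length). No end masking of
discordances is applied. Substitutions are recorded as cDNA template
base → incorporated second-strand base (complement of the aligned
base), and indels are left-normalized on the cDNA frame.

## Worked check

A small end-to-end run with planted rates and zero noise:

```{r recovery}
tpl <- make_template(1000, homopolymer_spec = data.frame(
  base = c("A", "T"), length = c(6, 5), count = c(2, 1)), seed = 7)
cfg <- sim_config(tpl,
                  rnap_model = preset_error_model("T7"),
                  rt_model = preset_error_model("Induro", "cDNA"),
                  n_molecules = 200, sequencing_noise_rate = 0,
                  seed = 42)
sim <- simulate_run(cfg)
fit <- roll_seq(sim$reads, tpl)
fit
```

The injected T7 rates (38, 2, 13 per 1e6 for substitution, deletion,
insertion) and Induro rates (57, 6, 49 per 1e6) should be recovered
within a few binomial standard errors; the package's acceptance suite
performs this check at 5,000 molecules together with
attribution-accuracy verification against the truth table.

## Known limitations

* Rates are estimated on a single ~1 kb template; template-sequence
  effects (structured RNA raises both transcription and RT error
  rates) mean the numbers are template-specific.
* The AMBIGUOUS class absorbs all intermediate-support variants; no
  probabilistic deconvolution of coincident errors is attempted.
* Homopolymer runs spanning a read's rotation point, and indels within
  one anchor length of a copy junction, can receive alternative (but
  alignment-equivalent) coordinates.
* The simulator's independence assumptions (per-base, per-copy) are the
  null model of the method, not a model of instrument artifacts.
* Replicate-based standard errors require user-supplied replicate
  labels; the default binomial errors understate variability if reads
  are not exchangeable.
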