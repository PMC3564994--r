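---
title: "Calling differential transcript ends from coverage topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential transcript ends from coverage topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endscan)
```

# The problem

Strand-specific RNA-seq measures, at every base, how often that base was
transcribed. When the same gene is profiled in a reference condition
(e.g. rich-medium exponential growth) and a stress condition, the two
coverage landscapes should agree over the ORF up to a global expression
change — but may disagree sharply at the transcript boundaries, where a
condition-specific transcription start site or cleavage site lengthens or
shortens the UTR. `endscan` detects these *differential ends* from the
coverage topology alone, then annotates them: upstream ORFs (uORFs) gained
or lost in 5′ ends, and RNA-binding-protein (RBP) motifs in either end,
each scored for enrichment against a sampling null.

# The end-calling model

For one gene, let $r_i$ and $c_i$ be raw per-base coverage on the gene's
strand over an analysis window (ORF extended by `flank_max` on both
sides, clipped at the chromosome and at the nearest same-strand
neighbour's ORF so a neighbour's signal is never attributed to the gene).
Both are transformed as $\log_2(v + 1)$ and the condition track is
shifted so the two ORF medians coincide; the shift removes a global
expression-level difference, which is not an end phenomenon. Writing
$d_i$ for the per-base difference (condition minus reference):

* **Noise.** Over the annotated ORF the two medians agree by
  construction, so $d_i$ there is noise. Its population standard
  deviation is the gene's noise level $n$. Using the gene's own ORF means
  highly expressed, stable genes get tight thresholds and noisy genes get
  conservative ones.
* **Threshold.** A base qualifies when both a 10-bp and an 80-bp centred
  sliding-window mean of $d$ exceed $T = \max(3.5\,n,\ 2.0)$ (in log2
  units; 2.0 is a fourfold floor), with sign giving the direction:
  positive means the condition transcript is *longer* there, negative
  *shorter*. Requiring both windows is a conjunction: the 10-bp window
  pins boundaries, the 80-bp window suppresses isolated noise spikes.
  Windows are truncated (not dropped) at window edges.
* **Scan.** Qualifying bases are grouped into maximal uniform-sign runs;
  runs of at least `min_end_length` (40 bp) are candidates. Candidates
  are considered nearest-the-ORF-boundary first — the called end is the
  one that changes the gene's UTR content — scanning the upstream flank
  for the 5′ side and the downstream flank for the 3′ side, and
  continuing up to `inset_max` (300 bp) into the ORF so that a
  truncation that removes the annotated start or stop codon is still
  seen. Such a run sets `start_codon_lost` / `stop_codon_lost` when it
  covers the codon.
* **Filters.** A candidate run is rejected when the higher condition's
  mean raw coverage over it is below `min_region_expression` (5, echoing
  the expressed-gene threshold), when it lies wholly inside an annotated
  intron (an intron retention difference is not an end), or when mean
  mappability over it is below 94.

At most one 5′ and one 3′ call is made per gene per condition.

Two properties follow from the construction and are enforced by tests:
swapping the two conditions maps every call to the opposite direction
over the same interval (antisymmetry), and raising `noise_multiplier` or
`min_fold_log2` never creates calls (threshold monotonicity).

## A known self-limitation

$n$ is computed over the *full* annotated ORF, including any truncated
span. A shorter end that invades the ORF therefore inflates its own
threshold: for a truncated ORF fraction $f$ the inflation is roughly
$|d_0|\sqrt{f(1-f)}$, which exceeds $|d_0|/3.5$ — making the call
impossible — once $f \gtrsim 0.09$. Deep truncations are thus
systematically conservative; shallow codon-loss truncations (a few
percent of the ORF) remain callable. We keep this behaviour because it is
the stated method; the alternative (excluding the qualifying region from
$n$) would be circular.

# Mapping and mappability

The mapper demands a unique exact match over both strands. A read that
fails is trimmed by 4 bp from the 3′ end and retried, down to 28 bp
(76, 72, …, 28: thirteen attempts for a 76-mer). A multimapping attempt
*continues* the cascade rather than aborting — the goal is to maximize
recovered information, and a longer read can be ambiguous where a shorter
prefix is unique only in degenerate cases. `N` never matches.

Mappability simulates one 76-mer and one 28-mer starting at every base on
each strand and adds 1 over the span of every read that occurs exactly
once genome-wide, *at its own length, without trimming* — the only
reading under which an interior base of unique sequence scores exactly
76 + 28 = 104. Under exact matching a read and its reverse complement
have equal genome-wide occurrence counts, so the plus and minus tracks
coincide; reads crossing a chromosome end are not simulated, so terminal
bases score lower (base 0 scores 2). A gene is mappable when its ORF mean
is at least 94, the smallest integer satisfying the 90%-of-104 rule.

# Poly(A) end tags

A read ending in a poly(A) tail fails to map at full length. Tag calling
strips the maximal trailing A-run (at least 3 required), re-maps the
remainder, and — if the anchor is at least 28 bp, unique, and the genomic
continuation does not itself reproduce the A-run — places the cleavage
site at the first post-alignment base, in transcript orientation on
either strand. Only reads unmapped at *full* length are candidates: a
trimming-rescued read has lost its 3′ evidence, and using both routes
would double-count. Tags cluster into sites by single linkage within
10 bp; the multi-site report flags genes with more than 10 tags whose
site representatives lie more than 50 bp apart.

One ambiguity is intrinsic: when the base immediately 5′ of a cleavage
site is itself an A, no tail-stripping method can distinguish it from the
tail, and the recovered site shifts by the length of that genomic A-run.
The synthetic generator therefore nudges planted cleavage sites into
clean context (last transcribed base and first post-cleavage base both
non-A, a walk of under one base on average), so that on clean data
recovery is exact — which is what the tests assert. On real data this
ambiguity is simply part of the method's resolution limit.

# uORFs, motifs, and enrichment

`find_uorfs()` scans the coding strand of a differential 5′ end in all
three frames: every ATG inside the end interval and upstream of the main
start codon is extended to its first in-frame stop, searching into the
main ORF; an ATG with no stop before the ORF 3′ boundary is not reported.
uORFs may overlap the main ORF out of frame — we do not require the stop
to precede the main ATG (a strict mode is available), since out-of-frame
overlapping ORFs are a real regulatory configuration. Minimal uORFs
(start codon immediately followed by stop) are flagged.

Motif matching is plain IUPAC set membership with no scoring: AAACACAW
matches AAACACAA and AAACACAT, never AAACACAG; overlapping matches all
count; `U` in a consensus is normalized to `T` at file-reading time since
matching runs in DNA space; `N` in the *sequence* matches nothing.

Enrichment uses total counts: the observed total over all differential
ends is compared with `n_iter` (default 1000) null totals over
length-matched random segments — drawn from the 1000 bp upstream of
random genes' start codons for uORFs (promoter-like base composition),
and uniformly from the whole genome, either strand, for motifs. The
promoter window is sampled raw, without masking neighbouring features.
Then $z = (\mathrm{obs} - \bar{x}_{null})/s_{null}$, significant at
$z > 3$. The samplers are deterministic per seed and the z-scores are
calibrated: observed values drawn from the null exceed $|z| > 3$ at about
the Gaussian rate.

# The synthetic-data generator

The generator emulates the study design, not the full complexity of real
data:

* i.i.d. genomes at GC 0.38 (yeast-like), with optional exact repeats for
  mappability tests;
* non-overlapping genes with at least 1200 bp of intergenic space, so a
  1000-bp promoter window never reaches a neighbour; ORFs 600–1200 bp,
  rewritten to ATG…stop with no internal in-frame stop, alternating
  strands;
* reference UTRs of 120 bp (5′) and 100 bp (3′) by default;
* per-base counts drawn from Poisson (default) or negative binomial
  (dispersion 0.2 — a convention, not a measured value) around an
  expected landscape: `base_depth` (default 50) over each condition's
  transcript span on the coding strand, a uniform background of 0.5% of
  `base_depth` elsewhere (echoing the observation that most of a compact
  genome is transcribed at low level; set 0 for clean unit tests);
* a planted *longer* end is expressed only in the gaining condition; a
  planted *shorter* end retains `base_depth / fold` residual coverage in
  the losing condition, since alternative end use in a population is a
  mixture, not an on/off switch;
* uORF cassettes (`ATG` + T-free codons + `TAA`, 6–60 nt) are written
  into 5′ UTR regions without overlap; T-free interiors make internal
  stops and starts impossible and the borders are patched so no
  accidental ATG spans them;
* simulated reads are 76-mers from the coding strand; a configurable
  fraction end at the transcript's cleavage site with 3–10 nongenomic
  A's replacing the post-cleavage bases.

What the generator does *not* emulate — sequencing error, quality decay,
spliced reads, antisense transcription, internal priming on genomic
A-rich stretches, replicate structure — bounds what passing tests show:
they demonstrate correctness of the algorithms under the stated model,
not robustness to every artifact of a real library.

# Numerical choices

* Coordinates are 0-based half-open everywhere internally; GFF3
  (1-based inclusive) is converted at the boundary; bedGraph is native.
* log2 uses pseudocount 1, so zero coverage maps to 0.
* Quantile normalization replaces rank $r$ by the across-column mean of
  the $r$-th order statistics; ties receive the mean over their full rank
  range (this differs from interpolation-at-mean-rank for ties spanning
  three or more ranks), which makes the operation idempotent.
* Median normalization and $n$ use the ORF only, not the wider window —
  the ORF is the region where the two conditions are expected to agree.
* Ties among candidate runs at equal boundary distance resolve to the
  first in genome order (stable sort).
* Problem sizes in the test suite (100-kb mappability genomes, 50-gene
  recovery and 200-gene null-calibration simulations, 1000-iteration
  nulls, 1000-case oracle sweeps) were chosen as the smallest scales at
  which the binomial/CLT tolerances used by the tests are meaningful.

# Limitations

* Exact matching stands in for a mismatch-tolerant aligner; counts on
  real, error-containing reads would differ.
* One call per gene per side per condition: genuinely multi-modal end
  landscapes collapse to the call nearest the ORF.
* Deep ORF truncations are under-called by construction (see above).
* Enrichment uses total counts over all ends pooled; per-gene enrichment
  is out of scope.
* The promoter null samples raw windows; in gene-dense genomes those
  windows may include neighbouring ORF sequence.
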