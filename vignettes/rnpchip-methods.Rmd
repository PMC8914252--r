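---
title: "Methods: mapping intron RNP binding sites on circular multi-replicon genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping intron RNP binding sites on circular multi-replicon genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Group II introns are mobile retroelements whose ribonucleoprotein
particles (RNPs: the excised intron RNA bound to its intron-encoded
reverse transcriptase) invade DNA, preferentially the transiently
single-stranded template of lagging-strand synthesis at the replication
fork. ChIP-seq of an epitope-tagged RNP on a bacterial host with a
multipartite genome yields, after alignment, read placements for
eighteen libraries: three plasmid constructs (tagged active RNPs, tagged
protein without the intron RNA, untagged active RNPs as the
immunoprecipitation control) times two fractions (input, IP) times three
replicates. `rnpchip` implements the complete downstream chain: calling
enriched regions against the input background, removing peaks shared
with the control constructs, annotating the survivors by genomic context
and replication-fork orientation, testing whether they cluster around
the replication origins, locating those origins independently from GC
skew, scanning the libraries for occupancy of the intron's natural
insertion site, and comparing input-vs-IP coverage.

All coordinates inside the package are 0-based half-open on circular
replicons. GFF3 (1-based inclusive) is converted exactly once, at the
I/O boundary; BED is used natively. An interval crossing the circular
seam is stored either as two records sharing an id (in files and read
placements) or in "unwrapped" form with `end > L` (in memory); no
negative coordinates ever appear.

# The peak caller

The caller is a deliberately simple member of the family of windowed
Poisson-background ChIP-seq callers. Reads are extended to the
sonication fragment length $d$ (default 300 bp, the midpoint of a
0.2–0.5 kb size selection) from their 5' end in read orientation; no
fragment-shift model is estimated, and no duplicate removal exists
anywhere in the package (the upstream protocol kept duplicates). For
each bin of width $w$ (default 50 bp) the statistic is the number of
extended IP fragments overlapping the bin. Its null mean is estimated
from the pooled input as

$$\lambda_{\mathrm{local}} = r \cdot \max\!\Big(\frac{N\,(w+d)}{g},\;
  \bar c_{1\mathrm{k}}\frac{w+d}{d},\;
  \bar c_{5\mathrm{k}}\frac{w+d}{d},\;
  \bar c_{10\mathrm{k}}\frac{w+d}{d}\Big),$$

where $r$ is the IP/input fragment-count ratio, $N$ the input fragment
count, $g$ the effective genome size (default: total replicon length),
and $\bar c_s$ the mean input coverage in a circular window of span $s$
centered on the bin. The factor $(w+d)/d$ converts per-base coverage to
an expected *overlap count* for a $w$-bin: a fragment of length $d$
overlaps the bin iff its start falls in a window of length $w+d$, so a
per-base coverage $c$ (fragment-start rate $c/d$) implies $c\,(w+d)/d$
expected overlapping fragments. Using $w$ alone would understate the
null mean roughly sevenfold at the defaults and destroy FDR control;
this normalization is stated here because the published description of
this caller family leaves it implicit.

Per-bin upper-tail Poisson p-values are corrected by Benjamini–Hochberg
in a single pass across **all** bins of **all** replicons (mirroring
joint calling of pooled replicates in one execution), bins with
$q \le 10^{-3}$ (FDR < 0.001) are merged when separated by at most
`merge_gap` (100 bp) — circularly, so a peak may span the seam — and
merged peaks shorter than `min_peak_len` (200 bp) are dropped; observed
peak lengths then fall in the few-hundred-bp range. Each peak reports
the summit (position of maximal IP pileup), a fold enrichment (summit
pileup over the scaled local background), and the best bin's p- and
q-values. The caller never reproduces any specific external tool's
numeric output; it implements the stage, with every threshold surfaced
in `peak_caller_config()`.

# Construct subtraction

`subtract_overlapping()` reproduces `bedtools intersect -v` semantics
exactly: an interval of the first set survives iff it shares **zero**
base pairs with every interval of the second set on the same replicon
(half-open abutment is not overlap; one shared bp excludes). Overlap
detection runs on seam-split segments, so wrapping peaks exclude through
either segment. `unique_peaks()` applies the two-step filter — first
subtract the IEP-only construct's peaks, then the untagged construct's —
in that fixed order; the test suite verifies as a property that the
order cannot matter.

# Context and fork-orientation annotation

Each unique peak gets exactly one context category: `CDS` (contained in
one gene), `IR` (no gene overlap), `IR_5CDS` / `IR_3CDS` (intergenic
plus the 5'- or 3'-terminal part of exactly one adjacent gene, ends
taken in the gene's own strand orientation), `CDS5_IR_CDS3` (a 3' end,
the intergenic region, and the next gene's 5' end), and `OTHER` for
everything else — a peak spanning a whole gene, three or more genes, or
two same-polarity gene ends. A peak covering only an IR and one 3' end
stays `IR_3CDS`; it is never promoted to the composite category. For
`CDS` peaks the midpoint position within the gene is reported on a
5'→3' scale in $[0,1]$.

The fork-orientation call rests on one geometric convention, stated
once and used everywhere: with bidirectional replication from `ori`, a
position on the arc walked ori→ter in increasing coordinates is served
by the coordinate-increasing (CW) fork, and under a CW fork the plus
strand — running 5'→3' in the fork direction — cannot template
continuous synthesis, so it is the **lagging-strand template**; under a
CCW fork the minus strand is. A peak is `LAG` when the strand of the
gene(s) it overlaps equals the lagging template at its midpoint, `LEAD`
otherwise, and `ND` when no gene overlaps it, overlapping genes
disagree in strand, the midpoint sits exactly on ori/ter, or the peak
spans ori or ter. The source experiment never specifies how orientation
was derived for unstranded peaks; this gene-strand proxy is the
simplest rule consistent with an `ND` category, and it is isolated
behind `assign_fork_orientation()` so alternatives (e.g. summit-based
positioning, available via a flag) can be swapped without touching
anything else.

# Origin-proximity statistics

For a peak at circular distance $d$ from ori on a replicon of length
$L$, the normalized distance $u = d/(L/2)$ is exactly Uniform(0,1) when
peak positions are uniform on the circle — the bidirectional origin
makes the two arms exchangeable. "Peaks cluster around ori" therefore
becomes two standard tests on $u$: a one-sample Kolmogorov–Smirnov test
against Uniform(0,1) and a binomial test of the count with
$u \le \tau$ (default $\tau = 0.1$) against $n\tau$. Both are two-sided
and refuse $n < 5$.

# GC skew and ori/ter localization

Windowed skew is $(G-C)/(G+C)$ per tiling window (0 where a window has
no G or C), with a mean-centered cumulative sum attached so the
circular walk closes instead of drifting with overall composition. In
expectation the cumulative curve is a circular tent with minimum at ori
and maximum at ter. The default locator does not use the raw extremum:
the argmin of a noisy random walk is jittery. Instead it maximizes the
between-arm sum of squares $S_1^2/n_1 + S_2^2/n_2$ over all circular
boundary pairs — the maximum-likelihood two-segment mean-shift fit,
computable in one pass from prefix sums — and labels the
positive-mean arm's start as ori. The raw extremum remains available as
`method = "extremum"`.

Boundary precision is information-limited: each base contributes a
$\pm 1$ skew increment with probability `gc`, and the mean shift across
the boundary is $2s$, so the changepoint jitter has scale
$\sim 1/(gc\,(2s)^2)$ bp — about 650 bp at the defaults
($gc = 0.62$, $s = 0.05$) — **independent of the window width**.
Simulation during development confirmed ~400–500 bp typical error with
occasional multi-kb excursions. A display window of 100 bp (synthetic
scale) or 1 kb (real scale) is fine for the exported skew track, but
single-window localization at those widths is statistically
unattainable. `locate_ori_ter_window()` therefore recommends a locator
window of $50/(gc\,(2s)^2)$ bp (9 kb at the defaults), several times
the jitter scale, making a miss beyond one window rare; accuracy
claims are stated in units of that window.

# The synthetic study generator

The generator is first-class, tested code that defines the conditions
under which every end-to-end property is demonstrated. It emulates a
tripartite rhizobial genome at 1/10 scale — chromosome 365 kb and two
megaplasmid-like replicons of 147 kb and 161 kb, preserving the real
geometry while keeping full runs in seconds — with:

* per-base composition at 62% GC and skew amplitude $s = 0.05$,
  switching sign exactly at the configured ori/ter of each replicon;
* non-overlapping genes on both strands (gamma-distributed lengths,
  mean 900 bp, ~85% coding density);
* 13 insertion-sequence cassettes, each carrying the exact 25-nt
  insertion-site sequence with the upstream 25-mer starting 50 nt
  before the site and the downstream 25-mer starting 50 nt after it;
* 100 planted binding-site peaks (default), 200–600 bp, at 8-fold IP
  enrichment. Positions follow an exponential law in circular distance
  to ori (scale 20 kb), the arm chosen by fair coin; each peak is
  hosted in a gene whose strand is set to the lagging template with
  probability $p_{\mathrm{lag}} = 0.70$. Real enrichment in this
  system is far weaker (S/N ≈ 1.1); the synthetic default is set high
  so recovery properties are testable, and weak-enrichment runs are a
  single parameter away;
* one disjoint decoy peak set per control construct, so the expected
  unique-peak set equals the planted set exactly. Decoys and IS
  cassettes keep a 600-bp guard margin from true peaks because called
  peak boundaries bleed up to about a fragment length beyond the
  planted interval; without the margin a control call can brush a true
  peak and the subtraction filter silently removes it. The decoy count
  defaults to the true-peak count so total library sizes, and hence
  CPM normalizations, are comparable across constructs;
* eighteen libraries of 75-bp single-end reads from 300-bp fragments at
  20× mean fragment coverage each (a deliberate scale-down of the
  ~300× real coverage, matched to the 1/10 genome so that full
  pipeline runs stay interactive);
* optional insertion-site depletion (default 0.5) in the IP fractions
  of the two active-RNP constructs: the configured fraction of reads
  spanning the intact site 25-mer is removed, emulating interruption
  of the site by intron insertion during retrohoming. Depletion acts
  on junction-spanning *reads*, not on all overlapping fragments —
  fragment-level removal would deplete the flanking 25-mers (50 nt
  away, well within a fragment length) just as strongly and destroy
  their role as scan controls. It is applied to the IP fraction
  because that is where the deficit is observable relative to the
  construct's own input.

One integer seed drives every random draw; identical configuration and
seed give byte-identical output bundles, and every written table
carries the seed and a configuration hash in a `#` header.

What the generator does **not** emulate — sequencing errors, PCR
duplicates, mappability structure, copy-number gradients along the
replication coordinate, and the very weak real enrichment — bounds what
green tests mean: they demonstrate that the implementation recovers
planted structure under clean conditions at realistic scale, not that
the laboratory experiment would reach the same power.

# Validation experiments and problem sizes

The acceptance suite (one block per property, sizes chosen to finish in
minutes on one CPU) checks: FDR control of the caller (mean false-
discovery proportion at $q \le 10^{-3}$ over 100 simulations with 500
planted 8× peaks at 50× coverage, uniform positions so the ori-proximal
arm is not saturated); exact recovery of the 13 planted IS copies by
the genome-level scan; exact agreement of `subtract_overlapping` with a
brute-force all-pairs oracle on 1,000 random instances including
seam-wrapped intervals; recovery of $p_{\mathrm{lag}} = 0.70$ within
±0.06 from 300 planted genic peaks plus exact agreement of
`fork_direction` with a walking-simulation oracle on 10,000 random
geometries; calibration (type-I error within 3–7% at nominal 5% over
500 uniform draws) and power (≥90% at $n = 100$, decay scale $L/20$) of
the KS clustering test; ori/ter recovery within ±1 locator window on 20
synthetic genomes; end-to-end recovery of the planted unique-peak set
(recall ≥ 0.9, precision ≥ 0.95) on full pipeline runs and detection of
the depletion direction — via the flank-normalized site ratio, active
vs IEP-only construct — in ≥90% of 50 seeds; and a null coverage
comparison (no enrichment) in which each scope's Welch test stays
non-significant in ≥90% of 100 seeds. The null criterion is read per
scope: requiring both scopes jointly would have expectation
$0.95^2 \approx 0.90$ under exact calibration, i.e. a coin flip against
a ≥90% bound.

The real-data peak counts reported for this system (574/276/428 called,
321 unique, and the context tallies) depend on the deposited raw reads
and on external-tool internals; they are context for the category
vocabulary here, not targets, and nothing in the package is tuned to
them.

# Degenerate inputs and numerical conventions

Welch's test returns $p = 1$ for two zero-variance groups with equal
means and $p = 0$ with unequal means; `poisson_pvalue(0, λ) = 1`;
skew windows without G or C score 0; a constant-zero skew track yields
an explicit "undetermined" localization; BH q-values come from the
standard step-up implementation; ties in the KS test are tolerated
(test statistic unaffected, warning suppressed); subtraction of or from
empty peak sets is the identity/empty respectively. The coverage
comparison's "first 1,000 nt from the origin" is implemented as all
positions within 1,000 circular bp of ori on either arm (2 kb total),
since replication is bidirectional; the window is a parameter. The
pooled 9-vs-9 grouping is the default for that comparison, with
per-construct 3-vs-3 available via the `constructs` argument.

# Known limitations

The caller has no fragment-shift model, no IP-derived local background,
and no broad-peak mode; fork-orientation calls for intergenic peaks are
undefined by design (`ND`); megaplasmid replication is assumed strictly
bidirectional; GC-skew localization on replicons much smaller than ~20
locator windows loses the changepoint fit's advantage; and the
mismatch-tolerant site scan (edit distance ≤ k via the alignment-free
counter) is exact-match by default because exactness is what the tests
pin down.
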