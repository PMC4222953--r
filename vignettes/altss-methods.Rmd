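---
title: "Alternate splice-site choice from junction counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alternate splice-site choice from junction counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altss)
```

## The problem

Many mammalian exons carry two competing 5' (donor) or 3' (acceptor) splice
sites. The choice between the upstream and downstream alternative — A5C and
A3C events — rewires the mature mRNA: it can lengthen a UTR, insert or
remove coding sequence, or introduce a premature termination codon (PTC)
that routes the transcript into nonsense-mediated decay (NMD). RNA-binding
proteins such as the polypyrimidine tract-binding protein (Ptbp1) shift
this choice; coupling the shift to NMD lets a regulator set the abundance
of a target mRNA (AS-NMD), as in the donor-site switch of *Hps1* exon 18.

`altss` implements the junction-count route to discovering such events.
It consumes per-sample splice-junction read counts (it performs no
alignment), pairs junctions into candidate events, removes cassette-exon
look-alikes, tests differential usage across knockdown contrasts, predicts
the mRNA consequence of each event, and asks whether regulated classes
differ in two cis features: pyrimidine-motif density between the
alternative sites and donor-site strength asymmetry.

## Coordinate model

All coordinates are 0-based, half-open, genomic; a junction is its intron
interval. The donor is the intron boundary adjacent to the upstream exon
(`intron_start` on "+", `intron_end` on "-"), the acceptor the opposite
boundary. This single convention removes the ±1 ambiguities among the three
supported input dialects (SJ.out.tab, BED12 junctions, and the package's
generic junction TSV, which round-trips bit-exactly).

Junctions with unresolved strand (SJ.out.tab strand code 0) are dropped by
default, because u/d orientation — and everything downstream — requires
strand. If an exon annotation is supplied they are kept when all annotated
exons abutting either intron boundary agree on one strand. Only unique-read
counts are used by default; the multi-mapped column can be added by flag.
Introns shorter than 20 nt (configurable) are discarded as likely
alignment artifacts.

## Event model

An A5C event is an unordered pair of junctions sharing (chromosome, strand,
acceptor) with distinct donors; an A3C event shares the donor and differs
at the acceptor. With *k* alternative sites at one shared boundary, all
*k(k−1)/2* pairs are emitted and tested independently. The upstream (u) and
downstream (d) labels follow transcript orientation; the *extension region*
between the two alternative sites is exonic only in the long isoform, which
is in both event types the junction with the shorter intron.

**Cassette depletion.** A cassette exon's skipping junction shares a
boundary with an inclusion junction and therefore mimics an A5C/A3C pair.
The published recipe for this filter — requiring that the intron-distal
site "map to a known exon" — admits two readings. We implement the reading
that actually discriminates: an event is retained only when its full
extension region is contained in a single annotated exon on the same
strand. A cassette pair's inter-site region spans an intron, so it can
never satisfy containment, whereas a genuine A5C/A3C whose long exon
variant is annotated always does. The looser boundary-coincidence reading
is available behind `rule = "boundary"` for comparison. We do not require
the intron-proximal site to match an annotated exon edge, so events with
unannotated long isoforms can still be rescued by the looser rule.

## Differential usage

ψ is the long-isoform read percentage, `100 · n_long / (n_long + n_short)`,
undefined at zero depth. Replicates are pooled per condition before
testing; the emulated study design has one library per condition, and
pooling is the natural generalization (a dispersion-aware per-replicate
model is deliberately out of scope — the procedure is the exact test on
counts). Δψ uses the pooled ψ as well.

Each contrast (treatment vs reference) is tested with a two-sided Fisher's
exact test on the pooled 2×2 table, computed by the point-probability
rule: the p-value sums hypergeometric point probabilities of all tables
with the observed margins that are no more probable than the observed one
(with the customary 1 + 1e−7 relative slack against floating-point ties).
Zero row or column margins carry no information and give p = 1. An event is
**regulated** when *every* contrast has p < α (default 0.05) and |Δψ| >
δ (default 5 percentage points) and all Δψ share one sign — the
two-contrast consistency requirement. No multiple-testing correction
enters the flag by default; a Benjamini–Hochberg q column is always
reported, and `use_fdr = TRUE` gates on it instead.

Direction classes key on the intron-distal site so that one label covers
both event types: knockdown contrasts that *increase* ψ(long) mean the
factor was promoting the intron-distal alternative (**class 1**); decreases
mean **class 2**. For A5C the intron-distal site is the u5'ss (short
isoform), for A3C the d3'ss — in both cases Δψ(long) > 0 under knockdown
maps to class 1.

**Minimum evidence floor.** Fisher tables built from a handful of reads are
uninformative and their ψ estimates are wild. Events with fewer than 10
pooled reads (both isoforms, per contrast condition; configurable, 0
disables) are reported but not tested. The source procedure states no
floor; ours is documented, adjustable and off-by-default-able.

## mRNA consequence

Each retained event is grafted onto a host transcript: the longest
CDS-bearing annotated transcript with an exon boundary matching one of the
event's alternative sites (ties broken lexicographically by transcript id,
for determinism). The two isoform variants differ exactly by the extension
region. Both are spliced in silico and translated from the annotated CDS
start to the first in-frame stop.

Categories, in decision order: extension entirely 5' of the CDS start →
`UTR5_change`; entirely 3' of the reference stop → `UTR3_change`; altered
isoform's stop earlier than the reference stop and ending more than
`nmd_rule_nt` nucleotides upstream of the altered mRNA's last exon–exon
junction → `PTC_NMD`; earlier stop within that window or in the last exon →
`PTC_escape`; same stop with preserved frame → `ORF_change_noPTC`;
anything else (non-stop isoforms, non-coding hosts, incompatible
annotations) → `unresolved` with a reason. The NMD rule distance defaults
to the canonical 50-nt boundary rule; the underlying study predicted NMD
susceptibility without stating its rule, so the convention is explicit and
configurable here. Stop positions are measured at the last base of the
stop codon and junction distances in mRNA coordinates, which pins down the
±3 ambiguities.

## Cis features

**Motif density.** The density of the four Ptbp1-binding tetramers
(UCUC, UCUU, UUCU, CUCU; T ≡ U, case-insensitive) in the extension
sequence, counted with overlaps (a non-overlapping mode exists behind a
flag; the source analysis does not say which it used) and divided by the
extension length in nt. Any constant rescaling of the denominator cancels
in ECDF/KS comparisons, so the per-nt unit is a harmless choice.

**Donor strength.** Donor sites are summarized by the 9-mer at positions
−3..−1 (exonic) and +1..+6 (intronic), the window of classical donor
scorers; a percent-scaled score
`S = 100 (Σᵢ fᵢ(xᵢ) − Σᵢ minᵦ fᵢ(b)) / (Σᵢ maxᵦ fᵢ(b) − Σᵢ minᵦ fᵢ(b))`
places the per-position argmax 9-mer at 100 and the argmin at 0.
`ΔS = S(d5'ss) − S(u5'ss)`. The frequency matrix is either learned from
the annotation's internal donors (with pseudocounts; at least 50 distinct
donors required) or the bundled consensus-style default matrix. The
bundled matrix is a synthetic construction modeled on the familiar
mammalian donor consensus, not the matrix of any external scoring service,
so absolute scores are not comparable to published server scores; the
analyses here only use orderings and class-level distributions of S, which
are robust to that choice. The pipeline scores with the bundled matrix by
default so results do not depend on annotation completeness.

**Class comparison.** Class 1 and class 2 are the regulated A5C events by
direction; class 3 is a control of (by default) 100 events drawn uniformly
without replacement from the insensitive A5C pool (every contrast p ≥ α
and |Δψ| ≤ δ), with the sampling seed recorded in the report. Densities
are compared by the two-sample Kolmogorov–Smirnov test (D = pooled-ECDF
supremum; asymptotic two-sided p with effective n = n₁n₂/(n₁+n₂) — chosen
two-sided since the source analysis does not state sidedness) and ΔS by
the two-sample Wilcoxon rank-sum test against class 3. "Rank sum" here
denotes the two-sample test; a one-sample signed-rank against zero is a
defensible alternative reading of a "positive bias" claim and can be run
directly on the reported ΔS columns. The Wilcoxon p uses the exact
distribution for small tie-free samples and otherwise the tie-corrected
normal approximation with continuity correction; the exact small-sample
path keeps the test faithful in the tails, where a pure normal
approximation can be off by half an order of magnitude.

## The synthetic study

`synth_config()` fixes the emulated study conditions; these defaults *are*
the conditions under which the package's guarantees are stated, not tuning
knobs:

* three conditions — `control`, `kd1`, `kd2` — one replicate each
  (mirroring a design with one library per condition), contrasts
  kd1-vs-control and kd2-vs-control;
* three-exon genes, one per chromosome (avoiding accidental cross-gene
  junction grouping), strands alternating; exons 100–160 nt, introns
  120–200 nt, extensions 60–300 nt, GT..AG intron boundaries;
* class-1 genes: ψ(long) 10% in control, 40% in both knockdowns; class 2
  mirrored (40% → 10%); null genes: one ψ per gene from U[10, 90], equal
  across conditions; cassette decoys at constant 50% inclusion;
* read depth 200 per event per condition, drawn as
  `n_long ~ Binomial(depth, ψ/100)`, `n_short = depth − n_long` — the
  binomial matches the model the Fisher test assumes; there is no
  overdispersion, sequencing-error, or expression-level modeling;
* class-1 extensions are sampled from a pyrimidine-biased composition
  solving `rate = 4 p⁴` for the per-nt motif rate (0.08 for class 1 vs
  0.01 background — an 8× enrichment); class-1 donor pairs are two draws
  from the bundled matrix ordered so that the downstream donor is the
  stronger site (ΔS > 0 by construction), class-2/null donors are i.i.d.
  (ΔS symmetric about zero);
* both isoform variants of regulated and null genes are annotated (so
  containment-based depletion retains them); the reference ORF lives on
  the short isoform, with in-frame stops recoded out of the CDS and a
  terminal stop planted in the last exon;
* the generator consumes `seed` and the count simulator `seed + 1`, so
  counts can be re-simulated on a fixed reference; everything is
  byte-deterministic under the seed.

What passing tests on this generator do **not** show: robustness to
overdispersed counts, to incomplete annotations (exercisable via the
boundary rule), to multi-isoform genes beyond two variants, or to
alignment artifacts — the generator emulates junction-count statistics,
not reads.

## Numerical and design choices

* Problem sizes in the validation suite were chosen to make the
  statistical checks decisive at desk scale: 50 random junction sets of up
  to 500 junctions against the all-pairs oracle; 200 random 2×2 tables
  against full hypergeometric enumeration (≤ 1e−9 absolute); 200 planted +
  800 null events at depth 200 for recovery (observed sensitivity 1.00,
  false-positive rate 0.0075 at the default thresholds — the two
  independent 5% tests plus sign consistency bound the joint null rate
  well below 1%); 100-control class comparisons for the cis-feature
  structure.
* Ties in ranks use midranks; ties in the KS samples are handled by
  evaluating ECDFs on the pooled support (the D statistic is exact under
  ties; the asymptotic p is then conservative).
* Degenerate inputs have defined behavior rather than errors wherever a
  convention exists: zero-margin Fisher tables (p = 1), identical Wilcoxon
  samples (p = 1), zero-depth ψ (undefined, event reported untested),
  empty junction sets (empty event tables).
* The command surface is the R API itself (`run_simulate()`,
  `run_discover()`, `discover_from_files()`, plus the writers); a shell
  wrapper would add nothing for the package's intended interactive and
  scripted use.

## Known limitations

* Fisher on pooled counts treats biological replicates as exchangeable
  reads; with true replicate-level dispersion the false-positive rate is
  anti-conservative. The design keeps the exact-test procedure on purpose.
* NMD prediction implements only the 50-nt boundary rule — no uORFs,
  long-3'UTR triggers, or nuclear-retention modeling.
* Donor-strength scores are matrix-relative; only orderings and
  distributional comparisons of S should be interpreted, never absolute
  values against external servers.
* Events whose host transcript lacks an annotated CDS, or whose
  boundaries match no annotated transcript, are reported `unresolved`
  rather than guessed.
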