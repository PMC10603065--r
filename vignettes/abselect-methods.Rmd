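---
title: "NGS-guided antibody lead selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NGS-guided antibody lead selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abselect)
```

## The problem

In vitro antibody discovery campaigns (phage panning followed by
yeast-display sorting of an scFv library) produce polyclonal outputs in
which a few clones dominate and most are rare. Random colony picking
samples this distribution poorly, and deep sequencing of the sorted
populations over-reports diversity because PCR and sequencing errors
manufacture sequence variants that never existed in the sorted cells.
`abselect` implements the analysis path from raw barcoded long-read
amplicons to ranked lead candidates:

1. quality filtering and inline-barcode demultiplexing of scFv reads;
2. scaffold-anchored annotation of CDRs and frameworks;
3. density-based clustering of CDR regions of interest (AbScan),
   alongside traditional clonotyping and 100%-identity condensation;
4. per-population relative frequencies and early-to-late sort
   enrichment with pseudo-count corrections;
5. diversity-accumulation curves and a power-law read-depth model;
6. liability screening, representative selection and gradient-boosted
   binder classification / affinity regression.

A campaign simulator with complete ground truth makes each stage
testable at desk scale.

## Reads: quality filter and demultiplexing

Reads are expected as consensus long-read amplicons (circular-consensus
class accuracy), Sanger/Phred+33 encoded. The default filter demands
**every** base at Phred ≥ 40 (`fraction_required = 1`); this is an
aggressive filter that is only sensible for consensus reads, so
`fraction_required` is exposed for other read types. The threshold is
inclusive.

Demultiplexing matches the terminal 8-mers of a read against a barcode
table. A barcode matches when at most 2 of its 8 positions mismatch
(≥ 70% identity); a read is assigned to the unique population with both
barcodes matching and the minimal total mismatch count, and ties are
left unassigned rather than placed arbitrarily. The 3' barcode is
compared against the reverse complement of the read tail so that the
table stores both barcodes in sense orientation (`bc3_as_given`
disables this). Barcode placement is assumed terminal; inner primer
structure is out of scope.

## Annotation without a germline database

Because display libraries of this design are built on a small set of
fixed clinical scaffolds, germline-database alignment is unnecessary:
the framework sequences are known per scaffold and act as anchors.
`annotate_reads()` translates each read (three forward frames; the
first frame without internal stops is used; reads with none are
rejected as `frameshift`), locates the eight framework strings by exact
search with a substitution-tolerant fallback, and extracts the six CDRs
as the spans between consecutive anchors (0-based half-open intervals
on the translated chain; the scFv layout is VL–linker–VH). The scaffold
call is the reference with the best concatenated-framework identity;
calls below `identity_floor` (default 0.70) are rejected as
`no_scaffold`. The fuzzy fallback only engages for reads that already
hit at least six of the eight anchors exactly, which keeps wrong
scaffold candidates cheap to dismiss.

Substitution-only errors leave region lengths intact, which is the
regime the annotation targets; indels generally shift the frame and are
surfaced as rejections rather than silently mis-annotated.

## Regions of interest and the reduced alphabet

Counting and clustering operate on a *region of interest* (ROI): one
CDR (`HCDR3`), the light+heavy CDR3 pair (`HCDR3+LCDR3`), all six CDRs
(`CDRs`), or the full-length sequence (`FULL`). Concatenations are
fixed-order (light before heavy, CDR1 < CDR2 < CDR3) and joined with
`|`, so equal ROI strings mean equal region content.

For clustering, amino-acid sequences are first reduced to an 11-group
physicochemical alphabet. The shipped default groups aliphatics
(LVIM), aromatics (FYW), acids (DE), amides (NQ), bases (KR) and
hydroxyls (ST), and keeps A, C, G, H and P as singleton groups — an
11-class refinement in the style of the Murphy reduced alphabets. The
mapping is an ordinary named character vector and is intended to be
replaced wholesale when a different published grouping is preferred.
Group characters are lower-case, so reduction is idempotent and
pseudo-sequences cannot be confused with amino-acid strings. Reduction
is character-wise, hence length-preserving, and it contracts
Levenshtein distances (a within-group substitution costs nothing).

## AbScan clustering

AbScan clusters the *distinct reduced-space representations* of the ROI
values, each carrying the pooled read count of all amino-acid values
that condense onto it. Clustering condensed units rather than raw
values matters numerically: duplicated points (distance 0) produce
infinitely steep valleys in the reachability plot that the xi
extraction would carve into spurious micro-clusters.

For a set of units the procedure is:

* **Distances.** Pairwise Levenshtein distances in reduced space
  (`Biostrings::stringDist`).
* **Epsilon.** The k-distance curve (k = `min_pts`, with core-distance
  semantics: the k-th smallest entry of each row including the point
  itself, i.e. the nearest-neighbor distance at the default
  `min_pts = 2`) is sorted ascending and the knee is the point of
  maximum perpendicular distance to the chord between the curve's
  endpoints; ties break to the smallest index. The result is floored at
  the smallest positive pairwise distance; all-zero matrices fall back
  to a configured minimum, and two points fall back to their distance.
* **OPTICS.** The canonical ordering is computed under
  `max_eps = 10 × eps`, with deterministic seed and tie handling
  (smallest index); inputs are canonically sorted (descending
  abundance, then lexicographic) beforehand, so results do not depend
  on input order. Flat clusters are extracted from the reachability
  plot with the xi steep-area method (`xi = 0.01`, minimum cluster size
  `min_pts`), including predecessor correction; an eps-cut extraction
  (DBSCAN-equivalent at `max_eps`) is available as an alternative. On
  configurations whose groups are separated beyond `max_eps` with
  uniform internal density, the xi extraction provably returns the
  density-reachability components, and the test suite holds it to a
  brute-force density-reachability oracle on such instances.
* **Abundance-seeded rounds.** Clustering proceeds in rounds over a
  strictly decreasing percent-abundance schedule (default
  0.005, 0.0005, 0.00005, 0): the seed round clusters only units at or
  above 0.005% relative abundance — the trustworthy part of the
  population — and each later round re-clusters all units seen so far
  plus the next abundance tranche. Cluster identities are anchored by
  exemplars (a cluster's most abundant member): a new round's cluster
  inherits the id of the most abundant exemplar it contains, clusters
  without an exemplar get fresh ids, and previously assigned units
  that drop to noise keep their id. We deliberately re-cluster *all*
  seen units rather than exemplars only: the seed round is sparse, and
  any density method will merge or drop lone dominant units whose
  mutual distances approximate the inter-family scale; carrying only
  exemplars forward freezes those sparsity artifacts, whereas full
  re-clustering lets the dense later rounds recover the true structure
  while the exemplar anchoring keeps ids stable across rounds. The
  elbow epsilon is recomputed each round (each round has a different
  point set); `freeze_epsilon` pins the seed-round value instead.
* **Noise rescue.** After the last round, units still unassigned are
  rescued in two passes: a unit whose reduced-space read count reaches
  `rescue_min_count` (default 2) becomes its own singleton cluster
  (`rescued_count`) — dominant but isolated sequences are real; a unit
  whose amino-acid value matches an assigned value of equal length at
  ≥ 90% identity joins that value's cluster (`rescued_identity`,
  plain Hamming identity, best match wins with ties to the more
  abundant partner). Everything else is reported as `discarded_noise`
  with no cluster id — the artifact fraction of the library.

Each amino-acid ROI value inherits its unit's cluster and status; the
most abundant member of each cluster is flagged `core`.

`traditional_clonotype()` implements the conventional alternative:
single-linkage components over pairs with equal length, equal scaffold
call (the V/J surrogate) and ≥ 90% Hamming identity, with component ids
ordered by the lexicographically smallest member. `identity_cluster()`
is the 100%-identity baseline. On error-inflated data the three methods
are nested: identity values ≥ clonotypes ≥ AbScan clusters.

## Frequencies, enrichment and corrections

The relative frequency of ROI value *i* within one (population,
concentration) group is `100 · count_i / Σ count`, after condensing all
full-length clones that share the ROI value. Enrichment compares the
late (1 nM) sort round against the early (10 nM) one:
`enrichment_i = rel_freq_late_i / rel_freq_early_i`. The plain fold
ratio is the default output because every downstream threshold
("tenfold", "< 0.01x") is quoted in fold units; `percent_scale = TRUE`
multiplies by 100 for the percent form of the same quantity.

ROIs present in only one round receive a pseudo-count: the minimum
observed ROI count of the missing round divided by a correction factor
— 2 when absent early (rewarding apparent enrichment mildly), 10 when
absent late (penalizing depletion heavily). The policy object enforces
`factor_absent_late ≥ factor_absent_early`. By default the pseudo-count
enters only the corrected ROI's own numerator, leaving all observed
frequencies untouched; `pseudo_in_denominator = TRUE` adds it to the
denominator sum instead, and both conventions are pinned by regression
tests. The round minimum is read as the global minimum count of that
round's population; per-ROI alternatives are indistinguishable at the
level of the defining equations.

## Diversity and the read-depth model

`accumulation_curve()` shuffles per-read unit labels with a seeded
generator and counts distinct units in the first *d* reads, for a
log-spaced depth grid (default 10 depths from 100 to the read count,
5 replicates). The unit can be a ROI value or a cluster: the fast
cluster mode maps reads onto the full-data cluster labels, and an
exact mode re-clusters each subsample through `diversity_fun`. Reads
carrying no unit (discarded noise) add nothing.

The read-depth model is `reads = C · D^k`, fit by nonlinear least
squares with reads as the response (the sampled read number is the
dependent quantity; diversity is what it buys), initialized from the
log–log linear regression, with the log–log estimate returned and
flagged when the nonlinear fit fails. `reads_required()` evaluates
`ceiling(C · D^k)` at a target diversity. Two caveats: the model
describes the growing part of an accumulation curve, so fitting a
fully saturated cluster curve yields a steep, descriptive-only
exponent; and extrapolation beyond the fitted depth range inherits the
usual risks of power-law extrapolation.

## Lead ranking and the supervised models

Within a cluster the default pick is the most abundant full-length
member (ties broken by lexicographically smallest sequence, keeping
selection deterministic); selection by fold enrichment is available.
`liability_alternatives()` lists members with strictly fewer liability
motifs than the representative, annotated improved/similar/worse at
twofold and fivefold KD thresholds when affinities are known. The
default motif set covers deamidation (NG, NS), isomerization (DG), the
N-glycosylation sequon (N[^P][ST]), acid-labile DP, unpaired cysteine
and methionine oxidation; the last two are meaningful when scanning
CDRs, where no scaffold cysteines occur, and the whole set is a plain
named vector of regular expressions that callers can replace.

`bin_concordance()` scores whether clusters predict epitope bins: a
cluster with at least two characterized members is consistent when all
of them share one bin. `binder_heuristic()` applies the campaign-level
abundance cutoff (0.005% of the concatenated CDRs, inclusive) that
broadly separates binders from non-binders, with the documented caveat
that genuine binders occur below it.

The supervised models are gradient-boosted tree ensembles (xgboost).
Features per unique full-length clone: log10 early and late relative
frequency and log10 fold enrichment for each of the four ROIs, AbScan
cluster size, liability count, and optionally one-hot framework
residues over a fixed per-position vocabulary (20 residues + pad).
Missing frequencies are imputed with the smallest observed positive
value of the column and flagged. The evaluation protocol follows the
small-data regime it is meant for: an equal train/test split (default
100/100), hyperparameters chosen by seeded random search (default 25
draws over depth, learning rate, rounds and subsampling) scored by the
mean out-of-bag bootstrap metric on the training half (precision-recall
area for classification, Spearman for regression; default 100
resamples), then a single refit and one held-out evaluation. Reported
metrics: confusion matrix, precision, recall, ROC and precision-recall
areas, or Pearson/Spearman of predicted vs measured log10 KD, plus the
bootstrap metric distribution and the top-5 feature importances.

One evaluation subtlety the package's tests make explicit: clones of
one clonal family share their latent affinity, and NGS features
(frequencies, cluster size) fingerprint families almost uniquely.
Splitting related clones across train and test therefore yields real
held-out skill even when abundance is statistically independent of
affinity — the model recognizes families, not affinity. Property tests
that ask "is there affinity signal?" therefore evaluate one clone per
family. The same relatedness applies to any within-campaign evaluation
on real data.

## The campaign simulator

`simulate_campaign()` emulates the statistical structure of a
two-round, multi-arm selection campaign:

* a handful of fixed scaffolds (default 4) with known frameworks;
* clonal families (default 50) with random prototype CDRs of typical
  lengths (HCDR3 10–18 aa) plus Poisson-many variants within
  `intra_family_edits` (default 2) substitutions of the prototype;
* Zipf family abundance (exponent 1.5, arm-specific rank order),
  within-family geometric variant shares;
* per-family latent log10 KD ~ N(−8.1, 2.4) — the normal quantile
  match to a selection output with 64% sub-nanomolar binders and 19%
  non-binders (≥ 1 µM) — and family-level epitope bins (default 5);
* late-round weights ∝ early weights × exp(β · (−log10 KD)),
  renormalized; the default β = 0 encodes the empirical finding that a
  single late selective step couples abundance to affinity weakly, and
  tests that need signal set β explicitly;
* substitution-only sequencing errors (default 0.1% per base,
  consensus-read-like; indels are deliberately absent by default since
  they exercise only the rejection path), occasional barcode errors,
  and a 2% fraction of reads carrying one sub-40 quality base;
* inline 8-mer barcodes per (arm, concentration), generated with
  pairwise Hamming distance ≥ 5 so the 2-mismatch demultiplexer is
  unambiguous.

Everything is deterministic given the seed, including byte-identical
FASTQ output. `truth_metrics()` scores a pipeline run against the
ground truth: adjusted Rand index between cluster assignments and true
families over unique ROI values (each attributed to its majority family
of origin), total-variation distance between observed and configured
family weights, and the Spearman correlation of per-family fold
enrichment with latent affinity.

What the simulator does *not* model — and what passing tests therefore
do not establish about real campaigns: indel errors and chimeric PCR
products; context-dependent error rates; display biology (growth
competition, display valency, avidity on multimeric antigens);
germline-similar scaffolds whose frameworks are harder to distinguish
than random ones; and natural repertoire structure, where HCDR3s share
germline-derived motifs and sit closer together in reduced space than
random prototypes do. The cluster-recovery results on simulated
campaigns are therefore a correctness check of the machinery, not a
claim about cluster counts in any particular real library.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale campaigns chosen as the
package's own reference conditions: 50 families with 0.1%/nt
substitution error at 50,000 reads per population for the
diversity-plateau and cluster-recovery properties (one target arm;
per-arm properties do not depend on the arm count), three arms at the
same depth in the acceptance script, and 80-family/10,000-read
campaigns for the regression-signal properties. Oracle-equivalence
suites run on ≥ 100 random instances of ≤ 10 points (density
clustering), 1,000 random string pairs (Levenshtein), and ≤ 20-point
instances (ranking metrics).

Numerical conventions, in one place: Phred+33 encoding fixed (no
autodetection); all thresholds inclusive (`≥`); canonical sort is
descending abundance then lexicographic, and every tie-break in the
package (exemplars, representatives, knee, OPTICS seeds) resolves to
the smallest index or lexicographically smallest string so that every
result is deterministic; degenerate distance matrices floor the elbow
at `min_eps` (default 1, the smallest positive Levenshtein distance);
empty inputs return typed empty results, and contract violations are
hard errors naming the offending record.

## Known limitations

Rejected reads (frameshift, failed anchors) are reported but not
recovered; paired-end merging, consensus building and adapter discovery
are upstream concerns. Full germline numbering (IMGT/KABAT) is out of
scope — CDR boundaries are whatever the scaffold anchors say, and
published boundary conventions can be reproduced by adjusting the
anchor coordinates in the scaffold reference. The supervised models are
campaign-specific by design; nothing here claims cross-antigen
generalization.
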