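---
title: "Prioritizing rare structural variants shared within a phenotype subgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare structural variants shared within a phenotype subgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svprior)
```

## The problem

Severe tinnitus in Meniere disease (MD) is a rare, heritable trait. Beyond
single-nucleotide burden, rare copy-number variants (CNVs) — multi-kilobase
deletions and duplications — may contribute, but exome-based SV calls are
noisy: the three common caller families (read-depth segmentation, split-read,
discordant-pair) disagree on breakpoints and sometimes on the DEL/DUP label
of the same event. `svprior` implements a prioritization cascade that turns
per-sample, per-caller VCF call sets plus a phenotype table into a short
list of candidate regions shared by several patients of the phenotype-defined
subgroup of interest (here: severe tinnitus, defined by a Tinnitus Handicap
Inventory score above the cohort's third quartile), supported by at least
two callers, and absent from the comparison subgroup.

## The procedure

All interval arithmetic uses the VCF symbolic-allele convention: an SV
occupies `(start, end]` on a 1-based genome, its affected bases are
`start+1 .. end`, and its length is `end - start`. This is the only
convention under which a call's printed length, its BED representation and
its VCF POS/END agree without re-basing, and it reproduces the length of
every fixture record shipped with the package. BED input maps verbatim
(internal start = BED start, internal end = BED end), which provably
preserves the half-open overlap relation.

Per caller and per subgroup, the cascade runs:

1. **Length filter.** Calls longer than 100 kb are removed (strictly
   greater; a 100,000 bp call survives). Exome read-depth segmentation is
   unreliable at that scale and such calls are dominated by artifacts.
2. **ACMG class filter.** Only pathogenic, likely pathogenic and
   uncertain-significance calls are kept. Classification happens upstream
   (an AnnotSV-style annotator); the package consumes the class as an
   INFO key and maps absent annotations to `unclassified`, which is
   dropped by default.
3. **Within-subgroup sharing.** Same-caller calls are linked when they lie
   on the same chromosome, have the same SV type, and overlap reciprocally
   by at least 60%: `RO(a, b) = min(I/len(a), I/len(b))` with `I` the
   intersection length. Connected components of this link graph
   (single linkage — what RO-graph merging toolkits such as SVDB compute)
   are the shared regions; components carried by fewer than two distinct
   samples are discarded. Each cluster is summarized by its member-wise
   lower-median breakpoints and majority type.
4. **Split gene annotation.** Each region becomes one row per gene it
   overlaps by at least 1 bp.
5. **Blacklist filter.** Rows whose gene is on the FLAGS (frequently
   mutated genes) or olfactory-receptor lists are removed; a region is
   dropped only when all its gene rows are removed.
6. **Subgroup-unique genes.** A severe-subgroup row survives only if its
   gene appears in no retained non-severe cluster of the same caller's
   path.
7. **Cross-caller consensus.** The per-caller candidate lists are
   intersected: regions from different callers match when RO >= 0.6 *or*
   both breakpoints agree within 200 bp, and only groups supported by at
   least two callers are reported. Matching deliberately ignores the SV
   type: DEL/DUP disagreement between callers on the same region is a
   known failure mode that the original analysis resolved by manual IGV
   review, so the pipeline surfaces it as `type_discordant = TRUE` (with
   the per-caller labels recorded, and the majority label — or `OTHER` on
   a tie — as the display type) rather than silently deciding.

Reported candidates are then annotated against a population SV database
(any same-type record overlapping by >= 1 bp counts — population
references legitimately report small events that only partially tile a
candidate, so a reciprocal-overlap threshold is opt-in) and against a
gene-constraint table, ranking each candidate's genes by lowest LOEUF
with ties broken by highest pLI.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_sv_length` | 100,000 | bp | exome CNV resolution limit; strict "greater than" |
| `keep_acmg` | P/LP/VUS | — | benign and unclassified calls carry no candidate signal |
| `min_ro` | 0.60 | fraction | standard SV-merging reciprocal-overlap threshold |
| `min_samples` | 2 | samples | "shared" means two or more carriers in the subgroup |
| `min_callers` | 2 | callers | one caller alone is insufficient evidence |
| `breakpoint_tol` | 200 | bp | covers observed 1 bp / 70 bp inter-caller offsets with margin; rescues near-identical pairs whose RO is skewed by one stretched breakpoint |
| `thi_threshold` | data Q3 | THI score | severe iff score strictly above; override reproduces any published split |

The third quartile is estimated by linear interpolation between order
statistics (`quantile(type = 7)`, the default of most statistical
software). Because a published analysis may have used another estimator,
`partition_by_thi()` accepts an explicit threshold override, and the
threshold actually used is recorded in the result attributes and the
stage report.

Two genuinely open choices are exposed as switches rather than decided
silently. First, "60% overlap" could be reciprocal or directional;
reciprocal is the default (it is what the merging toolkits implement and
it is symmetric, hence oracle-checkable), with
`overlap_mode = "directional"` available. Second, the non-severe
comparison set for the uniqueness step defaults to retained non-severe
*clusters* (`uniqueness_basis = "clusters"`): a gene is subtracted only
when the non-severe subgroup shows the same kind of shared, filtered
evidence. The alternative (`"calls"`) subtracts genes touched by any raw
post-filter non-severe call, which is stricter and can be argued from the
wording "genes unique for severe patients"; it is available but not the
default because a single noisy private call should not veto a candidate.
The uniqueness comparison stays within each caller's path — the per-tool
paths are independent until the final consensus. A gene can therefore leak
through one caller's path when only other callers saw the non-severe
evidence; such leaks are caught at the consensus stage, which is why the
pipeline reports both stages in its count report.

## The synthetic cohort

Real patient-level call sets of this kind are access-restricted, so the
package ships a seeded generator (`generate_cohort()`) that emulates the
study conditions and makes every stage testable end to end:

* 310 samples whose THI distribution is skewed with its third quartile at
  exactly 68, placing 75 samples in the severe subgroup (both counts are
  functions of `n_samples`; the generator constructs the order statistics
  around the quartile window explicitly).
* Three callers per sample. Planted events are re-emitted per caller with
  breakpoint jitter (uniform, up to 5 bp at the start and 70 bp at the
  end — the asymmetry mirrors the observed inter-caller offsets), 10%
  per-carrier caller dropout, and a 10% chance per planted severe event
  that one caller reports the opposite DEL/DUP type.
* Four planted severe-specific shared SVs by default — three overlapping
  ~0.8 kb deletions inside an `ERBB3`-like gene and one 22.5 kb
  duplication spanning a seven-gene block (four coding, three microRNA) —
  plus one decoy family per rejection stage: oversize (150 kb), benign,
  blacklist-only, cross-group-shared, single-caller, and non-severe-only
  shared events.
* A population database containing near-copies of the planted candidates
  (breakpoints shifted by a few bases, low allele frequencies) plus random
  records; a constraint table carrying the published LOEUF/pLI values for
  the five fixture genes and synthetic scores elsewhere; and the three
  expression fixtures.

Coordinates live on a two-chromosome, 2 x 25 Mb mini-genome; the pipeline
is sequence-free, so no FASTA is needed. All draws come from category-scoped
RNG substreams keyed by `(seed, category)`, so enabling or resizing one
decoy category does not perturb the draws of another, and a fixed seed
yields byte-identical bundles.

Three generator rules keep the truth set decidable *by construction*,
which is what makes exact precision/recall assertions honest rather than
lucky:

* Background private calls (Poisson, mean 20 per sample) are
  rejection-sampled at least 50 kb away from every planted locus, so no
  background call can join, split, or veto a planted event. Their ACMG
  classes are drawn mostly benign (40% benign / 30% likely benign / 30%
  VUS), as an annotator would classify random exome CNV noise.
* Caller dropout is capped so that at least two callers retain *all*
  carriers of a planted multi-caller event — otherwise the >= 2-callers
  consensus could not be expected to recover it; when a type mislabel is
  planted, the mislabeled caller is chosen among those fully-covering
  callers so the discordance is guaranteed to reach the consensus stage.
* Cross-group events are exempt from dropout entirely: they emulate CNVs
  common to the whole cohort, and every caller must see their non-severe
  evidence for the uniqueness rejection to be decidable in every
  per-caller path.

What the generator does **not** emulate — and hence what passing its tests
does not show: realistic caller error models (false-negative structure,
depth-dependent breakpoint uncertainty, fragmented calls), linkage between
events, population stratification of the frequency database, or any
sequence-level effect. Recovering planted truth perfectly demonstrates the
cascade's logic and bookkeeping, not performance on real exomes.

## Expression summarization

Heterogeneous expression sources (human brain RNA-Seq in TPM, mouse
cochlear RNA-Seq in RPKM, mouse spiral-ganglion microarray intensities)
are made comparable by rescaling each dataset to 0–100 by its *dataset-wide*
maximum — not per gene or per tissue, so within-dataset contrasts are
preserved exactly and the transform is idempotent and scale-invariant.
Datasets are merged by human gene symbol (mouse rows translated through an
ortholog map; genes absent from a dataset carry `NA`, which is distinct
from measured zero), and displayed as `log10(x + 1)`: the pseudocount keeps
exact zeros at zero — a gene not expressed anywhere stays at the bottom of
the scale instead of becoming undefined — and the map is strictly monotone,
with range `[0, log10(101)]`.

## Numerical choices and degenerate inputs

* Reciprocal overlap is undefined for zero-length intervals; these (and
  BND records, which have no interval) are excluded from interval
  operations and the exclusion is logged at parse time.
* Cluster and consensus representatives use the *lower* median (the
  `floor((n+1)/2)`-th order statistic) so representatives are always
  observed breakpoints and no averaging artifacts appear.
* Majority-type ties fall back to `OTHER` plus a flag; they are never
  broken arbitrarily.
* A VCF record with `END` missing is recovered as `POS + |SVLEN|`; records
  with neither are skipped with a warning. A negative computed length is a
  record-level error, not a silent fix.
* Cohorts with fewer than four samples cannot support a quartile estimate
  and require an explicit threshold.
* An all-zero expression dataset cannot be rescaled and is returned
  unchanged with a warning.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
default 310-sample, three-caller cohort (roughly 6,300 calls) once from
disk; the test suite additionally runs it in memory across five seeds and
checks the clustering against a brute-force single-linkage oracle on 500
random instances of up to 12 calls. These sizes exercise every code path
at the cohort scale of the motivating study while keeping a full run in
the tens of seconds on one core.

## Known limitations

* The ACMG class is consumed, never computed; garbage in, garbage out.
* Breakend (BND) pairs are not resolved into intervals; inversions are
  clustered like any interval but receive no special breakpoint model.
* Population-frequency columns are reported as given and never recomputed
  from carrier counts.
* The per-caller uniqueness subtraction can be overly permissive when one
  caller systematically misses non-severe carriers (see above); the
  consensus stage mitigates but does not eliminate this.
* Family segregation, re-genotyping from BAMs, and visual review are out
  of scope: the `type_discordant` flag marks exactly the calls that would
  need such review.
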