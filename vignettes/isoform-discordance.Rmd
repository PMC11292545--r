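---
title: "Calling protein-isoform discordance from peptide-centric DIA quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling protein-isoform discordance from peptide-centric DIA quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathsplice)
```

## The problem

Bottom-up proteomics never observes proteins, only peptides. In a
DIA/SWATH experiment each identified peptide carries a per-sample ion
area, and each peptide matches a *set* of protein accessions — its
protein group. When a database includes splice isoforms, that accession
set is informative about splicing: a peptide present in *all* isoforms
of a gene's protein family reports total protein abundance, while a
peptide present in only *some* isoforms reports the abundance of those
isoforms specifically. If, between two cohorts, the isoform-specific
signal moves while the isoform-common signal stays flat, the protein's
overall amount is unchanged but its isoform usage is not — the
protein-level signature of an alternative-splicing change. swathsplice
implements that inference as a reproducible pipeline, from peptide area
export to per-family splicing verdicts, for two-cohort designs such as
a fertile/infertile sperm-proteome comparison.

## Peptide classification and protein-group composition

Accessions are grouped into isoform *families* by stripping a terminal
`-<integer>` suffix (UniProt isoform naming): `P68363-2` belongs to
family `P68363`, an accession without the suffix is its own canonical.
Given a catalog of families, every peptide's accession set falls into
exactly one of four classes:

* **UNIQUE** — all evidence points to a single-isoform family;
* **ISOFORM_SPECIFIC** — a proper subset of one family's isoforms;
* **SHARED_ISOFORMS** — all cataloged isoforms of one multi-isoform family;
* **SHARED_MULTI** — accessions spanning more than one family.

Peptides with *identical* accession sets are then pooled into protein
groups, and group areas are the per-sample sum of member peptide areas.
Summation runs over observed members only; a group is missing in a
sample only when every member is missing there. The primary cohort
comparison drops `SHARED_MULTI` peptides (their signal is a mixture
across genes), while the isoform analysis keeps everything — the
common-vs-specific contrast *requires* the shared-among-isoforms
groups. Peptides shared only among isoforms of one family are retained
in both branches for the same reason.

Two open representation choices are worth flagging for users. First,
peptides are keyed by `(sequence, modification)`: modification variants
are kept separate, but since they carry the same accession set they end
up summed into the same group anyway. Second, leucine/isoleucine are
*not* collapsed — search engines report the matched database sequence,
and the in-silico digestion module mirrors that.

## Normalization

Group areas are log2-transformed and each sample's median (over present
values) is subtracted. This removes multiplicative loading and
acquisition offsets; after centering, every sample's median is exactly
zero, and between-group log2 differences are invariant to any
per-sample constant offsets. Medians over an even count use the mean of
the two central order statistics — the convention is fixed so reruns
are bit-reproducible. Normalization is computed once, on the composed
group matrix with shared peptides included; the primary branch is the
row subset without `SHARED_MULTI` groups, which is exactly what an
exclusion-policy composition would have produced, because group values
depend only on the accession-set key. Running both branches from one
normalization pass keeps their records directly comparable. (Whether
the original analysis normalized at the peptide or composed-group level
is ambiguous; composed-group level is the default here, and the
peptide-level alternative can be had by composing after centering.)

## Differential statistics

Per group, cohorts are compared with a two-sided, equal-variance
(pooled) Student's t-test; the Welch alternative was deliberately not
made the default because the pooled test is the convention in the
Perseus-style workflows this pipeline mirrors. A group is *testable*
when it has at least `min_obs_per_group` (default 3) observed values in
each cohort. Constant testable groups take the defined limit
$t = 0, p = 1$.

False-discovery rates come from cohort-label permutations. For a
group's observed p-value $p_i$,

$$ q_i \;=\; \frac{\tfrac{1}{B}\sum_{b=1}^{B} \#\{j : p^{(b)}_j \le p_i\}}
                 {\#\{j : p_j \le p_i\}} $$

clipped to $[0, 1]$ and made monotone nondecreasing in $p$ by a sweep
from the largest p-value downward. When the number of distinct label
splits $\binom{n}{n_A}$ is at most `permutations` (default 1000), all
splits are enumerated instead of sampled, so small designs are exact.
The permutation generator is seeded from the thresholds object; results
are reproducible by construction.

The differential-abundance filter is the combined rule *p* <
`p_de` (default 0.05) **and** fold ≥ `fc_de` (default 2), with fold
defined symmetrically as $2^{|\Delta \log_2|}$ plus a direction label,
matching the "X-fold higher/lower" idiom of proteomic reporting.

## The discordance verdict

For each multi-isoform family the caller contrasts its
isoform-specific groups against its shared-among-isoforms (common)
group:

* **SPLICING_DISCORDANT** — some testable specific group passes the
  isoform filter (*p* < `p_iso`, default 0.01, **and** fold ≥ `fc_iso`,
  default 2) while the common group is testable and does *not* pass the
  abundance filter;
* **ABUNDANCE_CONCORDANT** — the common group passes the abundance
  filter and a testable specific group passes it in the same direction
  (a whole-protein shift);
* **UNTESTABLE** — no testable specific group, no testable common
  group, or neither pattern holds.

The raw-p isoform filter is kept as a raw threshold (not an FDR cut),
with q-values reported alongside for transparency. The fold gate on the
specific group is this package's design choice: with hundreds of
isoform-specific groups tested, a raw *p* < 0.01 criterion alone admits
a few chance hits per experiment, and every credible isoform-usage
event in this setting is a multi-fold change — the gate removes the
chance hits without touching real events (all planted events in the
validation suite are ≥ 6-fold). Users who want the bare raw-p behaviour
can set `fc_iso = 1`. A fold-change *ceiling* on the common group was
considered and rejected: the combined p/fold abundance criterion
already encodes "the common group did not change" and needs no second
knob.

## The synthetic validation data

Because the deposited raw data are not required at desk scale, a
truth-bearing generator emulates the study's structure: 12 vs 11
samples; 1400 protein families of which 10% carry 2–3 isoforms; 3–8
peptides per protein with roughly 30% of a multi-isoform family's
peptides isoform-specific (at least one per isoform); 2% of peptides
injected into a second family to create cross-family shared peptides;
369 planted whole-protein shifts drawn log-uniformly from 2–8-fold with
random sign; 6 planted isoform-usage shifts of 6–50-fold applied only
to the target isoform's specific peptides, with a small opposite
compensatory drift (≤ 1.2-fold) on the common peptides so the planted
event is splicing-like; lognormal measurement noise of CV 0.3;
per-sample loading offsets; and 10% missing-at-random masking. Peptide
log2 areas are a per-family level (N(17, 2.5²), about four orders of
magnitude of dynamic range) plus a per-peptide response offset
(N(0, 1.5²), mimicking ionization-efficiency spread). Where the
emulated study states a value (design sizes, counts, fold magnitudes)
the default *is* that value; the noise and missingness models and the
level/response spreads are this package's choices of what is realistic
for label-free DIA intensities, stated here once and not tuned.

Sequences are synthesized as concatenations of tryptic-friendly
peptides — no internal K/R, no leading proline, C-terminal K/R — so
that in-silico tryptic digestion of the emitted FASTA reconstructs
exactly the designed peptide-to-accession structure. The digest module
can therefore stand in for a search-engine distinct-peptide summary end
to end.

What the generator does **not** emulate: intensity-dependent
missingness (an option, but missing-at-random is the default so the
calibration tests stay sharp), correlated peptide noise within a
protein, batch effects, interference/chimeric signal, and
retention-time structure. Passing the validation suite therefore shows
the *inference* is correct under its stated model, not that real DIA
data meet that model.

## Numerical choices and known artifacts

* Zeros in area exports are non-detections and become missing on read
  (configurable); a present zero at the log2 step is an error, not a
  silent `-Inf`.
* Group keys are lexicographically sorted accession sets, so output is
  invariant to input row order.
* Both-groups-constant with unequal means is a degenerate-variance
  error in the scalar test; in the matrix path such rows get $p = 0$
  (the limit), and untestable rows propagate `NA`.
* Sum-over-observed aggregation has a known heavy-tail artifact: when a
  group's *dominant* peptide is masked missing in a few samples, the
  group's log2(sum) drops by the dominance gap in just those samples,
  inflating fold-change error far beyond the nominal noise level. This
  is a property of the summation rule (shared with the original
  workflow), not of the generator; validation checks that quantify
  generator fidelity therefore measure empirical fold changes at the
  peptide level (mean per-peptide cohort difference), where
  observed-value means are unaffected.
* Validation problem sizes: the suite runs the full 1400-family,
  23-sample configuration for recovery and calibration checks, with
  1000 label permutations; exhaustive-enumeration equivalence is
  checked on 3-vs-3 designs where all 20 splits can be listed.

## Limitations

The caller is deliberately rule-based — it codifies the
flat-common/shifted-specific contrast into explicit thresholds rather
than fitting an interaction model, so its sensitivity at small fold
changes is bounded by the `p_iso`/`fc_iso` pair. It assumes the
two-database protein grouping of the upstream search is adequately
approximated by suffix-based families; parsimony-style protein
inference, razor peptides and FDR-aware grouping are out of scope.
Only two-cohort designs are supported, and the pooled t-test inherits
the usual normality-on-log2 assumption.
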