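---
title: "Tag-based differential expression with supersage: models and methods"
author: "supersage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based differential expression with supersage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supersage)
```

## The experimental design this package analyses

SuperSAGE quantifies gene expression by counting 26-nt transcript
tags. Each tag begins at an NlaIII restriction site (CATG) and, in the
large majority of cases, derives from the 3'-most such site of a
transcript. Sequencing is performed on *ditags*: two tags ligated at
their non-anchor ends, so a clean ditag reads `CATG...CATG` over 52 nt
and contributes two tags, the second one reverse-complemented.

The design supported here is a 2x2 bulked-segregant contrast, as used
to profile cold acclimation in lentil: RNA from frost-tolerant and
frost-susceptible recombinant inbred lines is pooled into bulks, each
bulk is profiled with and without a cold-acclimation treatment, and
the four resulting libraries are labelled NAS, NAT, AS and AT
(non-acclimated/acclimated x susceptible/tolerant). The rationale of
bulking is that trait-linked expression differences accumulate in the
contrast between extreme pools while unrelated genes average out.
There is one deep library per condition and no replication; the
statistics below are exact count-based tests, not dispersion-modelling
GLMs, which are deliberately out of scope.

## Tag extraction

`extract_tags()` recovers tags from reads with two rules:

* **forward tag** -- the 26-nt window at the 5'-most CATG of the read,
  emitted if the window fits and contains no N;
* **reverse tag** -- the reverse complement of the final 26 nt,
  emitted if it begins with CATG (CATG is its own reverse complement),
  contains no N, and does not start at the forward anchor position
  (so a single-tag read yields its tag once).

Reads are assumed adapter-trimmed; quality strings are read and
ignored (no quality filter is part of the procedure). Tags containing
N are discarded rather than corrected, because identity counting
downstream assumes unambiguous bases. On clean, exact-length ditags
this recovers both generating tags for every read, a property the test
suite asserts on 10,000 simulated ditags. The exact parsing rules of
the original extraction software are unpublished; the
anchor-at-both-ends convention above is this package's own, and reads
that violate it are counted, not errors.

## Unitag counting and normalization

Identical tag sequences are aggregated into *unitags*
(`count_unitags()`). Because the four libraries differ in depth,
counts are normalized to tags per million:

$$\mathrm{TPM} = \frac{\text{count}}{\text{library total}} \times 10^6.$$

Library totals are the counts of **all** extracted tags, including
tags later removed by filters -- this is what makes a singleton in the
deepest library (5,357,611 tags) print as 0.19 per million and in the
NAS library (4,220,553 tags) as 0.24. TPM values carry full precision
internally; `round_half_up()` applies the half-up 2-decimal
presentation convention of the printed tables only at output.
`denormalize_tpm()` inverts the normalization, so raw counts can be
recovered from published per-million values (e.g. 1552.56 in AS maps
back to count 8318).

## The significance test

Counts of the same tag in two libraries of sizes $n_1$ and $n_2$ are
compared with the Audic-Claverie posterior

$$p(y \mid x) \;=\; \left(\frac{n_2}{n_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\bigl(1 + n_2/n_1\bigr)^{x+y+1}},$$

which is a negative-binomial distribution in $y$ with size $x+1$ and
success probability $n_1/(n_1+n_2)$. The one-sided p-value is the
smaller of the two tail sums at the observed $y$,
$\min\bigl(\sum_{k \le y} p(k|x), \sum_{k \ge y} p(k|x)\bigr)$, and
the two-sided p-value doubles it, capped at 1.

Numerical choices: terms are evaluated in log space via `lgamma`; the
infinite upper tail is summed directly past the distribution mode
until terms fall below $10^{-18}$ of the partial sum, so no
cancellation-prone complementation ($1 - \text{lower tail}$) is ever
performed. The test suite verifies the implementation against the
negative-binomial identity (`pnbinom`) and against an exact-rational
brute-force summation over the full $x, y \le 60$ grid to 12
significant digits, and checks that the pmf sums to 1 within
$10^{-10}$ for depth ratios 0.5-2.

One property worth stating explicitly: the construction conditions on
the first library, so swapping the two libraries does not give the
identical p-value. At equal depths the two orientations agree within a
factor of 2 (the observed point belongs to one tail but not to its
conjugate), and for depth ratios up to 3 they stay within an order of
magnitude; significance decisions at $P < 0.001$ coincide for all but
razor-edge cases. The package always tests in a fixed orientation
(pooled reference first), so results are deterministic and
reproducible.

## The filter cascade and the two searches

Candidate tags must first pass `prefilter_tags()`:

* coefficient of variation of the four TPMs **strictly above 1.5**
  (sample standard deviation, divisor $n-1 = 3$; a population-SD
  variant is available -- either choice lets single-library tags pass,
  since their CV is exactly 2 resp. $\sqrt 3$);
* summed raw count across the four libraries **of at least 50**
  (boundary inclusive), interpreting "under-represented" as overall
  scarcity; a per-library-maximum variant is switchable.

Two searches then run on the surviving tags:

1. **Exclusive sets** (`classify_exclusive()`): tags observed in
   exactly one library. Fold change is the observed TPM over the
   zero substitute (zeros are replaced by 0.5 TPM before any ratio is
   formed), and significance is the two-sided test of 0 counts in the
   three pooled absent libraries against the observed count -- one
   pooled contrast, matching the bulked design, rather than three
   pairwise tests (a pairwise mode was considered and rejected as
   redundant: with all three complements at zero the pooled contrast
   is the most powerful single test). Calls require FC $\ge 4.0$
   (boundary inclusive) and $P < 0.001$.

2. **Over-represented sets** (`classify_overrepresented()`): counts
   pooled on one axis -- treatment (A = AS+AT vs N = NAS+NAT) or
   genotype (T = NAT+AT vs S = NAS+AS) -- with pooled TPMs compared by
   the same fold-change rule and pooled counts by the same test.
   Calls require FC **strictly above** 4.0, exactly as the two
   searches are worded. A tag may be called on both axes and is then
   reported once per axis, mirroring dual labels such as "A18 = T25"
   in published tag lists.

`call_differential_tags()` runs both searches after the prefilter and
restricts the over-represented search to tags supported in more than
one library: an exclusive tag would otherwise always be duplicated
into two pooled sets, which would be inconsistent with summaries that
report exclusive and over-represented sets as disjoint groups of
comparable size. No multiple-testing correction is applied by the
procedure; a Benjamini-Hochberg column is attached to the output for
information only.

## Tag identification against a reference

`match_tag()` identifies the gene sequence a tag derives from using
two acceptance criteria: at least 22 of the 26 nt must match, and the
four anchor nucleotides must be present exactly. Matching is ungapped
(the homology criterion is positional), both strands are scanned, and
an N in the reference never counts as a match. The full window must
lie inside the reference; truncated end-of-sequence windows are
rejected. The anchor is required to match exactly and is counted
within the 26 -- the wording "at least 22 out of 26" leaves open
whether anchor mismatches beyond presence were tolerated; requiring
exactness is the stricter and simpler reading, and it makes the
anchored scan provably exhaustive: any accepted window must itself be
a CATG occurrence, so scanning only CATG positions (fast) equals the
full every-offset scan, a property the suite verifies against a
brute-force oracle. Coordinates are 0-based half-open on the forward
strand.

A tag whose best match (highest identity; ties broken by smaller
offset, sense before antisense) lies on the reverse strand is
classified antisense (`classify_strand()`); equal-identity best
matches on both strands are reported as `both`, never silently
resolved. `multi_site_report()` groups accepted matches by reference,
exposing genes identified by two or more tags from distinct NlaIII
sites.

## The synthetic-data generator

`simulate_experiment()` generates the structure the analysis assumes,
so every stage is testable without downloads:

* **references** -- random sequences, each with a guaranteed anchored
  26-nt window near the 3' end (the canonical tag); a configurable
  fraction carries a second upstream site (multi-tag genes); antisense
  tags are planted by inserting the reverse complement of a fresh tag
  into a host reference, emulating antisense transcription from the
  opposite strand.
* **truth table** -- planted categories with per-library expected
  rates (TPM): exclusive tags at 2000 TPM in one library and
  structurally zero elsewhere; over-represented tags at 3000/150 TPM
  in the two libraries of their favoured pooled pair and the pooled
  favoured rate divided by the effect fold (default 10) on the
  opposite side; null tags with log-normal rates (median 300 TPM)
  identical in all four libraries.
* **counts** -- per library, a single multinomial draw over all tags
  with the configured total, so library totals are exact (normalization
  uses exact totals) and zero-rate entries are structural zeros.
* **ditag reads** -- random tag pairs joined tail-to-tail with
  probability proportional to mean rate.

All generators are deterministic under the configuration seed
(derived sub-seeds per stage), and the defaults are the study
conditions: library totals are the published depths divided by 50
(about 60k-107k tags per library, keeping a full run under a minute),
25 planted tags per category and 2000 nulls.

The skewed major/minor pattern for over-represented tags is forced by
the filter cascade itself: a symmetric low/low/high/high pattern has
CV at most $2(h-l)/(\sqrt{3}(h+l)) < 2/\sqrt 3 \approx 1.15$ and so
can **never** pass the CV > 1.5 prefilter, however large its fold
change. Real over-represented tags that survive the published cascade
are necessarily dominated by one library; the generator plants that
shape deliberately. Under these defaults the cascade recovers about
97-100% of planted tags with a false-positive rate at or near zero
(`score_recovery()`), which the acceptance checks assert as >= 95%
and <= 1%.

What the generator does **not** emulate: sequencing errors (beyond
discarding N), 454 homopolymer artefacts, 3'-bias in tag formation
beyond the canonical-site convention, between-bulk biological
correlation structure, and reference incompleteness (truncated ESTs).
Passing tests therefore demonstrate the correctness of the
arithmetic, the filter semantics and the matching rules under the
stated sampling model -- not robustness to platform-specific noise.

## Degenerate inputs and tie-breaks

* All-zero count rows are rejected at table construction; a unitag
  must be observed at least once.
* An empty library is an error in `count_unitags()` (its total would
  be zero and TPM undefined).
* `fold_change(0, 0)` is 1 after substitution; a pooled comparison
  with exactly equal TPMs is never called.
* Fold change exactly 4.0 passes the exclusive search and fails the
  over-represented search, following the respective wordings "greater
  than or equal to" and "higher than".
* Match ordering is total (identity desc, offset asc, sense first),
  so outputs are byte-stable across runs.

## Problem sizes used in the checks

The bundled checks run at: the full published library depths for
normalization arithmetic (pure arithmetic, instantaneous); a
61 x 61 count grid for the exact-test oracle; 10,000 ditags for the
extraction round trip; 100 random planted references for matcher
oracle equivalence; and the default desk-scale simulation (~334k tags
over 2,204 tag species) for end-to-end recovery. These sizes were
chosen so the entire suite completes in well under a minute while
every planted-effect count still clears the abundance filter by a
comfortable margin.

## Worked example

```{r example, eval = FALSE}
library(supersage)

cfg <- sim_config(seed = 1)
sim <- simulate_experiment(cfg)
calls <- call_differential_tags(sim$counts)
matches <- match_tags(unique(calls$tag), sim$refs$sequences)
summarize_calls(calls, matches)
score_recovery(calls, sim$truth)

# or, end to end with all artefacts written to disk:
run_pipeline("run1", sim = cfg)
```

## Known limitations

* One library per condition: the exact test measures sampling noise
  only; biological variability between bulks is not modelled, so
  p-values overstate certainty about the population, as is inherent
  to the unreplicated design.
* The headline dataset-level counts of the original experiment
  (numbers of unitags, of filtered tags, of calls per set) depend on
  its raw libraries, which are not publicly deposited; the package
  reproduces the in-paper arithmetic exactly and the procedure's
  behaviour on synthetic data, not those dataset-level tallies.
* Ungapped matching cannot identify tags across indel polymorphisms,
  and references shorter than a full window at the matching position
  are not scored.
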