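---
title: "Profiling small non-coding RNAs from deep sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small non-coding RNAs from deep sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnatlas)
```

# The analysis

Deep sequencing of a size-selected small RNA library measures, in a single
run, mature microRNAs together with everything else in the 16--30 nt window:
length and end variants of each miRNA (isomiRs), the rare star strands from
the opposite precursor arm, fragments shed by snoRNAs and tRNAs, and reads
from unannotated loci that may be unrecognised miRNA genes. `srnatlas`
implements that analysis for a bovine retinal microvascular endothelial cell
library as a deterministic pipeline over explicit, testable stages:

1. **Read processing cascade** -- adapter clipping, a strict `> 15 nt`
   length filter, collapsing to unique tags with multiplicities, and removal
   of tags seen fewer than 3 times.
2. **Mapping** -- mismatch-bounded placement of every tag on the mature and
   precursor references and on the genome (both strands), keeping all
   placements in the best mismatch stratum.
3. **Annotation** -- single-class assignment of each tag by precedence over
   overlapping ncRNA annotations, and read-weighted library composition.
4. **isomiR and star analysis** -- signed 5'/3' offsets against the
   annotated mature, arm assignment, star fractions and positional variant
   (editing) profiles.
5. **Novel-miRNA discovery** -- expressed-interval calling from unannotated
   tags, hairpin folding of candidate frames, the structural/expression
   filter, and star-strand evidence tiers; ortholog detection against a
   foreign mature set and seed-family grouping.
6. **Host fragments** -- snoRNA-derived small RNAs and 5' tRNA fragments
   with positional arm calls and family-level aggregation for multi-copy
   tRNA genes.
7. **Quantification** -- reads-per-million-mapped expression tables and the
   `2^-dCt` relative-expression transform for qPCR comparisons.

A first-class synthetic-data generator emulates the statistical structure of
the real library, so every stage is verifiable against a known ground truth
without the original sequencing run.

# Read processing

Adapter matching is exact: the leftmost occurrence of either the full
adapter internally or an adapter prefix of at least `min_overlap = 6`
bases running to the read's 3' end. No mismatches are tolerated; with a
non-periodic adapter this makes the clipped length a deterministic function
of the insert, which is what lets the generator predict the cascade counts
exactly. Quality-based trimming is out of scope.

The boundary semantics follow the source conventions exactly: the length
filter keeps reads of *more than* 15 nt (a 15-mer is dropped), and the
abundance filter removes tags represented by *fewer than* 3 reads (a 3-read
tag survives). Both cutoffs are configurable; the stricter published
alternative (more than 10 reads) corresponds to `min_count = 11`.

# Mapping

Tags are placed by exact-match seeding with up to 2 substitutions
(`Biostrings` pattern matching does the scanning); indels are not modelled
because the downstream isomiR arithmetic is substitution/offset based. All
placements at a tag's minimum observed mismatch count are reported --
multi-locus tags such as multi-copy tRNA products keep all their loci. Tags
containing N are left unplaced. Correctness is certified in the test suite
by equivalence with an exhaustive sliding-window oracle written in plain R,
over a thousand random tag/reference pairs at every mismatch budget.

The default budget is 1 substitution for every target kind, including the
genome. A single genome-mapping pass serves both annotation and discovery;
sequencing-error variants of abundant tags that survive the abundance
filter then still map to their locus of origin instead of polluting the
unannotated set.

# The folding model

Candidate hairpins are folded with a built-in dynamic program so the
package is self-contained and its optimality is provable. The energy of a
structure is a sum over base pairs:

* a pair closing an empty interior (>= 3 unpaired bases) pays the
  hairpin-loop penalty;
* a pair stacked directly on another pair gains the mean of the two pair
  strengths -- GC 3.4, AU 2.2, GU 1.4 kcal/mol;
* a pair enclosing structured but non-stacked interior pays the
  internal-loop/branch penalty.

This is the entire model; `structure_energy()` evaluates it directly on any
explicit structure and is the definitional form. The dynamic program
(`fold_hairpin()`, in C++) minimises it exactly, which the tests verify by
exhaustive enumeration of all legal structures for sequences up to 25 nt.

The two penalties default to 6.5 kcal/mol each (`fold_params()`). They were
chosen by matching the model's minimum free energies against the
nearest-neighbor thermodynamic reference (ViennaRNA's RNAfold) on two
panels: random 70--110 nt sequences and canonical two-arm stem-loops. At
(6.5, 6.5) the mean MFE of random sequence agrees with the reference to
within 0.1 kcal/mol (about -18 kcal/mol) while stem-loops fold to -45 to
-60 kcal/mol, so the conventional -25 kcal/mol stability threshold keeps
its usual discriminating power. Softer penalties let random sequence reach
-25 far too often (78% of random windows at (4.5, 3.0) versus 16% under
the reference). The stated threshold "free energy of < 25 kcal/mol" is read
as a magnitude, i.e. MFE <= -25 kcal/mol.

# Novel-miRNA discovery

Unannotated tags are merged strand-specifically into expressed intervals;
the default merge gap of 15 nt is deliberately wider than a terminal loop,
so the mature and star products of one precursor coalesce into a single
locus instead of two half-loci. Around each interval the pipeline extracts
60 nt of flank, folds sliding frames of 70, 90 and 110 nt that contain the
dominant tag, and keeps the best frame -- preferring single-hairpin folds,
then lowest energy. Trying several frame lengths lets a genuine stem-loop
be judged on a window matching its own extent rather than being charged
for incidental structure in the surrounding sequence.

A candidate passes when *all* of the following hold: read support above
100; dominant tag length 21--23 nt; no overlap with annotated ncRNAs; MFE
at or below -25 kcal/mol; exactly one hairpin loop; and at least 75% of the
dominant tag's bases paired, with the tag wholly on one arm. The filter is
monotone -- weakening any threshold can only admit more candidates -- and
each criterion is reported separately so a failure is attributable.

Star-strand support upgrades a candidate from `structure_only` to
`star_supported`: reads whose 5' end falls, within +/-2 nt, at the position
the fold predicts for the star strand of a duplex with 2-nt 3' overhangs,
on the arm opposite the dominant tag.

Orthologs of foreign (e.g. human) matures are called for tags that match no
native mature: 5'-anchored comparison, at most 2 substitutions, none in the
seed (positions 2--8), length difference at most 2 nt. Seed families group
sequences sharing an identical 7-mer seed, named after the earliest known
member.

# Host-derived fragments

Fragments of snoRNAs and tRNAs are expressed in host coordinates with a
positional arm rule of this package's own design (the source material shows
arms graphically without a numeric rule): `five_prime` when the fragment
starts in the first quarter of the host, `three_prime` when it ends in the
last quarter, `internal` otherwise; full-length coverage is flagged. A tag
matching several copies of a multi-copy tRNA gene contributes its count
once to a family aggregate keyed by isotype/anticodon (e.g. `tRNA-Gly-GCC`),
matching how multi-copy families are reported in practice.

# Quantification

Expression is reported as reads per million mapped. The default denominator
is the total of miRNA-mapped reads: re-deriving the denominator from the
published table's own (reads, RPM) pairs -- every row constrains it to a
rounding interval, and the intervals intersect in a single value near
6.85 million -- shows that convention reproduces every printed RPM at one
decimal. `implied_denominator()` implements that interval argument and is
used by the desk checks. Percentages are reported rounded to whole numbers,
RPM to one decimal, as in the published table.

# The synthetic study

`default_manifest()` builds the study conditions; they are fixed design,
not tuning knobs:

* **25 known miRNAs** with relative abundances following the published
  expression table's strongly skewed profile (heaviest miRNA ~33.9% of
  miRNA-mapped reads; a 25th member aggregates the tail), one mature hosted
  by two precursors to exercise merged `a//b` naming.
* **isomiR distributions** per miRNA; the dominant miRNA's top isomiR is
  one base short at the 3' end (45% of its reads), the third miRNA's top
  isomiR is shifted at the 5' end -- the two signatures the real library
  shows most prominently.
* **star fractions**: 27/2,318,371 for the dominant miRNA (processing
  specificity at the limit of detection), 7.63% for the third, 1%
  elsewhere.
* **A-to-G editing** at 3% planted at position 12 of one mid-abundance
  miRNA.
* **a 5-member snoRNA cluster** (dominant member ~62% of snoRNA reads,
  products from both arms), **a 9-copy tRNA family** shedding 5' fragments
  of 28-30 nt, plus single rRNA/snRNA/miscRNA hosts.
* **3 novel hairpins** (~0.4% of reads each, with star reads), **5
  dinucleotide-shuffled decoys** embedded without hairpin context, and one
  locus matching a **foreign-only mature**.
* **7-nt GC-rich junk** (~18% of reads) reproducing the short-insert peak,
  and a per-base substitution error rate of 0.002 applied to inserts.

Hairpins are constructed as flank + mature + loop + star-arm + flank, the
star arm being the mature's reverse complement with three G-U wobbles at
internal positions. The wobbles matter twice: they mimic the imperfect
duplexes of natural precursors, and they put the two arms more than one
substitution apart so neither arm maps onto the reverse strand of the other
within the mismatch budget. Each hairpin is rejection-sampled until it
folds into a single stem-loop at or below -25 kcal/mol with the mature at
least 75% paired on one arm.

Reads are fixed at 36 nt before clipping (typical for the platform era),
with the adapter appended and A-padding past it for very short inserts.
Substitution errors are applied to the insert only; because the adapter
region is error-free and the adapter is non-periodic, the generator can
predict the full processing cascade -- raw count, reads over 15 nt, unique
sequences, tags at >= 3 reads -- by direct accounting of its own sampled
inserts, and the pipeline must reproduce those numbers *exactly*. That
exact-equality check substitutes for the real library's cascade, which
cannot be reproduced without the deposited data.

What the generator does **not** emulate: ligation bias (a known caveat of
real small RNA libraries), base-quality structure, indel errors, and
genomic repeat structure. Passing tests therefore demonstrate correctness
of the algorithms under the modelled sampling process, not robustness to
those real-data artefacts.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 30,000-50,000
reads for distributional checks and 200,000 reads for the parameter-recovery
study; discovery operating characteristics (sensitivity over planted
hairpins, pass rate over decoys) are measured across 20 independently
seeded studies at 50,000 reads. These sizes put binomial sampling error
well below the tolerances being asserted while keeping each run in seconds.

Ties are resolved deterministically throughout: lexicographic precursor
order in merged names, precedence then mismatch count then id in class
assignment, count then length then sequence for dominant fragments, and
nearest 5' boundary for arm membership. Degenerate inputs (empty libraries,
zero-read arms, unfoldable sequences) return empty results or errors as
documented per function, never silent defaults.

# Known limitations

* Alignment is substitution-only; isomiRs created by templated indels would
  be missed, as would non-templated additions beyond the mismatch budget
  (within the budget they surface as 3' mismatches, not a separate class).
* The folding model has no dangling ends, coaxial stacking, or
  temperature dependence; its energies are calibrated to, but not equal to,
  full nearest-neighbor values. An external thermodynamic folder can be
  swapped in through the `params`/fold interfaces without touching the
  candidate logic.
* Class assignment is single-label by precedence; a tag genuinely shared
  between two ncRNA classes contributes its reads to one class only, which
  is the partition convention the published composition figures imply.
* RPM normalisation ignores multi-mapping ambiguity beyond best-stratum
  reporting; each tag's count flows once to its assigned feature.
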