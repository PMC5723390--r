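---
title: "Methods: time-course small RNA analysis with submir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course small RNA analysis with submir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

submir implements the computational core of a time-course small RNA
sequencing study of a plant exposed to two contrasting hydrological
regimes. The design is eleven sequencing libraries: one untreated
control (`G0`), five libraries from drained ("upland") plants sampled
at 1, 3, 6, 12 and 120 h (`D1`-`D120`) and five from submerged ("pond")
plants at the same times (`W1`-`W120`). Each library is a pool of
biological replicates sequenced once, so there is no within-condition
replication; every inference rests on exact count statistics and on the
temporal structure of the design.

The pipeline answers four questions:

1. **Which known miRNAs are present?** Cleaned, collapsed reads are
   matched against a mature miRNA reference with bounded mismatches and
   gaps; each family is collapsed to its most expressed member and
   quantified.
2. **Which unexplained reads are novel miRNAs?** Candidate tags are
   placed on a transcriptome (the species has no genome assembly) and
   their surroundings evaluated against eight hairpin criteria.
3. **Which miRNAs respond to submergence, and when?** RPM-normalised
   profiles are compared between the pond and upland series per time
   point; fold-change and exact-test thresholds call responsiveness and
   a timing class (early / late / varied).
4. **What do they target?** Transcripts carrying complementary sites
   under plant target-scoring rules, restricted to differentially
   expressed transcripts and classified by inverse co-expression; qPCR
   (2^-ddCt) and 5' RLM-RACE summaries validate selected pairs.

## Read processing

`clean_reads()` trims an optional 3' adapter (first exact occurrence),
keeps reads of 18-30 nt (the gel size-selection window) and drops reads
with mean Phred quality below 20. The quality floor is a convention:
"low quality" is not defined more precisely by the upstream protocol,
and mean-Q20 is a common, easily-stated rule. `collapse_tags()` reduces
reads to unique sequence tags with per-library counts; all later stages
work on tags.

The count floor (`min_count_filter()`, 5 reads) removes sequencing
noise. The source description of the floor ("less than five counts in
each library") is ambiguous between a per-library and a global reading.
The default keeps a tag whose count reaches 5 in *at least one*
library: the floor is a noise gate, and removing a tag from individual
libraries would punch holes in time-course profiles. The stricter
per-library reading (`per_library = TRUE`) is available.

ncRNA annotation (`annotate_ncrna()`) is exact full-tag substring
matching against rRNA/tRNA/snRNA/snoRNA references with the fixed
precedence rRNA > tRNA > snRNA > snoRNA. Database alignment policies
differ between tools and versions; exact matching is reproducible and
sufficient for contaminant removal.

## Known miRNA identification

`match_known()` assigns a tag to a mature reference when an
*edit-optimal* global alignment (minimal substitutions + gap columns)
has at most 2 substitutions and 3 gap columns. The optimality
requirement matters: if mere existence of a bounded alignment counted,
any substitution could be laundered into a deletion/insertion pair and
a 3-mismatch tag would still pass. Requiring the bounds on the best
alignment mirrors how an aligner reports one alignment and the filter
is applied to it. Ties across references break to fewest edits, then
lexicographic reference id.

`build_temp_db()` keeps, per family, the member with the highest total
assigned count (ties to the smaller id), and `quantify_known()` counts
each tag toward at most one representative, gaplessly within 2
mismatches (the shorter sequence slid along the longer). Gapless
quantification is deliberate: at this stage the reference is the
already-matched family representative and indels would blur family
boundaries.

## Novel miRNA calling

A candidate tag (20-24 nt, unannotated, unassigned) must sit on the
transcriptome and fold into a miRNA-like hairpin. The eight acceptance
criteria, checked in order with the first violation reported, are:
mature length 20-24 nt; at most 20 loci on the reference; precursor
minimum free energy at most -18 kcal/mol; at most 300 nt between the
mature and star arms; at least 16 base pairs in the miRNA/miRNA*
duplex; largest duplex bulge at most 4 nt; duplex asymmetry at most
4 nt; and 20 nt of flanking sequence on both sides of the duplex.

Because no aligner-independent definition of "bulge" and "asymmetry"
is given upstream, submir defines them from the predicted structure:
the duplex is the set of base pairs between the mature arm and the
span of its partner positions (the star); a bulge is the longest run of
consecutive unpaired nucleotides on either strand of the duplex;
asymmetry is the absolute difference in unpaired nucleotides between
the two strands. The star arm receives the 2 nt 3' overhang of Dicer
processing.

Folding every candidate's wide neighbourhood is wasteful, so
`call_novel()` first runs a complementarity prescan: a banded dynamic
program searches the region within the allowed arm spacing for a
near-reverse-complement of the mature sequence. A duplex of 16+ base
pairs cannot exist without such a match, so tags with no hit are
rejected (reason `duplex_pairs`) without folding, and their precursor
free energy is reported as undefined. For tags with a hit, the implied
precursor (duplex plus flanks) is excised and folded; all duplex
statistics and the MFE criterion are evaluated on that folded
precursor. Precursors are folded in batches.

The default folding backend is ViennaRNA's `RNAfold`
(nearest-neighbour thermodynamics) when available on the `PATH`. A
bundled simplified folder (weighted Nussinov with a stacking-energy
readout: -2 kcal/mol per stacked GC-containing pair, -1 otherwise,
+3 per hairpin loop) serves as a dependency-free fallback and as a
structural screen in tests; it is not a thermodynamic model, and the
synthetic fixtures use long perfect stems precisely so that both
backends agree on accept/reject.

## Expression analysis

RPM is `count / library_clean_total * 1e6`; the denominator is the
clean-read total *before* the count floor, since the floor removes tags
from analysis, not reads from the library.

Fold changes follow two rules, applied in this order: if both RPM
values are below 1 the comparison is **excluded** (low expression); any
remaining zero is **revised** to 0.01 before the log2 ratio. Checking
exclusion first is the only order in which both rules can ever fire.

Significance between two libraries uses the exact posterior tail of
one count given the other under a flat prior on the underlying Poisson
rate (the classic single-library count test of early sequencing-census pipelines).
The directed two-sided tail is not exactly symmetric under exchanging
the libraries, so the reported p is the mean of the two directed
values, which restores exact symmetry. No multiple-testing correction
is applied, matching the upstream convention; `p.adjust` can be applied
to the tidy output if desired.

A miRNA is **submergence-responsive** when at one or more time points
|log2 FC(W_t / D_t)| >= 1 with p < 0.05. miRNAs expressed only in the
upland group are exempted from the p requirement (their pond counts are
structural zeros); this reads the upstream exemption as relaxing the
test rather than removing those miRNAs from consideration, and the
choice is switchable by passing occupancy = NULL. Timing is `early`
when every qualifying time point is in 1-12 h, `late` when all are at
120 h, `varied` otherwise. Upland- and pond-treated series are called
**consistent** when Pearson r > 0.9 with two-sided t-test p < 0.05 on
n - 2 = 3 degrees of freedom.

## Target analysis

Complementarity scoring uses the plant conventions: per column, match
0, G:U wobble 0.5, mismatch 1.0, indel 2.0, all doubled at miRNA
positions 2-13, with a total penalty cutoff of 4.0 (`allen` rule set).
The `schwab` rule set additionally rejects any site with a mismatch at
positions 10-11. The published pipelines pool two prediction tools;
submir models this as the union of the two rule sets over one scoring
engine, which reproduces the pool semantics without external services.
`scan_targets()` scores *every* transcript window within +-3 nt of the
miRNA length (banded DP in C++) and is tested against an exhaustive
per-window oracle.

Co-expression verdicts: a pair is `inverse` when Pearson r <= -0.5
*and* the fold-change signs oppose at every time point where the miRNA
qualifies as responsive; `positive` when r >= 0.5; otherwise
`uncorrelated`. The r threshold and the sign condition are package
choices (the upstream description is qualitative); both are arguments.

Cleavage summaries convert RACE clone 5' ends to miRNA coordinates:
the miRNA 5' end pairs opposite the site's 3' end, and a cleavage at
the phosphate between miRNA positions 10 and 11 is reported as
position 10, the canonical slicing register.

## The synthetic experiment

`simulation_config()` fixes the study conditions: 40 known + 20 novel
miRNAs, a 200-transcript transcriptome hosting the planted precursors
and target sites, 1e6 reads per library, negative-binomial noise with
dispersion 0.1, and 4-fold effects. Dynamics classes are assigned
round-robin per family unit (members of a known family share their
class, so the family representative that quantification reports has a
well-defined planted truth): `constant`, `upland_specific`,
`pond_specific`, `early_up`, `early_down` (change at 1-12 h only),
`late` (120 h only), `varied` (opposite changes at 1 h and 120 h) and
`consistent` (the same response in both treatment series).

Two modelling choices deserve emphasis:

* **Dispersion parameterisation.** Counts are drawn with variance
  `mu * (1 + dispersion)`, i.e. dispersion is the relative excess over
  Poisson sampling noise. Because each library is a sequencing of one
  pooled RNA sample, the relevant per-library noise is technical; a
  between-biological-replicate parameterisation (variance
  `mu + dispersion * mu^2`) would contradict the pooled design and
  would make the single-library fold-change rule unusable for any
  method.
* **Degradation background.** Real libraries contain a long tail of
  degradation fragments, almost all below the count floor. The
  generator emulates this with two components: recurrent transcriptome
  fragments drawn from a large uniform window pool (kept at low mean so
  only a bounded number of fragments pass the floor — these exercise
  the novel-calling rejection path), and a diverse background of
  effectively unique reads that fills each library to exactly the
  configured depth. Baseline miRNA abundances are log-normal, bounded
  away from the RPM exclusion floor, and rescaled so miRNA reads take
  the configured fraction of each library.

The aggregate read length histogram peaks at 24 nt with a secondary
mode at 21 nt, the canonical plant small RNA profile. Planted hairpins
are perfect stems with short loops so that acceptance does not depend
on folding-backend details; real precursors have bulged, imperfect
stems, so passing the recovery tests demonstrates correct plumbing and
thresholds, not sensitivity to marginal hairpins. Similarly, planted
target sites are exact reverse complements; recovery does not probe
the scoring scheme's behaviour on borderline sites (the oracle
equivalence tests do).

Problem sizes in the test-suite and acceptance runs (depth 1e6, 60
miRNAs, 200 transcripts) were chosen as the smallest configuration at
which all planted effects are comfortably detectable by the published
thresholds; determinism is guaranteed by deriving every random draw
from the configured seed.

## Known limitations

* Exact-substring ncRNA annotation and exact tag placement on the
  transcriptome cannot model sequencing errors in contaminant or
  precursor reads; real pipelines use mismatch-tolerant aligners here.
* The novel-calling prescan is a necessary-condition filter under the
  duplex criteria; a hypothetical precursor whose star pairs the mature
  only through many G:U columns *and* long bulges beyond the prescan
  band would be missed. Such structures would fail the bulge/asymmetry
  criteria anyway.
* `scan_targets()` evaluates miRNA-length windows with up to 3 nt of
  indel slack; target modes other than cleavage-style complementarity
  (e.g. translational inhibition with central bulges) are out of scope.
* One miRNA unit per family: isomiR resolution and family assignment of
  novel candidates are not attempted.
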