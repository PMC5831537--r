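---
title: "Predicting phage hosts from genomic signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage hosts from genomic signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(phagehost)
library(dplyr)
```

A phage genome assembled from a metagenome is, by itself, a string of
nucleotides: nothing in the assembly says which bacterium it infects.
Coevolution, however, leaves recoverable traces in both genomes. This
package computes the classical sequence-based host-prediction signals,
ranks candidate hosts per signal, scores predictions at six taxonomic
ranks, and ships a synthetic benchmark generator with planted ground truth
so every signal can be exercised end to end without downloading reference
data. This vignette explains each method, its tunable parameters, and the
design decisions taken where the choices were genuinely open.

## Signals

### Composition profiles

Phages tend to ameliorate their nucleotide composition towards that of
their host (restriction avoidance, nucleotide pools, tRNA availability).
`canonical_kmer_profile()` counts every window of length $k$ into the
canonical bin shared by a word and its reverse complement, making profiles
strand-invariant. For odd $k$ there are $4^k/2$ bins; for even $k$,
$2^k + (4^k - 2^k)/2$, because the $2^k$ palindromic words are their own
reverse complement (k = 3 gives 32 bins, k = 8 gives 32 896). Two special
cases: `gc_profile()` (k = 1, two bins) and `codon_profile()` (in-frame
k = 3 over coding regions, 64 bins — stop codons are included, since
excluding them would discard the stop-usage information and the choice is
otherwise immaterial to distances). Profiles are relative frequencies, so
genome length cancels; windows containing `N` are skipped rather than
fractionally distributed. `composition_scores()` compares profiles by
Euclidean distance by default (the variant with the strongest signal on
real benchmarks); Manhattan, cosine and Pearson variants are selectable.
Codon profiles use annotated CDS when present and internally called ORFs
otherwise, recording which in the `source` attribute; annotations can come
from GenBank-flavored records via `read_genbank()`, which also captures
the `/host=` qualifier used as benchmark truth.

### Exact matches

Prophage integration, spacer acquisition and recent gene transfer all
leave identical stretches in the two genomes. `exact_match_scores()`
implements a two-step search: all shared 15-mers are found by hashing,
then seeds on the same alignment diagonal whose start positions differ by
at most the seed length are merged. A mismatch on a diagonal forces a gap
of at least seed length + 1 between seed starts, so the merged runs are
*exactly* the maximal identical stretches of length ≥ 15 — no base-wise
extension step is needed, and the tests verify equivalence with an
independent longest-common-substring oracle. The phage forward strand is
searched against both host strands by default (`both_strands = FALSE`
restricts to forward-forward). `N` matches nothing. A score of 0 means no
15-mer is shared; the benchmark treats that as no evidence.

### CRISPR spacers

`detect_crispr_arrays()` is a deliberately simple repeat-spacer finder:
exact 21-mer words recurring at array-like spacings (repeat 21–48 bp,
spacer 18–72 bp, at least 3 repeat copies) are chained, repeat boundaries
grow while ≥ 90% of copies agree with the consensus, and near-identical
"spacers" are rejected as tandem repeats. It recovers planted arrays
verbatim and reports no arrays on i.i.d. random sequence at the default
thresholds; it is not a replacement for a dedicated finder on real genomes
(degenerate repeats without a conserved 21-mer core across three copies
will be missed), and `read_spacer_fasta()` lets externally produced
spacers bypass detection entirely.

`match_spacers()` aligns each spacer (both orientations) to the phage with
the short-query scoring regime — match +1, mismatch −1, gap open 10, gap
extend 2 — using a pattern-global alignment, so the whole spacer is placed
against its best-matching phage substring. This makes full coverage
structural rather than a post-hoc filter; mismatches count substitutions
and gaps are reported separately. Because alignment-significance estimates
depend on database size, qualification uses a deterministic floor instead:
a hit qualifies at budget $m$ if it has ≤ $m$ substitutions and raw score
≥ length − 2·m − (gap penalties incurred). Two scores are derived:
`crispr_best_hit_scores()` (best percent identity among qualifying hits;
default budget 2, sweepable to 13, the degeneracy still recognised by
CRISPR priming) and `crispr_spacer_count_scores()` (number of distinct
matching spacers; identical spacers within a host count once, and
`min_spacers = 2` gives the more specific multi-spacer variant). Hosts
without arrays are no-evidence, never zero.

### Homology

`homology_scores()` summarises local similarity in two modes, matching
the two axes a practitioner would get from nucleotide and translated
searches: the **nucleotide** score is the total phage length covered by
qualifying local alignments (overlaps collapsed, so splitting an alignment
into overlapping pieces changes nothing), and the **translated** score is
the number of phage ORFs whose best protein hit reaches a threshold. The
internal aligner is a seeded ungapped X-drop extender (11-mer seeds,
match +1/mismatch −2, X-drop 20, score floor 28 for nucleotides; 4-mer
amino-acid seeds, BLOSUM62, X-drop 20, floor 50 for proteins). It is not a
full aligner — no gapped DP, no E-values — and the floors are documented
as tunable. `read_tabular_hits()` accepts the standard 12-column tabular
alignment format so externally computed hits feed the identical summaries.

### Abundance co-occurrence

A phage can only thrive where its host lives, so their abundances across
samples co-vary. `pair_correlation()` applies the two printed rules in
sequence: samples where either member is absent (abundance exactly 0; no
detection threshold) are excluded pairwise, and a Pearson correlation is
only reported when **more than six** samples survive — read as ≥ 7 after
the exclusion, the stricter of the two possible orderings. Correlations
are computed on raw abundances by default (`log_transform = TRUE` is
available but off). Insufficient overlap and constant profiles yield
no-evidence (`NA`), distinct from a low correlation.

## Ranking, rank-level scoring, ROC, baseline

`top_hosts()` returns *all* hosts tied at the row optimum under the
table's recorded orientation; a prediction is correct when the true host
is among them. Because an all-tied row would be trivially "correct",
`accuracy_at_rank()` always reports the mean prediction-set size next to
the accuracy, and the benchmark converts match-length/alignment scores of
0 to no-evidence, so evidence-free phages predict nothing and count
incorrect. Accuracy is reported at species, genus, family, order, class
and phylum (case-insensitive name equality against a flat lineage table;
no synonym resolution — fixtures control their own names, and on
tree-consistent lineages accuracy is non-decreasing with rank by
construction).

`roc_curve()` sweeps the threshold from the optimal to the worst observed
score; tied scores enter together, the curve runs from (0, 0) to (1, 1),
and the area is computed by the trapezoid rule. No-evidence pairs are
excluded from the sweep rather than imputed as worst scores (an imputing
variant is a one-line `tidyr::replace_na` away for sensitivity analysis).
`random_baseline()` draws between one and four uniformly random hosts per
phage — the typical size of a real prediction set — and has closed-form
expectation $\bar{k}/H$; with 153 hosts that is 2.5/153 ≈ 1.6%,
inside the 1–3% band expected of random assignment.

## The synthetic benchmark

`build_benchmark()` generates a self-contained benchmark with known truth.
What it emulates, and what it does not:

* **Hosts** are first-order Markov chains with host-specific transition
  matrices (`bias_strength` blends a random matrix with the uniform one).
  This gives each host a learnable dinucleotide signature, like real
  genera differ in composition, but no genes, GC skew or repeats.
* **Mechanisms.** Each host group carries one planted mechanism, two
  phages per host: `prophage` copies the full phage into the host (the
  long-exact-match case); `shared_gene` plants a codon-structured 900 bp
  gene in the host and a 10%-diverged copy in the phage; `spacer_donor`
  inserts a CRISPR array (28 bp repeat × 4 copies) whose three 32 bp
  spacers are phage substrings at 0, 1 and 2 substitutions — so the
  budget sweep has real structure; `composition_only` samples the phage
  from the host's Markov model blended by `amelioration`;
  `abundance_only` leaves sequences unrelated. 30% of non-donor hosts get
  decoy arrays with random spacers: at permissive mismatch budgets
  (towards 13) decoys begin to qualify by chance, reproducing the
  predictions-up / precision-down trade-off, while at budget ≤ 2 they are
  inert.
* **Abundances** are log-normal with Bernoulli presence (0.6), phage
  dropout 0.1, and log-scale coupling to the true host: 0.9 for
  abundance-only phages, 0.3 background for the rest — phages co-occur
  with their hosts regardless of mechanism, but noisily, which keeps
  co-occurrence a genuinely weak overall signal as it is on real
  benchmarks.
* **Taxonomy** is a balanced tree (2 species/genus, 2 genera/family, ...),
  so rank-nesting invariants are exactly testable.

Scale defaults — 30 hosts × 50 kb, 60 phages × 20 kb, 40 samples — are
the package's chosen benchmark size: large enough that random 15-mer
collisions are expected and composition estimates are stable, small
enough that the full run completes in minutes on one CPU. Everything is
deterministic under `config$seed` (bundles rebuild byte-identically).

What passing this benchmark does *not* show: real genomes are not Markov
chains, real CRISPR repeats are degenerate, real homology spans deep time
with rearrangements, and real metagenome profiles have compositional and
batch structure. The benchmark validates the *machinery* — that each
signal recovers the mechanism it was designed for and that the evaluation
logic is sound — not field performance.

## Numerical choices and degenerate inputs

* Canonical representative: lexicographic minimum of word and reverse
  complement (any consistent choice works; this one is conventional).
* Coordinates are 0-based half-open everywhere; reverse-strand features
  are reported by their forward-strand footprint.
* Lowercase input is uppercased, `U` → `T`; anything outside
  `{A,C,G,T,N}` is an error, and all-`N` inputs error rather than return
  `NaN` profiles.
* ORF calling: starts ATG/GTG/TTG, standard stops, first in-frame stop,
  default minimum 60 codons — common prokaryotic conventions, used only
  when annotations are absent (the `source` attribute records which).
* Ties: score ties are kept everywhere (prediction sets, ROC groups);
  nothing depends on sort stability.
* Profile normalisation is checked to 1e-9; Pearson on constant vectors
  returns no-evidence rather than `NaN`.

## A small end-to-end run

```{r, eval = FALSE}
bench <- build_benchmark(fixture_config(seed = 1))
res <- run_benchmark(bench)
glance(res)      # species-level accuracy, AUC and set size per signal
tidy(res)        # full signal x rank table
autoplot(res)    # Fig-style accuracy bars by rank
```

On this benchmark the homology-driven signals (exact match, nucleotide
homology) recover the most hosts overall — they also see the planted
spacers and prophages — while composition and abundance recover
essentially only their own subsets, mirroring the ordering reported for
real benchmark collections. The acceptance script
(`scripts/acceptance.R`) recomputes these quantities from scratch at a
given seed.

## Known limitations

* The array finder requires an exact 21-mer conserved across three repeat
  copies; heavily degenerate arrays need an external spacer FASTA.
* The internal aligners are ungapped; indel-rich homology is
  under-counted in nucleotide mode (the tabular adapter exists for that).
* Name-based lineage matching cannot resolve synonyms or strain-level
  ranks.
* Signals are evaluated separately; no ensemble combination is attempted.
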