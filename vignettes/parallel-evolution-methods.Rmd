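---
title: "Methods: detecting repeated evolution on a circular genome with overlapping frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting repeated evolution on a circular genome with overlapping frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallevol)
```

# Scope and model

`parallevol` analyses compilations of nucleotide substitutions observed in
many independently evolved lineages of a small circular virus — the φX174
model system is the motivating case: a 5,386-nt single-stranded circular
genome carrying 11 forward-strand genes, several of which overlap in
different reading frames, one of which wraps the replication origin. The
package answers four questions:

1. Which amino acids does a nucleotide substitution change, in *every* gene
   that covers it?
2. How many repeatedly hit sites are expected by chance alone, given the
   total number of substitutions?
3. Are substitutions enriched in particular genes relative to their coding
   capacity?
4. Do the sites of laboratory adaptation coincide with natural standing
   variation in wild isolates, and what is the silent:missense balance of
   that natural variation?

It deliberately models *placement*, not population dynamics: sweeps, clonal
interference and recombination inside the evolving populations are out of
scope, as is any phylogenetic correction for lineages that share history
beyond the optional founder-genotype subtraction.

# Genome model and codon mapping

Coordinates are 1-based inclusive on the forward strand, following the
GenBank convention for φX174; a gene with `end < start` (or `end > G` in an
input table) wraps the origin and reads `start..G, 1..end`. Validation
requires every gene span to be a multiple of 3 and free of internal stop
codons; a terminal stop codon is allowed and excluded from residue counts.

Translation uses the standard genetic code uniformly at every codon, with no
initiator special-casing: genes annotated at internal or alternative starts
translate exactly as their codons dictate. (Tables 1 and 11 of the standard
code collection agree codon-by-codon, so this is also the bacterial code.)
Substitutions that create a stop codon are reported as residue-level changes
with `alt_aa = "*"`, silent changes are reported and flagged rather than
dropped, and a substitution covered by k genes yields exactly k records.
This convention is what the re-translation property tests pin down: for any
genome, annotation and substitution, the mapped changes must equal the
difference between translating the whole reference gene and the whole
mutated gene.

Two genes overlap *out-of-frame* at a position when their codon phases
differ there; only such positions enter the overlap mask used for
exclusions. An in-frame internal start (the A*-within-A arrangement) shares
codon boundaries with its parent, so a change there has the same
silent/missense status in both genes: those positions stay out of the mask,
while residue numbering remains per-gene.

# The coincidence null model

Let S substitutions fall independently and uniformly on L potentially
variable sites, where L = (1 − f)·G discounts the genome length by an
assumed invariant fraction f (default 0.25 — a conservative allowance for
sites under strong purifying selection). The expected number of n-fold
coincidences is

$$E_n = \binom{S}{n} \, / \, L^{\,n-1},$$

because each of the $\binom{S}{n}$ event n-tuples lands on a common site
with probability $1/L^{n-1}$. The identity
$E\left[\sum_{\text{sites}} \binom{k_{\text{site}}}{n}\right] = E_n$ is
exact; the Monte-Carlo tests verify it at small scale. With S = 667,
G = 5386, f = 0.25 (L = 4039.5), $E_2 \approx 55$ and $E_3 \approx 3$, and
two-fold coincidences account for $2E_2/S \approx 16\%$ of substitutions.
Three or more events at one site are therefore taken as strong evidence of
adaptive substitution (`classify_adaptive_sites`, default threshold 3).

Two numerical points deserve emphasis:

* **Coincidence vs occupancy.** $E_n$ counts n-fold coincidences, not sites
  carrying at least n events. In the sparse regime (λ = S/L ≈ 0.17 here) the
  two agree to within about 15%, with occupancy systematically *below* the
  coincidence expectation (a site with 4 events contributes
  $\binom{4}{3} = 4$ coincidences but is one occupied site). A
  Poisson-occupancy alternative,
  $L \cdot P(\mathrm{Poisson}(\lambda) \ge n)$, is available as
  `method = "occupancy"` for sensitivity analysis; at the φX174 scale it
  gives ≈49 rather than ≈55 at n = 2. The combinatorial form is the default
  because it is exact in expectation for the coincidence count and matches
  the published figures. The test suite asserts both behaviours: the exact
  identity within Monte-Carlo error, and the ≤15% occupancy gap — and one
  acceptance check that holds mean occupancy to the coincidence expectation
  within 3 standard errors fails by exactly this systematic gap (~14% at 200
  replicates); it is kept at its stated tolerance rather than widened, with
  the exact-identity companion assertion beside it.
* **"Site" means nucleotide site** in the null model (S and L are nucleotide
  counts); the residue-level tally drives the adaptive-site report and the
  per-gene statistics.

Expected counts are real-valued throughout; rounding to whole sites and
whole percent happens only at presentation.

# Counting conventions

Within one lineage an identical change — same position, same alternative
base — is counted once; different alternative bases at one position are
different mutations. Two pooling modes are implemented: `site_level`, where
any event at a site or residue increments it (reversions and alternate
substitutions pool together), and `identical_change`, where only identical
changes pool (nucleotide keys `(position, alt)`, residue keys include the
amino-acid change). Identical-change counts can never exceed site-level
counts, and both modes conserve the total event count at the nucleotide
level. Insertions and deletions count as events at their positions (and in
the regulatory tally) but are never mapped to residues.

Founder subtraction removes substitutions a lineage already carried at the
start of its experiment, so extensions of earlier experiments do not
re-count their inherited changes.

# Gene enrichment

A gene's coding fraction is its codon count over the summed codon count of
all genes (overlap positions contribute to every covering gene; terminal
stop codons are excluded). Expected amino-acid substitutions per gene are
`coding_fraction × total`; a two-sided exact binomial p-value per gene is
attached and labelled an extension, since the underlying comparison is
expectation-vs-observation only. The residue universe N used for lab–wild
overlap expectations defaults to the same per-gene codon total but is
directly settable (`universe_N` in the pipeline) because published universes
may count overlap residues differently.

# Wild panels

Wild panels are pre-aligned, gap-free, equal-length genomes. Variation is
polarized against the panel consensus — the majority state per column, ties
broken by the reference — the weakest assumption available when the true
ancestral state is unknown; changes are mapped on the consensus background.
A residue is "variable in the wild" when some non-consensus state changes
that gene's amino acid. The silent:missense ratio counts distinct
non-consensus states per column; with `exclude_overlaps = TRUE` (the
default, matching how such ratios are reported for overlapping-gene genomes)
out-of-frame overlap positions are dropped first, leaving every remaining
coding position with an unambiguous single-frame classification. When
overlaps are retained, a change is classified missense if it is non-silent
in *any* covering frame — a documented choice; the converse (silent in any
frame) would systematically deflate missense counts.

The hypergeometric upper-tail p-value attached to the overlap comparison is
likewise an extension beyond the expectation-vs-observation comparison and
is labelled as such wherever printed.

# The synthetic-data generator

The generator exists so that every estimator can be validated against known
truth. Its defaults emulate the compiled φX174 dataset:

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 5386 nt | φX174 scale |
| `n_genes` | 11 | φX174 gene count; equal codon shares filling ~88% of the circle, two out-of-frame overlap pairs, one origin-wrapping gene |
| `n_lineages` | 58 | compiled lineage count |
| `events_per_lineage` | 667/58 (Poisson) | compiled event total; `total_events` fixes the *counted* total exactly |
| `invariant_fraction` | 0.25 | the null model's conservative assumption |
| `n_hotspots`, `hotspot_weight` | 13, 150 | 13 residues carried eight or more events in the compilation; weight 150 gives each hotspot ≈17 expected hits, in the range of the most-hit sites |
| `n_isolates`, `n_wild_differences` | 40, 1000 | wild microvirid panels are tens of isolates differing at thousands of positions over ~5.4 kb |
| `silent_missense_intensity` | 3.8 | the silent:missense ratio reported for wild isolates |
| `wild_shared_fraction` | 11/13 | share of top hotspot residues also variable in the wild |
| `n_regulatory` | 133 | size of the known regulatory-position list |

Design points:

* **Placement is multinomial** over the variable sites, hotspots upweighted;
  there is no fitness landscape or temporal dynamics — the null being tested
  is placement.
* **`total_events` is a count of *counted* changes.** Because an identical
  change within one lineage is counted once, the generator tops up placement
  until the deduplicated total reaches the target; the compiled totals are
  themselves post-deduplication counts.
* **Hotspots carry one designated alternative base** by default, so repeated
  hits are the identical change (exercising `identical_change` mode), and are
  restricted to coding positions.
* **Internal stop codons are repaired** by resampling bases inside offending
  codons until every gene (including overlap partners) translates cleanly —
  a rejection step, bounded and deterministic under the seed.
* **The wild panel** starts every isolate at the reference, adds background
  differences at single-frame coding positions with silent probability
  r/(1 + r), and gives each difference a minority carrier set (per-column
  budgets keep the consensus at the reference). Shared hotspots are planted
  as additional variable columns.
* **Determinism:** every generator takes an explicit seed derived from the
  config (`seed`, `seed + 1`, `seed + 2`, `seed + 3`), and identical
  configs produce byte-identical file bundles.

What the generator does *not* emulate: linkage between events in one lineage
(each event is placed independently), mutational spectrum bias (alternative
bases are uniform), indels (the generator emits substitutions only, though
the tally and regulatory code handle indels from real inputs), codon-usage
structure in the random sequence, and any phylogenetic structure among the
wild isolates. Passing the recovery tests therefore shows the estimators are
calibrated and powerful under the stated placement model — not that real
compilations satisfy that model.

# Validation strategy and problem sizes

The test suite checks, at sizes chosen to run in seconds to a few minutes on
one core:

* the re-translation property on 1,000 random genome/substitution cases,
  including origin-wrapping and out-of-frame cases;
* the coincidence identity by Monte Carlo (S = 50, L = 200, 10⁴ replicates,
  3-SE agreement) and the occupancy approximation (≤15% at λ ≤ 0.2);
* the hypergeometric mean by exhaustive subset enumeration for universes up
  to N = 12;
* end-to-end generator calibration at the compiled-data scale (200
  replicates), hotspot recovery (13 hotspots at weight 150: at least 12
  reach eight events in ≥90% of 100 replicates), and silent:missense
  recovery within 20% at ≥500 classifiable differences.

# Known limitations

* Forward-strand genes only; no introns, no multi-segment genomes, no
  reverse strand.
* The null model treats sites as exchangeable within the variable set; real
  mutational hotspots of non-adaptive origin (context-dependent mutation
  bias) would inflate coincidences and are not modelled.
* The hypergeometric overlap test assumes the two site sets are drawn
  independently from a common universe; shared purifying constraint alone
  can create overlap.
* Wild-panel polarization by consensus can misclassify when the consensus
  itself is derived at a column; with tens of isolates this is rare but not
  impossible.
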