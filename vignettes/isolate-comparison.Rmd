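---
title: "Comparing closely related virus isolates: selection scans, deletion mapping and polymorphism curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing closely related virus isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virocomp)
```

## The problem

When two isolates of a large DNA virus — here modelled on
nucleopolyhedrovirus (baculovirus) genomes of 100–140 kb — are deep
sequenced against a common annotated reference, the biologically
interesting questions reduce to a small set of comparative quantities:
which fixed substitutions are shared between isolates and which are
unique; whether the fixed nonsynonymous changes are more or fewer than
neutral expectation (dN/dS); how fast intergenic sequence evolves
relative to the synonymous baseline (dI/dS); where large (>100 bp)
deletions lie and exactly which nucleotides are missing; and how much
genuine within-isolate polymorphism remains once read-mapping
artifacts are removed. `virocomp` implements that pipeline end to end,
plus a seeded synthetic-data generator so every stage can be validated
against a known ground truth without any sequencing data.

## The counting dN/dS model

The estimator is a counting method in the Nei–Gojobori tradition, with
transition:transversion weighting of the *possible* (expected) sites.
For every sense codon the nine single-nucleotide changes are
enumerated; a change is weighted $\kappa$ if it is a transition
(A$\leftrightarrow$G, C$\leftrightarrow$T) and 1 if a transversion,
and classified synonymous or nonsynonymous by comparing translations
under the standard genetic code. Under the default per-position
normalisation the three weights at each codon position are divided by
$\kappa + 2$, so each position contributes exactly one site and
$s + n = 3$ per codon:

```{r}
codon_site_counts("TTT", weight_scheme(kappa = 3))
```

Summing over the codon usage of a gene (or of all annotated ORFs)
gives the possible synonymous ($S$) and nonsynonymous ($N$) site
totals; every position outside all ORFs contributes one possible
intergenic site ($I$; the per-position weighting cancels there because
each base admits one transition and two transversions). With observed
fixed substitution counts $n, s, i$ the rates are $dN = n/N$,
$dS = s/S$, $dI = i/I$ and the reported ratios are $dN/dS$ and
$dI/dS$. Values below 1 indicate purifying selection, above 1
directional selection.

Because the mutational bias of these viruses is unknown, the scan is
run at assumed transition:transversion ratios (TTR) of 1, 3 and 5 and
all three are reported. Synonymous changes are transition-enriched
under the standard code, so raising the assumed TTR raises the
possible synonymous share and with it the estimated dN/dS — the
package exposes this as a monotonicity property and tests it.

Choices the model had to make where the method description is silent:

* **Changes that create a stop codon** count as nonsynonymous by
  default (they certainly alter the protein); `weight_scheme(...,
  stop_changes = "exclude")` removes them from both classes instead.
* **Terminal stop codons** are excluded from codon tallies; internal
  stops (which should not occur in curated annotations) are skipped
  with a warning.
* **Overlapping ORFs**: genome-wide totals count every coding position
  once, attributed to the longest ORF containing it
  (`overlap = "longest"`); per-gene tallies always use the gene's full
  CDS so gene values are self-contained. The alternative
  (`overlap = "per_orf"`, overlaps counted twice) is one argument
  away; the two differ only when annotations overlap.
* **Normalisation cancels**: dN/dS and dI/dS are identical under
  per-position and raw weighting, which the tests assert to machine
  precision.

### Genes without synonymous substitutions

A short gene often shows nonsynonymous changes but no synonymous one,
leaving dS undefined. `gene_dnds()` then approximates the expected
synonymous count from the genome-wide occurrence of synonymous
substitutions scaled to the gene — by the gene's share of possible
synonymous sites (default), or literally by its share of coding length
(`fallback = "length"`). The two differ only through codon usage; the
site-proportional form is the default because it is the one consistent
with the weighting model. Results carry an `s_approximated` flag, and
genes with no observed substitutions at all are reported as *no data*
rather than 0. Per-gene tables flag genes whose dN/dS exceeds 0.95 at
any assumed TTR.

## Variant classification and partitioning

Variants (SNPs, MNPs, short indels < 100 bp) are classified
strand-aware on the circular genome: the affected codon is rebuilt in
the coding frame (minus-strand ORFs complement the alleles), mutated,
and retranslated. An MNP is classified jointly per affected codon —
the reference codon against the fully mutated codon, one substitution
event per codon — with `decompose_mnp = TRUE` available to count
constituent SNPs instead. Classification is validated against a
brute-force oracle that rebuilds the whole mutated genome,
re-translates every ORF and diffs the proteomes. Short indels never
enter the dN/dS numerators; variants in masked intervals (e.g. the
flanks of a large deletion, where mapping artifacts concentrate) can
be dropped with `mask_regions`. Fixed variant sets from two isolates
are partitioned into shared and unique sets keyed on exact
(position, ref, alt) identity; the three sets are asserted to be a
disjoint cover of the input union on every call.

## Large-deletion mapping

Two independent evidence routes mirror the two ways such deletions are
found in practice:

1. **Depth + soft clips** (the resequencing route). Maximal runs of
   positions with fewer than 10 reads (and at least `min_run = 20`
   positions, to suppress isolated dropouts) are deletion candidates;
   runs merge across the origin on circular genomes. The consensus of
   the non-mapping (clipped) read portions at each flank is then
   matched — 15 nt exact seed, extension tolerating one mismatch per
   50 nt — against the reference adjacent to the *opposite* edge. A
   match pins both breakpoints (the clip's anchor gives one, the match
   the other); clipped prefix that maps nowhere is reported as a novel
   junction insert. Left and right flanks must agree within 5 bp or an
   ambiguity error is raised. Without usable clips the scan bounds are
   returned as `coverage_only`.
2. **Anchor chaining** (the assembly route). k-mers (default 31) that
   occur exactly once in both the consensus assembly and the
   reference are paired, the longest collinear chain is kept (after
   rotating a circular query into the reference frame, and after
   dropping short offset-outlier anchor runs, which arise when a
   substitution inside a tandem repeat pairs a repeat copy with the
   wrong counterpart), and every inter-anchor gap where the reference
   advances ≥ 100 bp more than the query (or vice versa) is reported.
   The junction is placed by minimising total mismatches over all
   possible breakpoints in the gap, which is robust to substitutions
   near the junction; when no single-junction placement explains the
   gap (a deletion with a novel insert), tolerant extension from both
   anchors delimits the insert instead. Pure deletions are
   left-normalised through junction homology, the usual VCF-style
   canonical placement. A precomputed aligned-FASTA pair can be used
   instead via `gaps_from_alignment()`.

Deletion coordinates are 1-based inclusive *first and last missing*
positions throughout (size = last − first + 1); the TSV writer also
emits 0-based half-open BED columns. One representational caveat is
worth stating: when a substitution sits within a few bases of a
junction that also carries sequence homology, two placements can be
exactly equally parsimonious and no method can tell them apart from
the data; the anchor route then returns a co-optimal call whose
implied genome is identical except for the relocated substitution
column. The tests treat such co-optimal calls as recovered; the
clip route is unaffected because the clip anchor pins the junction
physically.

## Polymorphism curation

Deep mappings call many low-frequency "heterozygous" variants that are
artifacts of reads stacking on repeats. The package automates the
triage as explicit rules: frequency ≥ 0.02, at least 10 supporting
reads, forward-strand fraction of supporting reads within 0.30–0.70,
and repeat-region membership either flagged (default) or dropped. The
strand bounds were chosen wide enough that genuinely balanced variants
(forward fractions around 44–50% in typical Illumina data) pass
comfortably while heavily one-sided pileups fail. All thresholds are
arguments; every rule outcome is recorded per variant; curation is
monotone in frequency. These rules are a declared, reproducible proxy
for what is usually manual inspection — not a reconstruction of any
particular curator's decisions.

## Pairwise comparison and in-silico RFLP

`pairwise_metrics()` reports percentage identity both excluding
large-deletion columns and counting them as differences (the
denominators differ: aligned non-deletion columns vs all columns),
genome-size difference, large-deletion count difference, and SNP
differences split by coding effect; all fields are symmetric in
operand order. `rflp_predict()` digests a genome in silico (EcoRI
G^AATTC by default), including origin-spanning sites on circular
genomes; fragments always sum to genome length and the fragment
multiset is rotation-invariant. The search runs on the given strand
only — for palindromic sites such as EcoRI's the reverse-strand search
would find the same cuts.

## The synthetic-data generator

`sim_config()` + `gen_genome()` + `evolve_isolate()` +
`gen_mapping_outputs()` emulate the *outputs* of a deep-sequencing
workflow, not the reads. Defaults, and why:

* 30 kb circular genome with 25 non-overlapping ORFs of 320 ± 60
  amino acids — about 80% coding, mirroring the gene-dense
  organisation of baculovirus genomes while staying small enough that
  the full test suite runs in minutes; G+C 0.43, typical of these
  viruses. Three 280 bp tandem-repeat loci emulate homologous regions
  (hrs).
* Substitutions are proposed uniformly over positions with the
  transition partner drawn at probability
  $\kappa_{true}/(\kappa_{true}+2)$; synonymous and intergenic
  proposals are accepted at the neutral rate, nonsynonymous with
  probability $\omega$ (for $\omega > 1$ synonymous acceptance is
  down-weighted instead), intergenic optionally scaled by a relative
  rate. Effects are classified against the pristine reference codon —
  exactly how the analysis classifies variants — so the analysis-side
  dN/dS estimand equals $\omega$ by construction, and the recorded
  ground truth matches the pipeline's effect labels event for event.
  Terminal stop codons are not mutated because they are excluded from
  the possible-site tallies.
* Depth is negative-binomial with mean 4545 and coefficient of
  variation 0.23 (the overdispersion seen in deep viral resequencing,
  where SD/mean ≈ 0.23 at means of several thousand), zero across
  deleted spans with a linear shoulder taper of up to half a read
  length; clip consensus records (default 75 nt, half of a 150 nt
  read) are emitted at each breakpoint; polymorphic SNP counts are
  binomial in the local coverage.
* Every stage seeds its own stream derived from `cfg$seed`, so a
  config determines all outputs byte for byte.

What the generator does **not** emulate: sequencing error,
read-length effects other than the clip/taper geometry, mapping bias
inside repeats (clips and depth are generated from the truth, not
from alignment), recombination, and copy-number variation. Passing
the synthetic suite therefore demonstrates that the *estimators and
detectors are correct under their own model*; it does not demonstrate
robustness to mapper-specific artifacts in real data — which is
precisely why the polymorphism curation rules exist and why deletion
calls carry their evidence class.

## Validation design and problem sizes

The test suite (a few seconds to ~1 minute per file) checks every
operation against an independent oracle where one exists: exhaustive
9-change enumeration for codon site counts; whole-proteome rediff for
effect classification; set algebra for partitioning; construction for
rotations, digests and alignment gaps. Parameter-recovery checks run
simulations of 2000 accepted substitutions and require genome-wide
dN/dS within [0.9, 1.1] at $\omega = 1$, within ±0.05 of 0.2 at
$\omega = 0.2$, and dI/dS within ±0.1 of a planted 0.5 rate ratio;
each reported estimate averages three replicate simulations to keep
Monte Carlo error (single-replicate SD ≈ 0.06) well inside those
bands. Deletion recovery runs 100 seeded replicates with one planted
deletion of 150–2000 bp and 200 substitutions each; the depth+clip
route must return the planted coordinates exactly in all 100, the
anchor route a single exact-size, parsimony-optimal call. The
genome-scale published-value checks (whole-genome and per-gene dN/dS
against the SpltNPV-G2b reference) additionally require the GenBank
MN342245 record, which is not redistributed with the package — see
`?load_spltnpv_g2b`.

## Known limitations

* The counting estimator has no variance model; no confidence
  intervals or likelihood-ratio tests are provided, consistent with
  its intended use on small numbers of fixed substitutions spread
  over many codons.
* Junction placement (both routes) is only defined up to genuine
  sequence ambiguity: homology at the junction shifts the canonical
  placement, and a substitution adjacent to a homologous junction can
  make two placements equally parsimonious.
* GFF3 cannot represent origin-wrapping ORFs; they are supported in
  memory (and by rotation) but not in annotation files.
* Repeat regions are flagged, not modelled: the generator plants
  clean tandem arrays, whereas real hrs have diverged palindromic
  units.
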