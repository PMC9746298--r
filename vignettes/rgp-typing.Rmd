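---
title: "In-silico Rgp typing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico Rgp typing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgptyper)
```

## The typing problem

The *rgp* locus of *Streptococcus thermophilus* is bipartite: a variable
5′ region encodes the biosynthesis of the decorative side chain of the
rhamnose–glucose cell-wall polysaccharide (Rgp), and a more conserved 3′
region encodes the rhamnan backbone machinery (RgpA/B/F
rhamnosyltransferases, the RgpC/D ABC transporter). The two halves
recombine independently, so a meaningful classification needs two
labels: a variable type (Vt1–Vt5), called from unique gene content of
the 5′ region, and a backbone type (Bt1–Bt3), keyed on the divergent
*rgpF* gene. Their combination V*i*B*j* identifies the overall Rgp
group; seven combinations have been observed (V1B1→1, V1B2→2, V2B2→2A,
V3B2→3, V3B3→4, V4B1→6, V5B1→7), and the typing scheme deliberately
leaves the remaining eight combinations open as `novel`.

This package realises the wet-lab two-step multiplex PCR entirely in
silico. The scheme itself — primer sequences written 5′→3′, expected
product sizes, target groups, the binomial map — is data, shipped as a
versioned flat TSV (`inst/extdata/rgp_scheme_v1.tsv`) and validated on
load (14 pairs; primer lengths 15–30 nt; every product longer than its
two primers; one control per panel role).

## In-silico PCR

`find_binding_sites()` scans both strands for primer annealing sites.
Bases are compared as IUPAC expansion sets (4-bit codes; two bases match
iff their sets intersect), so an `N` in a draft assembly is never a
mismatch, and degenerate primer positions behave like the corresponding
base mixture. Three knobs matter:

* `max_mismatch` (default **0**): the wet protocols report no mismatch
  tolerance, so the default demands exact annealing; the parameter
  exists because real assemblies contain sequencing errors.
* `exact_3prime` (default **3** nt): a polymerase-extension clamp — the
  3′-terminal bases must match exactly, reflecting that terminal
  mismatches abolish extension far more reliably than internal ones.
* `size_tolerance` (default **0.10**, fractional): a pair is scored
  "amplified" when a convergent product lies within expected ± 10 %, a
  surrogate for what agarose gel resolution would accept as the
  expected band.

An amplicon is any convergent, non-overlapping pairing of a forward
site on one strand with a reverse site on the other; its length is the
inclusive span from the first base of the forward site to the last base
of the reverse site, which is the convention the published product
sizes follow. All size-concordant products are reported; a pair whose
concordant products map to more than one location is flagged
`ambiguous`, because the scheme assumes single-copy targets. Products
never span contigs. Coordinates are 1-based and inclusive throughout,
the Bioconductor convention.

The scanner is deliberately simple — a bit-encoded Hamming scan — and
is held to an exhaustive sliding-window oracle in the test suite
(identical sites and products on random sequences up to 20 kb, with and
without planted imperfect sites). Reporting is monotone in
`max_mismatch`, and reverse-complementing the genome leaves the multiset
of product lengths unchanged.

## Calling logic

Panel interpretation distinguishes three outcomes deliberately:

* **assay-invalid** (control pair failed): an error condition
  (`rgp_assay_invalid`), not a call — nothing can be concluded;
* **untypeable** (control fine, no target pair amplified);
* **ambiguous** (more than one target pair amplified) — never
  propagated into a binomial, to avoid silent misclassification.

Group 5 needs special handling: its variable region is minimal and has
no Var target, so it is reachable only through the backbone panel. An
untypeable-by-panel-1 strain with Bt3 is therefore reported as group 5
with `tentative = TRUE` (the Fg3 pair targets groups 4 and 5). The
legacy single-step panel is also implemented (631/464/303/162 bp →
groups 1–4, control 801 bp); it cannot emit group 5 at all, and on
fixtures it agrees with the binomial caller exactly up to its known
blind spots (groups 1/6/7 collapse to legacy 1; 2/2A to legacy 2).

`summarize_collection()` reports percentages at 2 decimals by default,
with `digits = 1` for comparison against one-decimal survey tables. One
arithmetic note: a 9/21 share is 42.857 %, which rounds to 42.9 at one
decimal; a published figure of 42.8 for that share reflects truncation
rather than rounding, and the package does not add a truncation mode to
match it.

## Locus extraction and family clustering

`extract_locus()` cuts the locus between two anchor genes — the 30S
ribosomal-protein gene on the variable side and a predicted
transcriptional regulator on the backbone side — located by local
protein alignment. Anchors use the same acceptance contract as gene
families (one similarity contract everywhere): local alignment with a
BLOSUM62 substitution matrix and affine gaps (open 11, extend 1),
identity computed over alignment columns, coverage as the aligned
fraction of each sequence. The default thresholds are **50 % identity
over ≥50 % of both sequences, inclusive** ("50/50"). Whether coverage
should bind both sequences or only the query is genuinely
underdetermined; both-sequence coverage is the default because it makes
the edge relation symmetric, and `both_coverage = FALSE` relaxes it.
Anchor ties break towards the smaller genomic coordinate. If the anchor
pair lies on the reverse strand, gene order and strands are normalized
so the variable region always precedes the backbone region.

Annotation is expected as GFF3 (+ optional protein FASTA; otherwise
CDSs are translated from the genome). For bare assemblies a naive
ATG-initiated ORF finder (≥100 codons, standard code) is provided and
its products are explicitly flagged as lower-confidence predictions.

`build_families()` forms the similarity graph over bidirectional-pass
edges and partitions it by connected components (default) or by a
native Markov clustering implementation (matrix expansion/inflation;
inflation default 2.0 — the conventional MCL midpoint, since no value
is prescribed for this analysis). Components are the default because,
at the 50/50 acceptance threshold, planted families are already
well-separated and the two methods agree on such graphs (tested). An
alignment prefilter (shared amino-acid 8-mer plus a length-ratio bound
implied by the coverage threshold) keeps the all-vs-all step tractable;
it is an optimisation, not a definition, and can be disabled
(`prefilter = FALSE`), with tests asserting both paths give identical
partitions. Input order never matters: proteins are canonically sorted
before clustering.

Locus profiles are binary family presence/absence vectors, compared by
Jaccard distance (shared absences carry no signal) and clustered with
average linkage; the linkage/distance pair is a package choice, since
the original heatmap tooling does not document its defaults. Flat
clusters come from a height or a target count; dendrograms export as
Newick.

## The structure knowledge base

The genotype→structure link is an empirical finding, not an algorithm,
so structures live in a curated static knowledge base with per-entry
provenance: groups 1, 2, 3, 4 and 6 are `elucidated` (source strains
UCCSt50, UCCSt95, UCCSt89, UCCSt12, St64987), group 7 is `predicted`
(a UDP-galactopyranose mutase gene in its variable region implies a
Galf residue in the side chain), groups 2A and 5 are `unknown`. Side
chains of groups 1/2 are stored as composition (branched
tetrasaccharide, GlcNAc at the branch) because their full linkage
tables are published only in supplementary material; the disaccharide
side chains and both backbone repeats are stored residue-by-residue and
render/parse round-trip through a compact linear notation
(`-2-α-Rha-3-α-Rha-`).

`check_consistency()` operationalises one observable correlate: the
variable region should encode at least (side-chain residues − 1)
elongating glycosyltransferases, the priming transferase accounting for
the branch residue itself. The check is informational — real loci can
carry pseudogenes or trans-acting genes the rule cannot see.

## What the fixture generator emulates — and what it does not

`generate_locus()` builds a single-contig genome per genotype:
~39 % GC filler (species-like), anchor genes, the genotype's gene
families as proteins mutated from fixed family seeds and
back-translated with uniformly sampled synonymous codons, primer
cassettes (forward primer + filler + reverse-complemented reverse
primer) sized so the inclusive span equals the scheme's expected
product, the legacy cassettes, and the DNA-primase gene wrapped in the
2,724 bp MSControl cassette just outside the locus. Cassettes sit in
intergenic DNA so planted protein families stay intact, and every
planted primer site is verified unique in the genome. The default
`mutation_rate = 0.05` per site keeps intra-family identity near 90 %
(comfortably above the 50/50 acceptance) while inter-family pairs are
independent random sequences (far below it); fixtures therefore probe
the machinery, not threshold borderline behaviour. Everything is
deterministic in `(genotype, seed)`.

What the fixtures do **not** emulate: real intergenic sequence,
operonic structure, pseudogenes, mobile elements, assembly errors,
partial primer-site degeneration (e.g. whether real 2A strains retain
partial Var1 sites is untested — the generator follows the scheme's
target table literally), or phylogenetic correlation between strains.
Green round-trip tests therefore demonstrate the correctness of the
machinery under the scheme's own assumptions, not typing accuracy on
arbitrary field isolates.

## Problem sizes and numerical choices

The shipped tests run at desk scale: fixture genomes of ~20–30 kb;
typing round trips over all eight genotypes × five seeds; oracle
equivalence on 100 random sequences of 0.5–20 kb; family recovery on a
7-genotype × 3-replicate collection (~300 proteins, 32 planted
families, recovered exactly, with replicates co-clustering at k = 7).
The published 78-genome comparison (49 gene families) requires external
genome downloads and is out of scope here; the fixture-recovery
properties stand in for it. Percentages are `round()`ed, never
truncated; Jaccard uses the asymmetric binary form; hclust merge order
resolves equal-distance ties deterministically by row order.

## Limitations

* Amplicon sizes are scheme ground truth, not recomputed from reference
  genomes (target genome coordinates are not published data).
* No thermodynamic annealing model: a site with ≤ `max_mismatch`
  mismatches and an intact 3′ clamp "amplifies" regardless of melting
  behaviour, and primer-dimer or off-target faint bands are not
  modelled (off-target size-concordant products are reported and
  flagged instead).
* The legacy caller cannot emit group 5, mirroring the published
  scheme, and real anchor proteins must be user-supplied for real
  genomes (`rgp_anchor_queries()` matches only the packaged fixtures).
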