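---
title: "Detecting horizontally transferred islands with hgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontally transferred islands with hgtscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtscan)
```

## The inference

Horizontal gene transfer (HGT) between bacterial species leaves a signature
that is detectable purely comparatively: stretches of DNA that are nearly
identical between two genomes that are otherwise far too divergent for that
similarity to be inherited vertically. `hgtscan` operationalises this in
four steps.

**1. All-vs-all CDS homology.** Every protein-coding sequence (CDS) is
aligned against the CDS of every other genome. A hit is a local nucleotide
alignment with percent identity $\geq$ 99 over $\geq$ 500 aligned columns
(both cutoffs inclusive; both configurable via `homology_params()`).
Identity is computed over all alignment columns with gap columns counting
as mismatches, the convention of the common 12-column tabular hit format,
so internally computed and imported hits are filtered identically.
Same-genome hits are never emitted.

**2. ANI filter.** Near-identical genes between two strains of the same or
closely related species are the expected outcome of vertical inheritance,
not transfer. Relatedness is measured by fragment-based average nucleotide
identity (ANI): each genome is cut into 1000-nt non-overlapping fragments,
each fragment is aligned against the partner genome, and a fragment
qualifies when its best hit reaches 70% identity over at least 70% of the
fragment length. One-way ANI is the mean identity of qualifying fragments;
the reported value is the two-way mean. Hits between genomes labelled as
the same species, and hits between genomes whose two-way ANI exceeds 89,
are discarded. Both cutoffs are `detection_params()` arguments.

**3. Island assembly.** Surviving candidate genes on the same contig whose
inter-feature gap (next start minus the running maximum end) is at most
5000 nt are merged into an *island*, the putative unit of transfer. The
boundary is inclusive: a gap of exactly 5000 still merges. Non-candidate
genes lying inside a gap neither join nor break an island; islands never
span contigs.

**4. Group clustering.** Islands in different genomes that contain genes
joined by a retained hit are placed in the same *group*, taken as the
connected components of the island graph. Grouping is transitive by
construction: islands A and C that share no gene are still co-grouped when
both share genes with island B.

The method is symmetric and says nothing about the direction of gene flow;
donor inference is out of scope.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_identity` | 99.0 | percent | hit identity floor (inclusive) |
| `min_length` | 500 | nt (columns) | hit length floor (inclusive) |
| `kmer_size` | 31 | nt | exact-seed length of the aligner |
| `max_ani` | 89.0 | percent | relatedness ceiling; pairs strictly above are vertical |
| `island_max_gap` | 5000 | nt | inter-feature gap joining candidates into islands |
| `fragment_length` | 1000 | nt | ANI fragment size (non-overlapping) |
| `best_hit_min_identity` / `coverage` | 70 / 0.70 | percent / fraction | ANI fragment qualification |
| `min_fragments` | 5 | fragments | per-direction floor for a *defined* ANI |
| `screen min_identity` | 97.0 | percent | metagenome presence, **strict** inequality |
| `min_query_coverage` | 0.90 | fraction | metagenome presence coverage floor |

Two deliberate asymmetries in how thresholds are read: the homology
cutoffs are *inclusive* (a 500-nt, 99.0% alignment is a hit) whereas the
metagenome screen is *strict* (a CDS at exactly 97.0% is not present),
matching how each criterion is stated for its stage. The ANI ceiling is
exclusive upward: a pair at exactly 89.0 passes the filter; only strictly
greater is excluded. This keeps pairs like distinct species at ANI ~88 —
plausibly exchanging DNA — inside the analysis.

**Undefined ANI passes the filter.** When either direction has fewer than
`min_fragments` qualifying fragments, the pair's ANI is reported as
undefined (`defined = FALSE`, values `NA`, never a silent 0) and the pair
is *not* excluded. The filter exists to remove close relatives; genomes
with too little alignable sequence to measure relatedness are by that very
fact not close relatives.

**Promiscuous-gene diagnostic.** A gene whose retained hits span more than
`promiscuous_min_genomes` distinct partner genomes (default 10) is flagged
as a likely mobile element capable of chaining unrelated islands into one
group. Groups are reported as clustered, never auto-split; the flag is a
diagnostic. The default of 10 is calibrated to collections of ~100+
genomes; in small communities the threshold should be scaled to the
community size (we use 4 in the 8-genome validation community, where the
planted transposon reaches 5 partner genomes and no true island gene
exceeds 2).

## The internal aligner

The aligner is a classical seed-and-extend design: exact shared k-mers
(default k = 31) are clustered by diagonal, each cluster is resolved with a
banded affine-gap local alignment (match +1, mismatch −2, gap open −4, gap
extend −2; band half-width 16 around the seed diagonals, window slack
`extend_margin` = 400 nt), and overlapping alignments are deduplicated
keeping the highest score with deterministic tie-breaks (smaller query
start, then subject start). Bases outside A/C/G/T never match: IUPAC
ambiguity codes are mapped to N on read and N is a universal mismatch.
Both strands are searched by default.

At the identities the pipeline cares about (≥ 90%), alignments are densely
seeded and the banded window contains the full optimal local alignment, so
the aligner reproduces full Smith–Waterman results; the test suite pins
this against an independent dynamic-programming oracle
(`Biostrings::pairwiseAlignment` with the same scoring scheme) on random
pairs up to 2 kb at divergences up to 10%, asserting exact score equality.
Below ~75% identity seeds become sparse and the heuristic can miss or
fragment optimal alignments — the standard trade-off of seeded search, and
irrelevant here because no stage consumes alignments that weak. Per gene
pair only the single best-scoring alignment is kept: the pipeline counts
genes, not alignment segments.

For fragment ANI the same machinery runs with a shorter seed (k = 15),
since qualifying fragments may sit near the 70% identity floor where
31-mers are not reliably conserved; the subject genome is indexed once per
direction rather than per fragment.

## What the synthetic communities emulate

`generate_community()` builds seeded single-contig genomes containing:

- **independent random backgrounds** with non-overlapping background genes,
  so that any cross-genome near-identity is either planted or vertical by
  construction;
- **a shared ancestral core** (default 15 kb, ~15% of the genome): every
  genome carries a copy of one community-wide ancestral sequence,
  independently mutated at 12% per site, giving unrelated pairs ~78%
  pairwise identity over the core. Real genomes — however distantly
  related — share universally conserved loci at moderate identity, and it
  is exactly this alignable core that anchors cross-genus ANI in the
  70–85% range. Without it, the only alignable sequence between two
  unrelated synthetic genomes would be the planted island itself, and a
  fragment-based ANI computed over those fragments alone would read ~100%
  — an artifact of over-idealised backgrounds, not a property of the
  method. The core carries no CDS annotation, so it never enters the
  homology search;
- **relative pairs**: one genome is a whole-genome mutated copy of another
  at a stated rate r, so the expected ANI is 100(1−r); a few background
  genes are copied unmutated (highly conserved core genes), which *do*
  trip the 99%/500-nt homology threshold and must be removed by the ANI
  filter, never by luck;
- **planted islands**: multi-gene cassettes written into the gene-free
  tail of a donor and its recipients, recipient copies mutated at a
  controlled per-site divergence (substitution-only by default);
- **transposon confounders**: one short element copied verbatim into many
  genomes, optionally within 5 kb of a planted island, reproducing the
  documented artifact where a shared mobile element chains unrelated
  islands into one group.

Divergence is substitution-only by default so that identity and ANI have
closed-form expectations (Hamming distance is exact divergence); indels
are available but off. The ground truth marks each planted copy
*detectable* iff some partner copy is within the identity threshold over
at least the length threshold, computed by exact Hamming identity — recall
is measured against detectable truth, separating generator noise from
detector error. Expected islands and expected groups are re-derived from
the truth coordinates by an independent union-find, in two variants: the
per-element partition and the partition after transposon chaining (what
proximity clustering is expected to report).

What the generator does **not** emulate: codon structure and real gene
models, rearrangements, gene loss, GC skew, repeat families, assembly
fragmentation, and indel-rich divergence. Passing recovery tests therefore
demonstrates the correctness of the detection logic under its own model of
the signal, not robustness to every property of real sequence data. In
particular, real draft assemblies split islands across contigs (handled,
but producing multiple islands per event) and real annotation provides the
gene boundaries we take as given.

## Numerical and design choices

- **Identity denominator** includes gap columns (gaps are mismatches),
  for consistency between internal and imported tabular hits.
- **Group ranking** is fully deterministic: descending total genes, ties
  by descending total nucleotide content, then lexicographically smallest
  member genome id.
- **Compound GenBank locations** (`join(...)` within one contig) are
  flattened to their enclosing interval; cross-contig joins are skipped
  and counted in the parse report. Island logic needs one interval per
  gene.
- **Same-species exclusion** happens in the detection stage (where
  species labels live), not at search time; the search only excludes
  same-genome hits. Species, genus and phylum labels come from a curated
  metadata table and are never inferred from sequence.
- **The ANI cutoff is applied to the two-way mean** (one-way means are
  reported alongside), and one global cutoff is applied to all pairs.
- **Strand is ignored in island assembly**: a transferred operon may
  contain genes on both strands, and the proximity criterion is purely
  positional.
- **Genes-per-species in group statistics** sum across all of a species'
  islands in the group, including islands split across contigs.
- **Missing taxon labels** make `same_phylum`/`single_genus` unknown
  (`NA`), never `FALSE`.
- **Degenerate recovery metrics**: with no detected positives, precision
  is reported as 1 with an explicit `precision_defined = FALSE` flag
  rather than NaN.
- **Mobile elements** are recognised by case-insensitive product-keyword
  match (transposase, integrase, conjugal, conjugation, phage,
  recombinase, mobile element, insertion sequence); the list is a
  parameter.
- Gene identifiers are taken verbatim from the input annotation
  (`locus_tag`, falling back to `protein_id`, then a positional id).

## Validation problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data built at run time: an 8-genome × 100-kb reference community (two
planted islands at divergence 0 and 0.005, one relative pair at rate 0.05,
one transposon confounder bridging the two islands), 50-kb
substitution-only pairs for ANI recovery at rates 0.005–0.1, 100 random
pairs up to 2 kb for the Smith–Waterman oracle comparison, and 50 random
island graphs for the clustering-vs-transitive-closure check. These sizes
were chosen so the whole suite exercises every code path in minutes on a
laptop while keeping every expected value analytic (Hamming identity,
exact ANI expectations) or pinned by an independent oracle.

## Known limitations

- Sensitivity is bounded by the 99%/500-nt criterion: older transfers
  (island copies at ~97% identity) are invisible by design, and the
  candidate list is an underestimate whenever true relatives of the
  donor are absent from the collection.
- Fragment ANI between genomes sharing little alignable sequence rests on
  few fragments; the `defined` flag and fragment counts are reported so
  borderline pairs can be inspected.
- A mobile element shared across groups merges them (reported, flagged,
  not corrected); conversely an island split across contigs of a draft
  assembly is counted as several islands in one group.
- The aligner is heuristic below ~75% identity; it is not a general-purpose
  aligner and is only specified for the regimes the pipeline uses.
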