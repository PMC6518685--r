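---
title: "ltpscan: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ltpscan: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science in `ltpscan` the way a methods
section would: the models and their assumptions, the parameters that
matter, what the simulators do and do not emulate, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The eight-cysteine motif and type classification

Plant nsLTPs share the skeleton `C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C`: eight
cysteines, the third and fourth adjacent, the fifth and sixth separated
by exactly one residue. The five variable spacer lengths (s1..s5) are the
classification signal: each type's template lists the admissible length
set per spacer, and a motif belongs to a type when all five spacers fall
in the type's sets.

**Motif scan.** `find_ecm_matches()` enumerates every assignment of
eight cysteines satisfying the structural constraints. Two scan-level
decisions:

* *Cysteine-free spacers* (default). Literally, "X = any amino acid"
  would allow cysteines inside spacers, which both contradicts the
  "eight-cysteine" count and makes assignments combinatorially
  ambiguous. The default therefore requires spacers free of C, making
  the parse of a well-formed sequence unique; `allow_cys_in_spacers =
  TRUE` restores the literal reading, and the scan then returns every
  valid 8-subset.
* *Global spacer bounds* `[3, 40]` per spacer, applied before any
  template: every bundled template value lies in 3..30, so the bounds
  admit all real types with margin while preventing pathological
  "motifs" spanning unrelated domains. Both bounds are user-settable.

**Best match.** When several motif candidates exist, the scan keeps the
one that matches the fewest (but at least one) templates — the most
specific — breaking ties toward the most N-terminal occurrence (nsLTP
ECMs sit just after the signal peptide). This is a declared convention:
survey papers do not state how they resolved overlapping assignments.

**Ambiguous types.** A motif can satisfy several templates (the bundled
XII and XIII overlap on a thin slice of spacer space, e.g. spacers
9,13,21,21,9). The assigned type is then the first in registry order
(I, II, IV, V, VII, VIII, XII, XIII) and the full matched list is kept
in the results for audit. Zero-member types are simply absent from the
summary; the classifier does not explain biology.

**Similarity fallback.** Motifs matching no template can be assigned by
global alignment against user-supplied reference ECMs (this is the route
by which new types get erected in family surveys). Identity is computed
over all alignment columns; the threshold defaults to 50% — no published
value exists, so it is configurable and conservative. Ties go to the
first reference in table order.

## Protein descriptors

Molecular weight is the sum of average (not monoisotopic) residue masses
plus one water, in kDa — the convention of the proteome portals that
family tables cite. The isoelectric point is the root of the
Henderson–Hasselbalch net-charge curve over the termini and the D, E, C,
Y, H, K, R side chains, with a Bjellqvist-style pKa table; the curve is
monotone non-increasing in pH, so bisection on [0, 14] (tolerance 1e-4
on |Z| or on the interval) always converges. Both tables ship as TSV
data and are swappable; because the upstream tool behind published
MW/pI values is unnamed, exact reproduction of any specific published
table is deliberately not promised.

## Tandem duplication

Two family genes are a tandem pair when, on one chromosome, at most
`max_intervening = 5` other annotated genes (of any family — "five other
genes" is read as any genes) separate them *and* they lie within
`max_distance = 100000` bp. Clusters are connected components of the
qualifying-pair graph: a chain a–b–c is one cluster even when a–c alone
fails, matching "gene cluster" usage. Open points resolved here:

* *Distance anchor.* The published rule names no anchor; start-to-start
  distance is used because it is monotone with rank order and
  unambiguous for nested or overlapping gene models. A gap-distance
  option (`distance_mode = "gap"`) is provided.
* *Pairwise, not span-wide.* The 100-kb test is applied per pair, not to
  the whole cluster span; with transitive closure a long chain can
  exceed 100 kb end to end.

Ranks are assigned per chromosome by ascending start, ties by ascending
end then gene id, so rank sets are always permutations of 1..n.

## Ka/Ks and divergence dating

Coding pairs are aligned at the protein level (Needleman–Wunsch, BLOSUM62,
gap open 10, extend 0.5, gap of length L costing open + (L−1)·extend),
back-translated so each protein gap becomes a whole-codon gap, and
counted by the Nei–Gojobori (1986) scheme: per codon, the synonymous
site fraction is the proportion of one-step changes that preserve the
amino acid (changes to stop codons count as nonsynonymous), averaged
between the two codons; multi-position differences are averaged over all
orderings of single steps with stop-traversing paths excluded (if every
ordering hits a stop, the exclusion is dropped for that codon). Codon
columns containing gaps, stops or ambiguity codes are skipped and
counted. Proportions are corrected with Jukes–Cantor,
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 flags saturation and the pair becomes
`undetermined`.

Selection is categorized strictly: Ka/Ks < 1 purifying, > 1 positive,
= 1 neutral (ε = 1e-9), Ks = 0 undetermined. Divergence time is
t = Ks/(2r) with r = 2.6×10⁻⁹ substitutions·site⁻¹·yr⁻¹ by default
(configurable), reported in million years and rounded only at display.

**Estimator choice.** NG86 + JC was chosen over the MYN-family
estimators because every downstream consumer here — the selection
categories and the Ks-based dating — is estimator-agnostic at the
decision level, and NG86 admits an exact, independently checkable
counting oracle. The estimator name is recorded in every output row.

**Known limitation.** NG86+JC is essentially unbiased below Ks ≈ 0.1 but
overestimates at moderate divergence: two-fold degenerate sites
accumulate visible differences faster per site than the JC inversion
assumes (saturating toward 1/2 rather than 3/4), so at Ks = 0.5 the
estimate runs a few percent high of event-count truth — measured at
about +0.026 on Ks and +0.002 on Ka over 100 simulated 300-codon
replicates, outside a 3-standard-error band of the mean. This is the
documented regime where counting estimators degrade and the reason
likelihood-style estimators exist; the acceptance suite records this
check honestly rather than hiding it (see the test marked criterion 4).

## Phylogenetics

Distances are p-distances — mismatches over sites where both sequences
carry an unambiguous, non-gap residue (pairwise deletion; complete
deletion available). Trees are Saitou–Nei neighbor joining with the
standard Q-criterion; the implementation is exact on additive matrices
(verified against matrices derived from random trees). Determinism under
ties: each active node is represented by its lexicographically smallest
leaf, and among equal-Q pairs the lexicographically first representative
pair is joined. Negative branch estimates are clamped to zero and
counted in an attribute. Bootstrap support resamples alignment columns
with replacement, rebuilds the tree, and reports the percentage of
replicates containing each internal bipartition of the reference tree;
the RNG seed is recorded on the result.

Because classified ECMs share the eight-cysteine skeleton, the multiple
alignment feeding the tree is anchor-based: cysteines pinned columnwise,
spacers right-padded to their per-slot maxima. This avoids re-deriving a
progressive MSA and preserves exactly the structure classification
established; pre-aligned input is also accepted.

## Promoter elements

Promoters are the 1500 bp (configurable) immediately 5' of the gene
start — the gene-feature boundary approximates the transcription start
site, as in portal-derived upstream windows — reverse-complemented for
minus-strand genes and truncated (with a flag) at chromosome edges.
Motif *sequences* are user input: the upstream motif database's content
is not redistributable, so only the element-name → category mapping
(A = hormone, B = stress, C = growth) ships as data; endosperm-related
elements are deliberately absent. Scanning is exact IUPAC matching on
both strands by default (a flag disables the reverse strand, since
published surveys rarely state their choice); overlapping hits are all
reported.

## What the simulators emulate — and what they do not

`generate_proteome()` draws each spacer uniformly from the named type's
allowed set, fills spacers and flanks (leader 20–35 aa, tail 0–20 aa)
with cysteine-free residues, and back-translates by uniform codon choice
plus a random stop. Consequently every family protein has exactly one
valid motif parse, and coding sequences always translate to their
proteins. Decoys probe one failure mode each: a mutated motif cysteine
(no motif), one spacer outside every template but inside scan bounds
(motif, no type), or a cysteine-free random protein. Not emulated: real
amino-acid composition (spacer fill is uniform over 19 residues — the
classifier only reads the cysteine skeleton), signal peptides, or real
length distributions. A green planted-recovery test therefore
establishes the scan/classification logic, not performance on real
proteomes.

`generate_gene_map()` lays planted clusters (consecutive members 0–2
background genes and 5–15 kb apart — both respecting the rule, validated
against it), singleton family genes, and decoy pairs violating exactly
one rule condition each (six intervening genes within 70 kb; adjacent
ranks at 150 kb), with separator runs violating both conditions between
units. Intron counts are arbitrary (1–3 exons); no UTRs, no alternative
transcripts.

`simulate_codon_pair()` applies Poisson numbers of class-forced single
nucleotide substitutions (half per lineage) to a stop-free random
ancestor, resampling any change that would create a stop, and records
event counts over ancestor site counts as the truth. It emulates
divergence *depth*, not compositional realism (no transition bias, no
codon-usage bias) — which is exactly what the recovery analysis above
needs.

All generators are fully deterministic given `seed`.

## Numerical and formatting details

* Coordinates are GFF3 1-based inclusive everywhere; nothing converts.
* Terminal stop codons are stripped before translation checks and Ka/Ks;
  any other translation mismatch (beyond X opposite N-codons) is a hard
  error, because silent repair would corrupt Ka/Ks.
* Alignment tie-breaks prefer substitution, then a gap in the second
  sequence, then a gap in the first — byte-reproducible alignments.
* Summary patterns collapse consecutive integers to `a-b` (ASCII hyphen)
  and comma-join the rest, e.g. `CX9-10CX12-17CCX19CXCX20-24CX3,13-14C`.
* Percentages are rounded to 2 decimals at display; divergence times to
  2 decimals at display only.
* The pipeline validates stage inputs before running any stage, logs
  every filtering decision (no-motif, unclassified, skipped codon
  columns, truncated promoters), and re-runs byte-identically under a
  fixed config and seed.

## Representative-transcript policy

When a gene model carries several mRNAs, the first in file order is
taken as representative and recorded in the gene model (`mrna_id`).
Surveys typically filter to one representative transcript upstream;
this package does not second-guess the input annotation.
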