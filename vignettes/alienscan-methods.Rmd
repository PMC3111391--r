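---
title: "Detecting alien-chromosome transcripts by identity-by-descent: methods and design"
author: "alienscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alien-chromosome transcripts by identity-by-descent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alienscan)
```

## The problem

A chromosome addition line carries the full genome of a recurrent parent
plus one whole chromosome from a distantly related donor. Transcripts
expressed from that alien chromosome are *identical by descent* with the
donor's copies: both descend from the same haplotype only a few generations
back, so — unlike orthologs of the two species, which differ by fixed
substitutions — they should match exactly. This turns a hard expression
question ("which transcripts come from the alien chromosome?") into a
sequence question: find contigs from the donor library and the
addition-line library that are literally identical over their mutual
overlap.

The motivating system is apomixis genetics in *Pennisetum*: an octoploid
donor (*P. squamulatum*) whose ASGR-carrier chromosome — the chromosome
bearing the Apospory-Specific Genomic Region — is carried as a single alien
chromosome in a backcross derivative of tetraploid pearl millet. The
package is written generically: any donor / recurrent-parent / addition
design with two assembled transcript libraries fits.

## The detection funnel

1. **Scan** (`findExactMatches`): every maximal exact match of length at
   least `minExactLen` (default 100 bp) between the two libraries, on both
   strands. Matching is seeded with `minExactLen`-mers through a rolling
   hash; each maximal match is expanded once from its leftmost seed, so the
   output provably equals a brute-force all-common-substrings enumeration
   (a quadratic dynamic-programming oracle in the test suite checks exactly
   this). `N` matches nothing, including `N`.
2. **Score and filter** (`karlinAltschulEvalue`, `filterCandidatePairs`):
   hits are scored as ungapped alignments (+1 match) and assigned
   Karlin-Altschul E-values, \(E = K m n e^{-\lambda S}\), with the BLASTN
   defaults \(\lambda = 1.28\), \(K = 0.46\) for +1/−2 scoring, m the query
   length and n the total subject-library length (no edge correction — the
   controlling filter is the exact-length rule). Hits with 100% identity,
   length ≥ 100 bp and E below the primary threshold become *candidate
   comparisons*; the distinct query and subject contig counts are reported
   alongside.
3. **Verify** (`verifyComparisons`): each candidate pair is aligned
   end-gap-free over the full contigs (match +1, mismatch −2, gap −4).
   A pair is *accepted* only if the whole mutual overlap aligns with zero
   mismatches, zero internal gaps, and flush ends (terminal unaligned
   sequence only as dangling overhangs). Pairs whose exact core does not
   extend to the contig ends are rejected as non-extending; the zero-
   mismatch rule is the binding criterion, so the verdicts do not depend on
   the particular score values.
4. **Uniqueness screen** (`uniquenessScreen`): each verified candidate is
   searched against both full libraries (16 bp exact seeds, ungapped
   X-drop extension) at a relaxed E-threshold, to find homeologs, paralogs
   and the recurrent ortholog. Candidate positions that differ from every
   such hit are *discriminative* — the raw material for marker design.
5. **Marker design and in-silico screening** (`designMarker`,
   `insilicoPcr`, `screenPanel`, `classifyLinkage`): a pair of 20 bp primer
   tags is placed on the candidate, preferring placements whose 3'-terminal
   15 bases cover discriminative sites, and accepted only if it amplifies
   the donor's genomic templates and nothing in the recurrent-parent /
   sexual-segregant context. The binding model — 3'-terminal bases exact,
   at most two mismatches in the remainder — is a deliberate surrogate for
   real PCR chemistry (annealing temperatures and primer thermodynamics
   are out of scope). The linkage rule engine then encodes the mapping
   logic: carrier-chromosome linkage requires amplification from the donor
   and every apomictic segregant but none from the recurrent parent or any
   sexual segregant; tight linkage to the ASGR additionally requires
   amplification from every apomictic F1 and no sexual F1. CAPS
   polymorphisms (`findCapsPolymorphism`) and allele co-segregation
   (`segregationCheck`) cover markers that are not presence/absence.
6. **Library comparison** (`compareTermLibraries`): annotation-term counts
   of the two libraries are compared per term with a two-sided Fisher's
   exact test ("probability no larger than observed" convention) and
   Benjamini-Hochberg adjustment. The FDR variant is pluggable in
   principle; BH is the default because the original tooling documents
   only "FDR".

### E-value threshold notation

The protocol this pipeline models prints its cutoffs as "e^-100" (primary)
and "e^-25" (uniqueness). Read as decimal exponents (1e-100), the primary
cutoff would be unreachable by any 100 bp perfect match — under the
Karlin-Altschul parameters above, a 100 bp exact hit against a 15 Mb
library scores E ≈ 5e-47 — and the funnel would be empty, contradicting
the fact that 100 bp matches were retained. Read with the natural base
(e^-100 ≈ 3.7e-44), minimum-length perfect matches pass. The package
therefore defaults to the natural-base reading
(`pipelineConfig(evalueNotation = "natural")`), with the decimal reading
selectable for sensitivity analysis.

## The synthetic experiment

`simulateExperiment` generates the full study design under one seed, so
every stage can be validated against planted truth:

* Ancestral genes (default 60, a deliberately scaled-down transcriptome
  that keeps a full 20-seed validation sweep fast while leaving several
  alien transcripts per replicate) are laid out round-robin on 7 donor
  chromosome groups; each gene gets a transcript of 300-900 bp and 0-2
  introns of 80-500 bp for the genomic templates. Intron sizes are a
  modeling choice: the protocol designed intron-spanning primers but
  reports no sizes.
* The donor lineage carries 4 homeologous haplotypes per gene (haplotype 1
  is the reference; the others diverge by `dHomeolog` = 0.02
  substitutions/site), emulating a high-ploidy donor whose assembler
  separates homeologous transcripts into distinct contigs. The recurrent
  parent and a third relative each diverge from the ancestor by
  `dSpecies`/2 per branch, so donor-recurrent ortholog distance is
  `dSpecies` (default 0.05 — a modeling default, not a measured value for
  any real species pair).
* The addition line expresses the recurrent transcriptome plus the alien
  chromosome's haplotype-1 transcripts copied without substitutions —
  the identity-by-descent signal the funnel must recover.
* Contigs are single 3'-biased fragments of the expressed transcripts
  (no read-level assembly: assembly internals are out of scope, and the
  funnel operates on contigs). Lengths are normal (mean 250, sd 60)
  clamped to 180-450 bp, the length scale of verifiable assembled contigs
  in this design; the 3' bias weights a fragment's start by
  `exp(beta * s / T)` (default beta 1.5), the exponential model chosen
  because the protocol states only the direction of the bias. The default
  contig error rate is 0: contigs model assembler consensus sequences.
* The genotype panel mirrors the crossing design: donor, recurrent parent,
  a relative, 4 + 4 apomictic/sexual backcross segregants and 10 + 12
  apomictic/sexual F1s. A quarter of the alien-chromosome genes are
  flagged as the ASGR block: apomictic F1s carry all donor haplotype-1
  loci, sexual F1s carry them *minus* the ASGR block (the donor's other
  chromosomes segregate into sexual F1s too, which is why most
  carrier-linked markers amplify both F1 classes and only ASGR-block
  markers are tightly linked).

What the generator does **not** emulate: sequencing-error profiles of any
real platform (homopolymer errors, quality values), read-level coverage
and mis-assembly, indel divergence (substitutions only by default — the
funnel's filters are substitution-sensitive and no indel statistics were
available to calibrate against), segregation of non-focal chromosomes
within a panel class (all members of a class share one genome), and any
real chromosome's gene content. Passing the recovery tests therefore shows
the *logic* of the funnel is sound under the stated divergence structure,
not that real assemblies of a particular depth would yield the same
counts.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere in R, with the
  BLAST-outfmt-6 convention (minus-strand hits as `sstart > send`) only in
  the tabular files.
* **Deduplication** of multiple matches between one contig pair keeps one
  verification per unordered pair, better strand by alignment score, ties
  to plus. The published counts do not fully pin down the pair-to-contig
  mapping rule; this choice is explicit and testable.
* **Alignment scores** (+1/−2/−4) affect only which rejection reason a
  failing pair gets, never acceptance, which requires a perfect flush
  overlap.
* **Marker design** spreads successive candidate placements across
  position bins of the candidate so that a locally conserved corner cannot
  exhaust the attempt budget, and tests at most 60 placements before
  declaring failure — a design *failure* is a recorded outcome, not an
  error, mirroring primer pairs that had to be redesigned or abandoned.
* **Degenerate inputs**: empty FASTA files read as empty libraries; an
  empty hit list filters to an empty comparison set; a transcript shorter
  than the minimum fragment yields no contig; summaries of zero accepted
  pairs flag their means as undefined rather than emitting NaNs silently.
* **Determinism**: a single integer seed fixes the generator byte-for-byte
  (the test suite compares FASTA md5s), and every pipeline stage is a pure
  function of its inputs, so re-running a stage from saved artifacts
  reproduces it exactly.

## Validation strategy

The test suite pits each engine against an independent oracle: the MEM
scanner against a quadratic all-common-substrings dynamic program (1000
random instances), the overlap aligner against a full scoring-matrix DP
with traceback, Fisher p-values against exhaustive hypergeometric
enumeration, and the 3'-bias sampler against numeric integration of its
density. End-to-end, twenty seeded replicates of the default synthetic
design must recover every detectable planted alien pair (sensitivity 1 at
zero contig error), classify every verified alien candidate as
carrier-linked — with exactly the ASGR-flagged genes tight — and produce
zero carrier-level calls involving a recurrent-origin contig.
`scripts/acceptance.R` re-runs this computation from scratch and writes
the measured quantities as JSON.

## Known limitations

* The in-silico PCR binding rule is a surrogate; its thresholds cannot be
  validated against the motivating study's primers, whose sequences are in
  a supplement that ships separately from the article text.
* With four homeologous donor copies at 2% divergence, occasional homeolog
  pairs survive zero-mismatch verification over short overlaps; they are
  caught at the panel-screening stage (exactly as in the wet protocol,
  where verified contigs still had to prove chromosome specificity by
  PCR).
* The published funnel counts (118 comparisons → 61 verified contigs)
  can only be reproduced from the deposited assemblies, which are too
  large to ship inside this package; the corresponding test states that
  requirement explicitly and fails — rather than silently skipping — when
  the files are absent.
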