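---
title: "Designing antisense PNAs and screening a holo-genome for off-targets"
author: "pnaScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing antisense PNAs and screening a holo-genome for off-targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnaScreen)
```

## The problem

Peptide nucleic acids (PNAs) are synthetic DNA analogues with a
pseudopeptide backbone. Conjugated to a cell-penetrating peptide (CPP), a
short antisense PNA can enter a bacterial cell, hybridise to an mRNA around
its translational start, and block ribosome assembly — a way to knock down
a gene in organisms that cannot be cultured or transformed, such as
*Buchnera aphidicola*, the obligate endosymbiont of the pea aphid. Because
effective CPP-PNAs are only ~10–12 bases long, a designed oligomer will
often match other loci by chance. Any credible design therefore needs an
off-target screen over every genome the molecule will meet *in vivo*: the
symbiont's **and** the host's, scanned jointly (the *holo-genome*).

`pnaScreen` implements that workflow: extract the start-codon window of a
target gene, emit the antisense PNA, locate every occurrence of a query
sequence or its reverse complement across one or more annotated genomes,
classify each occurrence by genomic context, and generate and validate
mismatch-control oligomers.

Throughout this package "TSS" means the **translational** start site — the
position of the start codon — not a transcription start site.

## The design rule

For a target transcript with start codon beginning at genomic position
$t$ (0-based, first base of the ATG), the target window spans coding-strand
offsets $-u..+d-1$ relative to $t$; the defaults $u = d = 5$ give the
classical $-5..+5$ ten-base window with the ATG at window bases $u..u+2$.
The window's *sense sequence* is read 5'→3' on the coding strand, so for a
minus-strand gene it is the reverse complement of the genomic slice, and
the upstream bases sit at *higher* genomic coordinates. The designed PNA,
written N-terminus→C-terminus, is identified with the antisense DNA strand
written 5'→3': the reverse complement of the sense window. A window sense
of `GTCAAATGGC` yields the PNA `GCCATTTGAC`.

```{r design}
fx <- buildFixture(defaultFixtureSpec(), tempfile("fx"))
g <- fx$genomes
holo <- lapply(seq_len(nrow(g)), function(i)
  readAnnotatedGenome(g$fasta[i], g$gff[i], g$genome_id[i]))
names(holo) <- g$genome_id

w <- extractStartWindow(holo$symbiont, transcriptId = "groL_t1")
w
designAntisense(w, "PNA_GroEL", nConjugate = "(RXR)4XB", cConjugate = "NH2")
```

Melting temperature is deliberately **not** predicted: no thermodynamic
model is bundled, and vendor-reported Tm values can be stored as opaque
metadata on a `PNAOligo`. Conjugates (CPPs, fluorophores, amide caps) are
likewise opaque labels; no chemistry is modelled. Window extraction always
uses the genomic sequence flanking the first CDS base, even for spliced
genes — a window whose footprint spans an intron is flagged
(`crossesSpliceJunction`) rather than stitched, since a spliced-transcript
design mode is out of scope.

## The off-target scan

`findExactMatches()` reports **every** position at which the query string
(orientation `forward`) or its reverse complement (orientation `revcomp`)
occurs in the + strand text, including overlapping occurrences.
Correctness is defined by a naive position-by-position comparison; the
shipped engine is a vectorised byte-wise comparison over whole contigs,
and the test suite holds the two equal on randomized genomes up to 50 kb.
Three semantics are worth making explicit:

* **Palindromes.** A query equal to its own reverse complement would
  otherwise be reported twice per position; it is reported once, with
  orientation `forward` — a deterministic tie-break, not a biological
  claim.
* **Ambiguity codes.** A genome `N` (or any non-ACGT IUPAC code) matches
  nothing in the default exact mode. `iupacGenome = TRUE` opts into
  treating codes as character classes (`R` matches a query `A` or `G`).
  The conservative default means hits are never invented inside gaps.
* **Mismatches.** `findMismatchMatches()` counts substitutions only
  (Hamming distance); PNA:RNA duplex mismatches are substitutional and no
  gap model is defined for them. At `k = 0` it reproduces the exact
  search; its hit set is non-decreasing in `k`.

`annotateHits()` classifies each hit with a fixed precedence:
`TSS_included > CDS_internal > exon > SD_region > intergenic`. A hit is
`TSS_included` when its footprint contains the *first base* of some start
codon. The field description this implements says only that a hit
"overlaps a TSS"; containing the single defining base is the unambiguous,
strand-symmetric reading, and the alternative (any of the three codon
bases) is available as `tssRule = "any-start-codon-base"`. The
Shine-Dalgarno window default, coding-strand offsets $-15..-5$, is the
canonical placement of the ribosome-binding motif in bacteria; it is
configurable, and SD overlap is reported as its own class, never merged
into `TSS_included`. Classification is orientation-agnostic: whether a
given match would actually titrate a ribosome depends on which strand is
transcribed, which the report leaves to the reader, listing the
contributing transcripts in `gene_ids`.

```{r scan}
res <- scanHoloGenome(c(PNA_GroEL = "GCCATTTGAC", PNA_mm = "GCGATTTGTC"),
                      unname(holo))
res$hits[, c("query_id", "genome_id", "start", "end", "orientation",
             "overlap_class", "gene_ids")]
res$summary
```

The per-genome summary counts hits, start-site hits, and
`n_genes_cds_overlap` — distinct genes whose CDS the query overlaps in
either orientation, the closest computable reading of "matches with
untargeted genes within coding regions". Whether that count should include
the intended target is a reporting choice; the summary includes it, and
the target contributes exactly one gene.

## Mismatch controls

A negative-control PNA should carry at least two substitutions: one
mismatch can still permit appreciable binding. `generateControls()`
enumerates all candidates at Hamming distance *exactly*
`minMismatches` (default 2) — all $\binom{L}{m}3^m$ of them at full
enumeration — because larger distances drift in base composition;
`atLeast = TRUE` relaxes the policy. No transversion bias is imposed: the
published control's two substitutions happen to be transversions, but no
selection rule to that effect is stated anywhere, so all three alternative
bases per position are enumerated. Terminal positions are mutable for the
same reason.

`validateControl()` passes a candidate iff an exact holo-genome scan finds
**zero** `TSS_included` hits; CDS-interior matches are counted but not
disqualifying, mirroring the acceptance of an active PNA that matches a
gene mid-CDS. Ranking is deterministic: pass before fail, fewer
CDS-interior hits, GC content closest to the parent (a crude proxy for a
similar melting temperature, absent any Tm model), then lexicographic
order.

```{r controls}
cand <- generateControls("GCCATTTGAC", maxCandidates = 6)
validateControls(cand, unname(holo), parent = "GCCATTTGAC")
```

## What the synthetic fixtures emulate — and what they do not

`buildFixture()` turns a declarative `FixtureSpec` into FASTA + GFF3 +
ground truth. Backgrounds are i.i.d. bases at a stated GC fraction; genes
are spliced in with an ATG...TAA coding sequence; planted query
occurrences overwrite the background at declared coordinates. The builder
*verifies* rather than assumes: every planted query must occur exactly
where planted (in either orientation, across **all** genomes) and every
declared-absent query nowhere; on a chance background collision it redraws
the background up to a bounded retry count, then errors, so ground truth
is exact, not probabilistic. Each plant's intended context class is
re-derived by brute-force interval checks at build time, and the same
spec + seed is byte-identical across runs (integer coordinates, one
Mersenne-Twister stream, no locale dependence).

Two ready-made specs ship with the package:

* `defaultFixtureSpec()` — a 5 kb, 30% GC "symbiont" (three genes: a
  groEL-like target whose −5..+5 window designs to `GCCATTTGAC`, a
  pyrG-like gene carrying the same 10-mer mid-CDS, and a minus-strand
  gene) plus a 20 kb, 35% GC "host" (five genes including one spliced
  gene and a decoy start-site occurrence for the single-mismatch variant
  `ACCATTTGAC`). The sizes keep a full property-based test run in seconds
  while exercising every hit class, both strands, and splicing.
* `syntheticBuchneraFixtureSpec()` — a single 21 kb, 26% GC contig whose
  groEL gene model reproduces the published *Buchnera aphidicola* str.
  APS geometry (CDS 18,715–20,361, 1,647 bp, plus strand) with a pyrG
  gene carrying the anti-groEL 10-mer mid-CDS. It is **synthetic**: only
  the gene geometry is real, the sequence between planted windows is
  random. It demonstrates coordinate and classification fidelity offline;
  it says nothing about how many off-targets the real 641 kb chromosome
  or a real host assembly would contain.

That last caveat generalises. Random i.i.d. backgrounds contain no
repeats, no compositional skew, no gene-dense operons; a passing test
shows the *machinery* is correct (coordinates, strands, classes,
completeness of the scan), not that any particular real genome is clean
for a given oligomer. Real screens should be run on real FASTA + GFF3
inputs — the code path is identical. Published host-genome off-target
counts for a 10-mer (tens of genes with CDS matches) also depend on which
annotation release is scanned, which is why no such count is asserted
anywhere in this package's tests.

## Numerical and interface choices

* **Coordinates.** Everything internal is 0-based half-open; all file
  I/O — GFF3 in, report TSV out — is 1-based inclusive, so GFF
  `101..160` becomes `[100,160)` internally and is printed back as
  `101..160`. Half-open arithmetic removes the ±1 traps from window and
  overlap math; the file dialects stay native.
* **Sorting.** Hits are sorted by (genome, contig, start, orientation);
  report writing and re-reading is field-for-field stable; all four CLI
  subcommands are byte-identical across re-runs.
* **Parsing.** FASTA headers are cut at the first whitespace; lowercase
  (soft-masked) sequence is uppercased and treated as unmasked, since the
  screen is genome-wide with no masking semantics. GFF3 feature-to-
  transcript resolution is Parent, then ID, then gene/locus_tag, with a
  logged message on fallback; bacterial GFFs lacking exon rows get exons
  copied from CDS; transcripts with no CDS are skipped with a warning.
* **Degenerate inputs.** Empty queries, mismatch budgets ≥ query length,
  windows leaving the contig, and hits on unannotated contigs are
  errors; a query longer than every contig is an empty result.
* **CLI.** `pna-screen design|scan|control|simulate` (installed under
  `system.file("scripts", ...)`) wires these functions together. Genome
  sets come from a YAML config (repeatable paired paths make poor flags);
  logs go to stderr, data only to files; exit 0 on success, 2 on
  validation errors with a one-line diagnostic.

## Problem sizes used by the shipped checks

The property-based suite holds the scanner equal to an independent naive
oracle on 200 randomized instances up to 50 kb (queries 6–15 nt, planted
occurrences, palindromic and overlapping cases), checks strand symmetry on
the same instances, and verifies planted-site completeness and control
validation on the default fixture; the whole suite runs in under two
minutes on one core. The standalone acceptance script re-runs the design,
screen, control validation, and a 100-instance oracle comparison from
scratch and writes the resulting quantities as JSON.

## Known limitations

* Exact and Hamming matching only — no indels, no local alignment, no
  thermodynamic ranking of near-matches, no RNA-accessibility model.
* Tm is never computed; controls are GC-matched at best.
* One annotation dialect (GFF3). No GenBank flat files, GTF, or
  compressed indexes.
* The orientation-agnostic classifier flags genomic context, not
  predicted silencing; interpreting a `CDS_internal` match as harmless is
  a judgement the report supports but does not make.
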