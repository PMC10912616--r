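# pnaScreen

Antisense PNA design and holo-genome off-target screening.

## What this is for

Peptide nucleic acids (PNAs) conjugated to cell-penetrating peptides can
silence a bacterial gene by hybridising to its mRNA around the
translational start codon — a route to gene knockdown in unculturable,
untransformable bacteria such as insect endosymbionts. Effective CPP-PNAs
are only ~10 bases long, so a designed oligomer can match other loci by
chance, in the symbiont **or in its host**. `pnaScreen` is for researchers
designing such molecules: it extracts the start-codon window of a target
gene, emits the antisense PNA, finds every exact (or k-mismatch)
occurrence of the oligomer and its reverse complement across all supplied
genomes (the *holo-genome*), classifies each occurrence by genomic
context, and generates and validates mismatch-control PNAs.

The core conventions, in the field's standard notation:

- **Target window**: coding-strand positions −u..+d around the first base
  of the start codon; defaults u = d = 5, the −5..+5 ten-base window with
  the ATG at window bases 6–8 (1-based).
- **Antisense PNA**: written N→C, identified with the antisense DNA
  strand 5'→3', i.e. the reverse complement of the window sense sequence.
- **Hit**: a genomic interval where the query (orientation `forward`) or
  its reverse complement (`revcomp`) occurs on the + strand text, Hamming
  distance ≤ k (default 0, substitutions only).
- **Context classes**, in precedence order: `TSS_included` (footprint
  contains the first base of a start codon; "TSS" here is the
  *translational* start site), `CDS_internal`, `exon`, `SD_region`
  (coding-strand offsets −15..−5 by default), `intergenic`.
- **Mismatch control**: a variant at Hamming distance exactly 2 from the
  parent (configurable), valid iff it has **zero** perfect matches at any
  translational start site in every scanned genome.

## Worked example

The package ships a deterministic fixture generator; `defaultFixtureSpec()`
describes a 5 kb symbiont genome (groEL-like target, pyrG-like gene
carrying the same 10-mer mid-CDS, one minus-strand gene) and a 20 kb host
genome (five genes, one spliced, one decoy start site for a single-mismatch
variant).

```r
library(pnaScreen)

fx <- buildFixture(defaultFixtureSpec(), tempfile("fx"))
g <- fx$genomes
holo <- lapply(seq_len(nrow(g)), function(i)
  readAnnotatedGenome(g$fasta[i], g$gff[i], g$genome_id[i]))
names(holo) <- g$genome_id

w <- extractStartWindow(holo$symbiont, transcriptId = "groL_t1")
w
#> TargetWindow groL_t1 [symbiont:sym1 1195-1204 +] -5..+5 sense 5'-GTCAAATGGC-3'
designAntisense(w, "PNA_GroEL", nConjugate = "(RXR)4XB", cConjugate = "NH2")
#> PNAOligo PNA_GroEL: (RXR)4XB-O-gccatttgac-NH2 (10 bases, N->C)
```

The window sense reads `GTCAAATGGC` (five bases upstream, then `ATG`, then
two more), so the antisense PNA is its reverse complement, `GCCATTTGAC`.
Screening it and a two-mismatch control across both genomes:

```r
res <- scanHoloGenome(c(PNA_GroEL = "GCCATTTGAC", PNA_mm = "GCGATTTGTC"),
                      unname(holo))
res$summary
#>    query_id genome_id n_hits n_TSS_included n_genes_cds_overlap
#> 1 PNA_GroEL  symbiont      2              1                   2
#> 2    PNA_mm  symbiont      0              0                   0
#> 3 PNA_GroEL      host      0              0                   0
#> 4    PNA_mm      host      0              0                   0
```

`PNA_GroEL` hits the symbiont twice: once *at* the target's translational
start (the on-target site, class `TSS_included`, gene `groL_t1`) and once
inside the coding region of the pyrG-like gene (`CDS_internal`) — a match
the start-site rule tolerates, because mid-CDS sites are far less
sensitive to antisense inhibition. The control hits nothing. Validating it
explicitly:

```r
validateControl("GCGATTTGTC", unname(holo))
#>   candidate_seq validation n_tss_hits n_cds_hits
#> 1    GCGATTTGTC       pass          0          0
```

`generateControls()` enumerates all 405 two-mismatch variants of a 10-mer
and `validateControls()` ranks them (pass first, fewer CDS-interior hits,
GC closest to parent). `hammingDistance("GCCATTTGAC", "GCGATTTGTC")` is 2,
at positions 3 and 9 (`mismatchPositions()`).

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
PNA=$(Rscript -e 'cat(system.file("scripts", "pna-screen", package = "pnaScreen"))')
$PNA simulate --default-fixture --out-dir fx
$PNA design --fasta fx/symbiont.fasta --gff fx/symbiont.gff3 \
    --genome-id symbiont --transcript groL_t1 --out design.tsv
$PNA scan --query design.tsv --config holo.yaml --out-dir scanout
$PNA control --parent GCCATTTGAC --config holo.yaml --out controls.tsv
```

`holo.yaml` lists the genome set (`genomes:` with `fasta`/`gff`/
`genome_id` per entry). Logs go to stderr, data to files; exit status is 0
on success, 2 on validation errors.

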