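#' Reverse complement of a nucleotide sequence
#'
#' IUPAC-aware (N<->N, R<->Y, and so on); input is validated and uppercased.
#'
#' @param seq a single character string over the IUPAC nucleotide alphabet.
#' @return the reverse complement, uppercase.
#' @examples
#' revComp("GCCATTTGAC")  # "GTCAAATGGC"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (!nzchar(seq)) return("")
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), seq)
  if (bad > 0L)
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the translational start window of a transcript
#'
#' Returns the `-upstream..+downstream` window around the first base of the
#' annotated start codon, on the coding strand. The genomic footprint is the
#' contiguous genomic interval flanking the first CDS base — even for spliced
#' genes, in which case `crossesSpliceJunction` is flagged when the footprint
#' spans a gap between the transcript's segments.
#'
#' @param models a [GeneModels] (or [AnnotatedGenome]).
#' @param genome the companion [GenomeSet]; may be omitted when `models` is
#'   an [AnnotatedGenome].
#' @param transcriptId transcript to extract.
#' @param upstream bases 5' of the start codon's first base (>= 0, default 5).
#' @param downstream bases from the start codon's first base onward
#'   (>= 3 so the window always spans the whole start codon; default 5).
#' @return a [TargetWindow].
#' @examples
#' \donttest{
#' fx <- buildFixture(defaultFixtureSpec(), tempfile("fx"))
#' ag <- readAnnotatedGenome(fx$genomes$fasta[1], fx$genomes$gff[1],
#'                           fx$genomes$genome_id[1])
#' extractStartWindow(ag, transcriptId = "groL_t1")
#' }
#' @export
extractStartWindow <- function(models, genome = NULL, transcriptId,
                               upstream = 5L, downstream = 5L) {
  if (is(models, "AnnotatedGenome")) {
    genome <- models@genome
    models <- models@models
  }
  if (is.null(genome))
    stop("a GenomeSet must be supplied alongside GeneModels")
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  if (is.na(upstream) || upstream < 0L)
    stop("upstream must be >= 0")
  if (is.na(downstream) || downstream < 3L)
    stop("downstream must be >= 3")
  tr <- models@transcripts
  i <- match(transcriptId, tr$transcript_id)
  if (is.na(i))
    stop(sprintf("unknown transcript '%s' in genome '%s'", transcriptId,
                 models@genomeId))
  strand <- tr$strand[i]
  tss0 <- tr$tss0[i]
  contig <- tr$contig_id[i]
  clen <- contigLengths(genome)[[contig]]
  # genomic footprint: upstream bases are 5' on the coding strand
  if (strand == "+") {
    s0 <- tss0 - upstream
    e0 <- tss0 + downstream
  } else {
    s0 <- tss0 - downstream + 1L
    e0 <- tss0 + upstream + 1L
  }
  if (s0 < 0L || e0 > clen)
    stop(sprintf("window out of bounds for '%s' ([%d,%d) on %s of length %d)",
                 transcriptId, s0, e0, contig, clen))
  slice <- substr(contigSeq(genome, contig), s0 + 1L, e0)
  sense <- if (strand == "+") slice else revComp(slice)
  seg <- models@segments
  seg <- seg[seg$transcript_id == transcriptId, , drop = FALSE]
  # footprint crosses a splice junction if any inter-segment gap intersects it
  crosses <- FALSE
  for (type in unique(seg$type)) {
    s <- seg[seg$type == type, , drop = FALSE]
    s <- s[order(s$start0), , drop = FALSE]
    if (nrow(s) > 1L) {
      gaps_s <- s$end0[-nrow(s)]
      gaps_e <- s$start0[-1L]
      if (any(gaps_s < e0 & gaps_e > s0)) crosses <- TRUE
    }
  }
  w <- new("TargetWindow", transcriptId = transcriptId,
           genomeId = models@genomeId, contigId = contig, strand = strand,
           start0 = as.integer(s0), end0 = as.integer(e0),
           senseSequence = sense, upstream = upstream,
           downstream = downstream, crossesSpliceJunction = crosses)
  validObject(w)
  w
}

#' Design the antisense PNA for a target window
#'
#' The PNA base sequence, written N-terminus to C-terminus, is the reverse
#' complement of the window's sense sequence (the convention in which a
#' 10-mer PNA against a -5..+5 window reads as the antisense DNA strand
#' 5'->3'). Conjugate labels are attached verbatim as metadata; no chemistry
#' or melting temperature is modelled.
#'
#' @param window a [TargetWindow].
#' @param pnaId label for the oligomer.
#' @param nConjugate,cConjugate free-text N-/C-terminal conjugate labels,
#'   e.g. a cell-penetrating peptide such as `"(RXR)4XB"` and `"NH2"`.
#' @param metadata optional named list (e.g. a vendor-supplied Tm).
#' @return a [PNAOligo] with `sourceWindow` recorded.
#' @export
designAntisense <- function(window, pnaId, nConjugate = "", cConjugate = "",
                            metadata = list()) {
  stopifnot(is(window, "TargetWindow"))
  p <- new("PNAOligo", pnaId = as.character(pnaId),
           baseSequence = revComp(window@senseSequence),
           nTerminalConjugate = as.character(nConjugate),
           cTerminalConjugate = as.character(cConjugate),
           sourceWindow = window, metadata = metadata)
  validObject(p)
  p
}

#' Construct a PNAOligo from a raw base sequence
#'
#' For user-supplied oligomers with no design window.
#'
#' @param pnaId label.
#' @param baseSequence bases over {A,C,G,T}, N-terminus to C-terminus.
#' @param nConjugate,cConjugate conjugate labels.
#' @param metadata optional named list.
#' @return a [PNAOligo].
#' @export
pnaOligo <- function(pnaId, baseSequence, nConjugate = "", cConjugate = "",
                     metadata = list()) {
  p <- new("PNAOligo", pnaId = as.character(pnaId),
           baseSequence = toupper(as.character(baseSequence)),
           nTerminalConjugate = as.character(nConjugate),
           cTerminalConjugate = as.character(cConjugate),
           sourceWindow = NULL, metadata = metadata)
  validObject(p)
  p
}
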