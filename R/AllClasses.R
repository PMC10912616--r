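#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' GenomeSet: the contigs of one named genome
#'
#' A thin container pairing a genome label with a set of named contig
#' sequences. Sequences are stored uppercased; only IUPAC nucleotide letters
#' are permitted, and contig identifiers must be unique within the genome.
#'
#' @slot genomeId single character label for the genome.
#' @slot sequences a [Biostrings::DNAStringSet] named by contig identifier.
#'
#' @seealso [readGenomeFasta()], [genomeId()], [contigIds()]
#' @exportClass GenomeSet
setClass("GenomeSet",
         representation(genomeId = "character",
                        sequences = "DNAStringSet"))

setValidity("GenomeSet", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  nm <- names(object@sequences)
  if (is.null(nm) || any(!nzchar(nm)))
    msg <- c(msg, "every contig must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicate contig_id within genome '%s': %s",
                          object@genomeId,
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "empty contig sequence")
  if (length(msg)) msg else TRUE
})

#' GeneModels: strand-aware gene models for one genome
#'
#' Holds per-transcript translational start sites and the CDS/exon segments
#' of every transcript, together with a prebuilt interval index used for
#' overlap classification. Coordinates in the `transcripts` and `segments`
#' slots are internal 0-based half-open; the index is an equivalent
#' [GenomicRanges::GRanges] (1-based) used only for overlap queries.
#'
#' @slot genomeId single character label, matching the companion [GenomeSet].
#' @slot transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `contig_id`, `strand` (`+`/`-`) and `tss0`, the 0-based genomic
#'   coordinate of the first base of the start codon (smallest CDS start on
#'   `+`, largest CDS end minus one on `-`).
#' @slot segments data.frame with columns `transcript_id`, `type`
#'   (`"cds"`/`"exon"`), `contig_id`, `strand`, `start0`, `end0`
#'   (0-based half-open), sorted in genomic order within transcript/type.
#' @slot index GRanges over all segments plus one 1-bp range per start-codon
#'   base, with metadata columns `transcript_id` and `type`.
#'
#' @seealso [readGeneModels()], [annotateHits()]
#' @exportClass GeneModels
setClass("GeneModels",
         representation(genomeId = "character",
                        transcripts = "data.frame",
                        segments = "data.frame",
                        index = "GRanges"))

setValidity("GeneModels", function(object) {
  msg <- character()
  tr <- object@transcripts
  seg <- object@segments
  need_tr <- c("transcript_id", "gene_id", "contig_id", "strand", "tss0")
  need_seg <- c("transcript_id", "type", "contig_id", "strand",
                "start0", "end0")
  if (!all(need_tr %in% names(tr)))
    return("transcripts slot is missing required columns")
  if (!all(need_seg %in% names(seg)))
    return("segments slot is missing required columns")
  if (anyDuplicated(tr$transcript_id))
    msg <- c(msg, "duplicate transcript_id within one genome")
  if (nrow(seg) && any(seg$end0 <= seg$start0))
    msg <- c(msg, "segment with non-positive width")
  cds <- seg[seg$type == "cds", , drop = FALSE]
  if (nrow(cds)) {
    by_tr <- split(cds, cds$transcript_id)
    for (tid in names(by_tr)) {
      s <- by_tr[[tid]]
      o <- order(s$start0)
      if (any(s$start0 != sort(s$start0)))
        msg <- c(msg, sprintf("CDS segments of '%s' not in genomic order", tid))
      s <- s[o, , drop = FALSE]
      if (nrow(s) > 1L && any(s$start0[-1L] < s$end0[-nrow(s)]))
        msg <- c(msg, sprintf("overlapping CDS segments in '%s'", tid))
      i <- match(tid, tr$transcript_id)
      expect_tss <- if (tr$strand[i] == "+") min(s$start0) else max(s$end0) - 1L
      if (tr$tss0[i] != expect_tss)
        msg <- c(msg, sprintf(
          "tss0 of '%s' disagrees with first CDS base in transcription order",
          tid))
    }
  }
  if (length(msg)) msg else TRUE
})

#' AnnotatedGenome: a genome paired with its gene models
#'
#' The scan unit for holo-genome screening: one [GenomeSet] and the
#' [GeneModels] built against it.
#'
#' @slot genome a [GenomeSet].
#' @slot models a [GeneModels] with the same `genomeId`.
#'
#' @seealso [readAnnotatedGenome()], [scanHoloGenome()]
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
         representation(genome = "GenomeSet", models = "GeneModels"))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  if (object@genome@genomeId != object@models@genomeId)
    msg <- c(msg, "genome and models carry different genomeId")
  known <- names(object@genome@sequences)
  used <- unique(c(object@models@transcripts$contig_id,
                   object@models@segments$contig_id))
  missing <- setdiff(used, known)
  if (length(missing))
    msg <- c(msg, sprintf("gene models refer to unknown contig(s): %s",
                          paste(missing, collapse = ", ")))
  # every CDS segment within contig bounds
  seg <- object@models@segments
  if (nrow(seg)) {
    lens <- Biostrings::width(object@genome@sequences)[
      match(seg$contig_id, known)]
    if (any(seg$start0 < 0L) || any(seg$end0 > lens))
      msg <- c(msg, "segment outside contig bounds")
  }
  if (length(msg)) msg else TRUE
})

#' TargetWindow: the translational start window of one transcript
#'
#' The -u..+d window around the first base of the start codon, on the coding
#' strand. `senseSequence` is read 5'->3' on the coding strand, so for
#' minus-strand genes it is the reverse complement of the genomic slice.
#'
#' @slot transcriptId,genomeId,contigId character labels.
#' @slot strand `"+"` or `"-"`.
#' @slot start0,end0 0-based half-open genomic footprint of the window.
#' @slot senseSequence window sequence, 5'->3' on the coding strand.
#' @slot upstream,downstream integer offsets u and d; window length is u + d
#'   and bases u..u+2 are the start codon whenever d >= 3.
#' @slot crossesSpliceJunction TRUE when the genomic footprint spans a gap
#'   between CDS/exon segments of the transcript.
#'
#' @seealso [extractStartWindow()], [designAntisense()]
#' @exportClass TargetWindow
setClass("TargetWindow",
         representation(transcriptId = "character", genomeId = "character",
                        contigId = "character", strand = "character",
                        start0 = "integer", end0 = "integer",
                        senseSequence = "character",
                        upstream = "integer", downstream = "integer",
                        crossesSpliceJunction = "logical"))

setValidity("TargetWindow", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (nchar(object@senseSequence) != object@upstream + object@downstream)
    msg <- c(msg, "sense sequence length must equal upstream + downstream")
  if (object@end0 - object@start0 != object@upstream + object@downstream)
    msg <- c(msg, "genomic interval length must equal upstream + downstream")
  if (object@downstream >= 3L) {
    codon <- substr(object@senseSequence, object@upstream + 1L,
                    object@upstream + 3L)
    if (codon != "ATG")
      msg <- c(msg, sprintf("bases u..u+2 are '%s', not the start codon", codon))
  }
  if (length(msg)) msg else TRUE
})

#' PNAOligo: a designed or user-supplied PNA
#'
#' The base sequence is written N-terminus to C-terminus, which for an
#' antisense PNA designed by [designAntisense()] is identified with the
#' antisense DNA strand written 5'->3': the reverse complement of the target
#' window's sense sequence. Conjugate labels (cell-penetrating peptide,
#' fluorophore, amide) are opaque strings; no chemistry is modelled, and no
#' melting temperature is predicted (user-supplied Tm may be stored in
#' `metadata`).
#'
#' @slot pnaId character label.
#' @slot baseSequence bases over {A,C,G,T}, N-terminus to C-terminus.
#' @slot nTerminalConjugate,cTerminalConjugate free-text conjugate labels.
#' @slot sourceWindow the [TargetWindow] it was designed from, or NULL.
#' @slot metadata named list of optional user-supplied annotations.
#'
#' @seealso [designAntisense()], [pnaSequence()]
#' @exportClass PNAOligo
setClass("PNAOligo",
         representation(pnaId = "character", baseSequence = "character",
                        nTerminalConjugate = "character",
                        cTerminalConjugate = "character",
                        sourceWindow = "ANY", metadata = "list"))

setValidity("PNAOligo", function(object) {
  msg <- character()
  if (!grepl("^[ACGT]+$", object@baseSequence))
    msg <- c(msg, "base sequence must be non-empty over {A,C,G,T}")
  if (!is.null(object@sourceWindow)) {
    if (!is(object@sourceWindow, "TargetWindow"))
      msg <- c(msg, "sourceWindow must be a TargetWindow or NULL")
    else if (object@baseSequence !=
             revComp(object@sourceWindow@senseSequence))
      msg <- c(msg, "base sequence must be the reverse complement of the source window")
  }
  if (length(msg)) msg else TRUE
})

#' FixtureSpec: declarative description of a synthetic annotated genome set
#'
#' Drives [buildFixture()]. All coordinates here are 1-based (matching the
#' emitted GFF3); the builder converts internally.
#'
#' @slot seed integer seed for the pseudo-random background (required; no
#'   wall-clock default).
#' @slot contigs data.frame: `genome_id`, `contig_id`, `length`, `gc`
#'   (background GC fraction in \[0,1\]).
#' @slot genes data.frame: `gene_id`, `transcript_id`, `genome_id`,
#'   `contig_id`, `strand`, `tss1` (1-based first base of the start codon on
#'   the coding strand), `cds_length` (multiple of 3), `intron_offset`
#'   (bases of CDS before the intron, NA for none), `intron_length`,
#'   `emit_exons` (write exon rows to the GFF3).
#' @slot plants data.frame: `query`, `genome_id`, `contig_id`, `pos1`,
#'   `orientation` (`forward`/`revcomp`), `intended_class`. The genomic text
#'   written at `pos1` is the query itself (forward) or its reverse
#'   complement (revcomp).
#' @slot absentQueries queries the builder guarantees occur nowhere in the
#'   emitted genomes, in either orientation.
#'
#' @seealso [fixtureSpec()], [buildFixture()], [defaultFixtureSpec()]
#' @exportClass FixtureSpec
setClass("FixtureSpec",
         representation(seed = "integer", contigs = "data.frame",
                        genes = "data.frame", plants = "data.frame",
                        absentQueries = "character"))

## ---- accessors & show ------------------------------------------------------

#' Accessors for pnaScreen objects
#'
#' `genomeId()` returns the genome label; `contigIds()` and
#' `contigLengths()` describe a [GenomeSet]'s contigs; `contigSeq()` returns
#' one contig as a character string. `transcripts()` and `segmentTable()`
#' return the coordinate tables of a [GeneModels] (0-based half-open).
#' `senseSequence()` and `pnaSequence()` extract sequences from a
#' [TargetWindow] and [PNAOligo].
#'
#' @param x a pnaScreen object.
#' @param contigId single contig identifier.
#' @return see details above.
#' @name accessors
#' @aliases genomeId contigIds contigLengths contigSeq transcripts
#'   segmentTable senseSequence pnaSequence pnaId
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))
#' @rdname accessors
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))
#' @rdname accessors
#' @export
setGeneric("contigSeq", function(x, contigId) standardGeneric("contigSeq"))
#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("senseSequence", function(x) standardGeneric("senseSequence"))
#' @rdname accessors
#' @export
setGeneric("pnaSequence", function(x) standardGeneric("pnaSequence"))
#' @rdname accessors
#' @export
setGeneric("pnaId", function(x) standardGeneric("pnaId"))

#' @rdname accessors
setMethod("genomeId", "GenomeSet", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeId", "GeneModels", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeId", "AnnotatedGenome", function(x) x@genome@genomeId)
#' @rdname accessors
setMethod("contigIds", "GenomeSet", function(x) names(x@sequences))
#' @rdname accessors
setMethod("contigLengths", "GenomeSet", function(x) {
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})
#' @rdname accessors
setMethod("contigSeq", "GenomeSet", function(x, contigId) {
  if (!contigId %in% names(x@sequences))
    stop(sprintf("unknown contig '%s' in genome '%s'", contigId, x@genomeId))
  as.character(x@sequences[[contigId]])
})
#' @rdname accessors
setMethod("transcripts", "GeneModels", function(x) x@transcripts)
#' @rdname accessors
setMethod("segmentTable", "GeneModels", function(x) x@segments)
#' @rdname accessors
setMethod("transcripts", "AnnotatedGenome", function(x) x@models@transcripts)
#' @rdname accessors
setMethod("senseSequence", "TargetWindow", function(x) x@senseSequence)
#' @rdname accessors
setMethod("pnaSequence", "PNAOligo", function(x) x@baseSequence)
#' @rdname accessors
setMethod("pnaId", "PNAOligo", function(x) x@pnaId)

#' Genome sequences of a GenomeSet
#' @param x a GenomeSet or AnnotatedGenome.
#' @return a [Biostrings::DNAStringSet] named by contig.
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname genomeSequences
setMethod("genomeSequences", "GenomeSet", function(x) x@sequences)
#' @rdname genomeSequences
setMethod("genomeSequences", "AnnotatedGenome", function(x) x@genome@sequences)

#' Gene models of an AnnotatedGenome
#' @param x an AnnotatedGenome.
#' @return the [GeneModels] component.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname geneModels
setMethod("geneModels", "AnnotatedGenome", function(x) x@models)

setMethod("show", "GenomeSet", function(object) {
  cat(sprintf("GenomeSet '%s': %d contig(s), %s bp total\n",
              object@genomeId, length(object@sequences),
              format(sum(Biostrings::width(object@sequences)),
                     big.mark = ",")))
  for (nm in utils::head(names(object@sequences), 5L))
    cat(sprintf("  %s (%d bp)\n", nm,
                Biostrings::width(object@sequences[nm])))
  if (length(object@sequences) > 5L) cat("  ...\n")
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels for genome '%s': %d transcript(s), %d segment(s)\n",
              object@genomeId, nrow(object@transcripts),
              nrow(object@segments)))
})

setMethod("show", "AnnotatedGenome", function(object) {
  show(object@genome)
  show(object@models)
})

setMethod("show", "TargetWindow", function(object) {
  cat(sprintf(
    "TargetWindow %s [%s:%s %d-%d %s] -%d..+%d sense 5'-%s-3'%s\n",
    object@transcriptId, object@genomeId, object@contigId,
    object@start0 + 1L, object@end0, object@strand,
    object@upstream, object@downstream, object@senseSequence,
    if (object@crossesSpliceJunction) " [crosses splice junction]" else ""))
})

setMethod("show", "PNAOligo", function(object) {
  cat(sprintf("PNAOligo %s: %s-O-%s-%s (%d bases, N->C)\n",
              object@pnaId,
              if (nzchar(object@nTerminalConjugate))
                object@nTerminalConjugate else "H",
              tolower(object@baseSequence),
              if (nzchar(object@cTerminalConjugate))
                object@cTerminalConjugate else "OH",
              nchar(object@baseSequence)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: seed %d, %d contig(s) in %d genome(s), %d gene(s), %d plant(s)\n",
    object@seed, nrow(object@contigs),
    length(unique(object@contigs$genome_id)), nrow(object@genes),
    nrow(object@plants)))
})
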