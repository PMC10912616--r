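#' Read a genome FASTA into a GenomeSet
#'
#' Reads a (possibly multi-record, wrapped or unwrapped) FASTA file. The
#' header token before the first whitespace becomes the contig identifier.
#' Sequences are uppercased — soft-masked lowercase is treated as unmasked —
#' and must contain only IUPAC nucleotide letters after normalisation.
#'
#' @param path path to a FASTA file.
#' @param genomeId label for the genome the records belong to.
#' @return a [GenomeSet].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1 demo", "acgtACGT"), fa)
#' gs <- readGenomeFasta(fa, "demo")
#' contigSeq(gs, "chr1")  # "ACGTACGT"
#' @export
readGenomeFasta <- function(path, genomeId) {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e))))
  if (length(seqs) == 0L)
    stop(sprintf("malformed FASTA '%s': no records", path))
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  for (i in seq_along(chars)) {
    if (!nzchar(chars[[i]]))
      stop(sprintf("malformed FASTA '%s': record '%s' (record %d) is empty",
                   path, ids[[i]], i))
    bad <- regmatches(chars[[i]],
                      regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS,
                                                     collapse = "")),
                              chars[[i]]))
    if (length(bad))
      stop(sprintf(
        "malformed FASTA '%s': record '%s' (record %d) contains non-IUPAC character '%s'",
        path, ids[[i]], i, bad))
  }
  if (anyDuplicated(ids))
    stop(sprintf("malformed FASTA '%s': duplicate contig_id '%s'",
                 path, ids[duplicated(ids)][1L]))
  gs <- new("GenomeSet", genomeId = as.character(genomeId),
            sequences = stats::setNames(Biostrings::DNAStringSet(chars), ids))
  validObject(gs)
  gs
}

#' Construct GeneModels from coordinate tables
#'
#' Low-level constructor used by [readGeneModels()] and the fixture builder.
#' Coordinates are internal 0-based half-open. Transcripts with no exon rows
#' get `exon` segments copied from their CDS (bacterial GFFs often omit exon
#' features). The start-codon interval index is derived per strand.
#'
#' @param genomeId genome label.
#' @param transcripts data.frame with `transcript_id`, `gene_id`,
#'   `contig_id`, `strand`; `tss0` is derived here and may be omitted.
#' @param segments data.frame with `transcript_id`, `type` (`cds`/`exon`),
#'   `contig_id`, `strand`, `start0`, `end0`.
#' @param genome optional [GenomeSet] used to check contig bounds.
#' @return a [GeneModels].
#' @export
makeGeneModels <- function(genomeId, transcripts, segments, genome = NULL) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    segments <- segments[order(segments$transcript_id,
                               segments$type, segments$start0), , drop = FALSE]
    rownames(segments) <- NULL
  }
  cds <- segments[segments$type == "cds", , drop = FALSE]
  tss0 <- vapply(transcripts$transcript_id, function(tid) {
    s <- cds[cds$transcript_id == tid, , drop = FALSE]
    if (!nrow(s)) return(NA_integer_)
    if (transcripts$strand[match(tid, transcripts$transcript_id)] == "+")
      min(s$start0) else max(s$end0) - 1L
  }, integer(1))
  transcripts$tss0 <- tss0
  # exon default: copy CDS for transcripts with no exon rows
  has_exon <- unique(segments$transcript_id[segments$type == "exon"])
  need <- setdiff(unique(cds$transcript_id), has_exon)
  if (length(need)) {
    ex <- cds[cds$transcript_id %in% need, , drop = FALSE]
    ex$type <- "exon"
    segments <- rbind(segments, ex)
    segments <- segments[order(segments$transcript_id, segments$type,
                               segments$start0), , drop = FALSE]
    rownames(segments) <- NULL
  }
  idx <- .buildSegmentIndex(transcripts, segments)
  gm <- new("GeneModels", genomeId = as.character(genomeId),
            transcripts = transcripts, segments = segments, index = idx)
  validObject(gm)
  if (!is.null(genome)) {
    lens <- contigLengths(genome)
    missing <- setdiff(unique(c(transcripts$contig_id, segments$contig_id)),
                       names(lens))
    if (length(missing))
      stop(sprintf("gene models refer to contig(s) absent from genome '%s': %s",
                   genomeId(genome), paste(missing, collapse = ", ")))
    if (nrow(segments)) {
      over <- segments$end0 > lens[segments$contig_id] | segments$start0 < 0L
      if (any(over))
        stop(sprintf("CDS/exon segment of '%s' extends beyond contig '%s'",
                     segments$transcript_id[over][1L],
                     segments$contig_id[over][1L]))
    }
  }
  gm
}

# GRanges index over segments and per-base start codons (1-based internally)
.buildSegmentIndex <- function(transcripts, segments) {
  gr_seg <- if (nrow(segments)) {
    GenomicRanges::GRanges(
      seqnames = segments$contig_id,
      ranges = IRanges::IRanges(start = segments$start0 + 1L,
                                end = segments$end0),
      transcript_id = segments$transcript_id, type = segments$type)
  } else GenomicRanges::GRanges(transcript_id = character(),
                                type = character())
  tr <- transcripts[!is.na(transcripts$tss0), , drop = FALSE]
  gr_tss <- if (nrow(tr)) {
    GenomicRanges::GRanges(
      seqnames = tr$contig_id,
      ranges = IRanges::IRanges(start = tr$tss0 + 1L, width = 1L),
      transcript_id = tr$transcript_id, type = "tss")
  } else GenomicRanges::GRanges(transcript_id = character(),
                                type = character())
  suppressWarnings(c(gr_seg, gr_tss))
}

#' Read GFF3 gene annotation into GeneModels
#'
#' Parses a GFF3 file (version directives tolerated, comments ignored) and
#' builds one gene model per transcript from its CDS and exon features. GFF
#' 1-based inclusive coordinates become internal 0-based half-open. The
#' translational start site is the first CDS base in transcription order:
#' smallest CDS start on `+`, largest CDS end minus one on `-`.
#'
#' Feature-to-transcript resolution follows Parent, then ID, then a
#' gene/locus_tag fallback (a message is logged when the fallback is used).
#' mRNA/gene parents are resolved so that `gene_id` reflects the enclosing
#' gene where one is annotated. Transcripts lacking any CDS are skipped with
#' a warning; features whose Parent cannot be resolved at all are skipped
#' with a warning.
#'
#' @param path path to a GFF3 file.
#' @param genome the companion [GenomeSet] (used for contig-bound checks).
#' @return a [GeneModels].
#' @examples
#' \donttest{
#' fx <- buildFixture(defaultFixtureSpec(), tempfile("fx"))
#' g <- readGenomeFasta(fx$genomes$fasta[1], fx$genomes$genome_id[1])
#' m <- readGeneModels(fx$genomes$gff[1], g)
#' transcripts(m)
#' }
#' @export
readGeneModels <- function(path, genome) {
  if (!file.exists(path))
    stop(sprintf("GFF3 file not found: %s", path))
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- tolower(as.character(gff$type))
  strands <- as.character(GenomicRanges::strand(gff))

  ids <- if ("ID" %in% names(S4Vectors::mcols(gff)))
    as.character(gff$ID) else rep(NA_character_, length(gff))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gff)))
    vapply(as.list(gff$Parent),
           function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gff))

  # map feature id -> (type, parent, gene-ish name) for parent resolution
  id_type <- stats::setNames(typ, ids)
  id_parent <- stats::setNames(parents, ids)
  gene_name <- function(i) {
    mc <- S4Vectors::mcols(gff)
    for (f in c("gene", "locus_tag", "Name", "ID"))
      if (f %in% names(mc)) {
        v <- mc[[f]][i]
        v <- if (is.list(v) || is(v, "List"))
          (if (length(v[[1L]])) v[[1L]][[1L]] else NA_character_)
        else as.character(v)
        if (!is.na(v) && nzchar(v)) return(v)
      }
    NA_character_
  }

  is_seg <- typ %in% c("cds", "exon")
  used_fallback <- FALSE
  rows <- vector("list", sum(is_seg))
  k <- 0L
  for (i in which(is_seg)) {
    if (typ[i] == "cds" && !strands[i] %in% c("+", "-"))
      stop(sprintf("CDS at %s:%d..%d has strand '%s'; must be + or -",
                   as.character(GenomicRanges::seqnames(gff))[i],
                   GenomicRanges::start(gff)[i], GenomicRanges::end(gff)[i],
                   strands[i]))
    tid <- parents[i]
    if (is.na(tid)) {
      tid <- ids[i]
      if (is.na(tid)) tid <- gene_name(i)
      if (is.na(tid)) {
        warning(sprintf("skipping %s feature at %s:%d with no resolvable Parent/ID",
                        typ[i],
                        as.character(GenomicRanges::seqnames(gff))[i],
                        GenomicRanges::start(gff)[i]))
        next
      }
      used_fallback <- TRUE
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      transcript_id = tid, type = typ[i],
      contig_id = as.character(GenomicRanges::seqnames(gff))[i],
      strand = strands[i],
      start0 = GenomicRanges::start(gff)[i] - 1L,
      end0 = GenomicRanges::end(gff)[i],
      stringsAsFactors = FALSE)
  }
  if (used_fallback)
    message("readGeneModels: some features lacked Parent; resolved via ID/gene/locus_tag fallback")
  segments <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(transcript_id = character(), type = character(),
               contig_id = character(), strand = character(),
               start0 = integer(), end0 = integer())

  # gene_id: walk Parent chain from transcript id up to a gene feature
  resolve_gene <- function(tid) {
    seen <- character()
    cur <- tid
    while (!is.na(cur) && !cur %in% seen) {
      seen <- c(seen, cur)
      t <- id_type[cur]
      if (!is.na(t) && t %in% c("gene", "pseudogene")) return(cur)
      cur <- if (cur %in% names(id_parent)) id_parent[[cur]] else NA_character_
    }
    tid
  }

  tids <- unique(segments$transcript_id)
  # transcripts whose only rows are exons (no CDS): skip with warning
  with_cds <- unique(segments$transcript_id[segments$type == "cds"])
  no_cds <- setdiff(tids, with_cds)
  if (length(no_cds)) {
    warning(sprintf("skipping transcript(s) lacking CDS: %s",
                    paste(no_cds, collapse = ", ")))
    segments <- segments[segments$transcript_id %in% with_cds, , drop = FALSE]
    tids <- with_cds
  }
  tr <- data.frame(
    transcript_id = tids,
    gene_id = vapply(tids, resolve_gene, character(1)),
    contig_id = segments$contig_id[match(tids, segments$transcript_id)],
    strand = segments$strand[match(tids, segments$transcript_id)],
    stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  makeGeneModels(genomeId(genome), tr, segments, genome = genome)
}

#' Read a genome and its annotation as one scan unit
#'
#' @param fasta,gff file paths.
#' @param genomeId genome label.
#' @return an [AnnotatedGenome].
#' @export
readAnnotatedGenome <- function(fasta, gff, genomeId) {
  g <- readGenomeFasta(fasta, genomeId)
  m <- readGeneModels(gff, g)
  ag <- new("AnnotatedGenome", genome = g, models = m)
  validObject(ag)
  ag
}

REPORT_COLUMNS <- c("query_id", "genome_id", "contig_id", "start", "end",
                    "orientation", "overlap_class", "gene_ids", "tss_included")

#' Write the annotated hit report
#'
#' Tab-delimited, one row per hit, header row always present. Coordinates
#' are reported 1-based inclusive; `gene_ids` is comma-separated and empty
#' for intergenic hits; `tss_included` is `yes`/`no`. Rows are sorted by
#' (genome_id, contig_id, start, orientation).
#'
#' @param hits annotated hit data.frame from [annotateHits()] or
#'   [scanHoloGenome()] (internal 0-based half-open `start`/`end`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeHitReport <- function(hits, path) {
  df <- data.frame(
    query_id = character(), genome_id = character(), contig_id = character(),
    start = integer(), end = integer(), orientation = character(),
    overlap_class = character(), gene_ids = character(),
    tss_included = character(), stringsAsFactors = FALSE)
  if (!is.null(hits) && nrow(hits)) {
    df <- data.frame(
      query_id = hits$query_id, genome_id = hits$genome_id,
      contig_id = hits$contig_id,
      start = hits$start + 1L, end = hits$end,
      orientation = hits$orientation,
      overlap_class = hits$overlap_class,
      gene_ids = hits$gene_ids,
      tss_included = ifelse(hits$tss_included, "yes", "no"),
      stringsAsFactors = FALSE)
    df <- df[order(df$genome_id, df$contig_id, df$start, df$orientation), ,
             drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop(sprintf("cannot write report to '%s': %s", path,
                 conditionMessage(ok)))
  invisible(path)
}

#' Read back a hit report written by [writeHitReport()]
#'
#' Restores the internal representation: 0-based half-open coordinates,
#' logical `tss_included`.
#'
#' @param path report path.
#' @return annotated hit data.frame.
#' @export
readHitReport <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (!identical(names(df), REPORT_COLUMNS))
    stop(sprintf("'%s' is not a pnaScreen hit report", path))
  df$start <- as.integer(df$start) - 1L
  df$end <- as.integer(df$end)
  df$tss_included <- df$tss_included == "yes"
  df
}
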