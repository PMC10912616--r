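## Hit classification against gene models. Precedence:
## TSS_included > CDS_internal > exon > SD_region > intergenic.
## "TSS" throughout means the translational start site — the position of the
## start codon — not a transcription start site.

OVERLAP_CLASSES <- c("TSS_included", "CDS_internal", "exon", "SD_region",
                     "intergenic")

# SD-region genomic footprint for one transcript, 0-based half-open.
# Offsets are coding-strand positions relative to the start codon's first
# base: the default c(-15, -5) covers the 11 bases -15..-5.
.sdInterval <- function(tss0, strand, sdWindow) {
  a <- sdWindow[1L]
  b <- sdWindow[2L]
  if (strand == "+") c(tss0 + a, tss0 + b + 1L)
  else c(tss0 - b, tss0 - a + 1L)
}

# start-codon genomic footprint (3 bases), 0-based half-open
.startCodonInterval <- function(tss0, strand) {
  if (strand == "+") c(tss0, tss0 + 3L) else c(tss0 - 2L, tss0 + 1L)
}

.modelsList <- function(annotations) {
  if (is(annotations, "GeneModels")) {
    l <- list(annotations)
    names(l) <- annotations@genomeId
    return(l)
  }
  if (is(annotations, "AnnotatedGenome")) {
    l <- list(annotations@models)
    names(l) <- genomeId(annotations)
    return(l)
  }
  if (is.list(annotations)) {
    l <- lapply(annotations, function(a) {
      if (is(a, "AnnotatedGenome")) a@models
      else if (is(a, "GeneModels")) a
      else stop("annotations must be GeneModels or AnnotatedGenome objects")
    })
    names(l) <- vapply(l, function(m) m@genomeId, character(1))
    return(l)
  }
  stop("annotations must be GeneModels, AnnotatedGenome, or a list of them")
}

#' Classify hits by genomic context
#'
#' Assigns each hit one `overlap_class` with precedence
#' `TSS_included > CDS_internal > exon > SD_region > intergenic`:
#' * `TSS_included` — the hit footprint contains the translational start
#'   site of some transcript. Under the default `tssRule = "first-base"`
#'   that means the single first base of the start codon (unambiguous and
#'   strand-symmetric); `"any-start-codon-base"` accepts overlap with any of
#'   the three start-codon bases.
#' * `CDS_internal` — overlaps a CDS segment without containing a start
#'   site.
#' * `exon` — overlaps an exon segment only (non-coding exon sequence).
#' * `SD_region` — overlaps the configured Shine-Dalgarno window upstream of
#'   some start codon on that transcript's coding-strand footprint
#'   (default coding-strand offsets -15..-5).
#' * `intergenic` — none of the above; `gene_ids` is empty.
#'
#' `gene_ids` lists every transcript contributing the winning class,
#' comma-separated. Classification is orientation-agnostic: the biological
#' reading (a PNA binds the mRNA when the query's reverse complement lies on
#' the transcript's sense strand) is left to the report reader.
#'
#' @param hits hit data.frame from [findExactMatches()] /
#'   [findMismatchMatches()].
#' @param annotations a [GeneModels], [AnnotatedGenome], or list of either
#'   covering every genome the hits refer to.
#' @param sdWindow length-2 integer vector of coding-strand offsets
#'   (default `c(-15, -5)`).
#' @param tssRule `"first-base"` (default) or `"any-start-codon-base"`.
#' @return the hits with columns `overlap_class`, `gene_ids`,
#'   `tss_included` appended.
#' @export
annotateHits <- function(hits, annotations, sdWindow = c(-15L, -5L),
                         tssRule = c("first-base", "any-start-codon-base")) {
  tssRule <- match.arg(tssRule)
  sdWindow <- as.integer(sdWindow)
  if (length(sdWindow) != 2L || any(is.na(sdWindow)) ||
      sdWindow[1L] > sdWindow[2L])
    stop("sdWindow must be two ordered integer offsets, e.g. c(-15, -5)")
  ml <- .modelsList(annotations)
  out <- hits
  out$overlap_class <- rep("intergenic", nrow(hits))
  out$gene_ids <- rep("", nrow(hits))
  out$tss_included <- rep(FALSE, nrow(hits))
  if (!nrow(hits)) return(out)

  for (gid in unique(hits$genome_id)) {
    if (!gid %in% names(ml))
      stop(sprintf("hits refer to genome '%s' with no annotation set", gid))
    models <- ml[[gid]]
    rows <- which(hits$genome_id == gid)
    known <- unique(c(models@transcripts$contig_id,
                      models@segments$contig_id))
    unknown <- setdiff(unique(hits$contig_id[rows]), known)
    if (length(unknown))
      stop(sprintf("hit on contig '%s' unknown to annotation of genome '%s'",
                   unknown[1L], gid))
    tr <- models@transcripts
    hgr <- GenomicRanges::GRanges(
      seqnames = hits$contig_id[rows],
      ranges = IRanges::IRanges(start = hits$start[rows] + 1L,
                                end = hits$end[rows]))
    # feature GRanges (1-based) per class
    tssw <- t(vapply(seq_len(nrow(tr)), function(i) {
      if (tssRule == "first-base") c(tr$tss0[i], tr$tss0[i] + 1L)
      else .startCodonInterval(tr$tss0[i], tr$strand[i])
    }, integer(2)))
    sdw <- t(vapply(seq_len(nrow(tr)), function(i)
      .sdInterval(tr$tss0[i], tr$strand[i], sdWindow), integer(2)))
    featGR <- function(iv, ids) {
      keep <- iv[, 2L] > iv[, 1L]
      GenomicRanges::GRanges(
        seqnames = tr$contig_id[keep],
        ranges = IRanges::IRanges(start = iv[keep, 1L] + 1L,
                                  end = iv[keep, 2L]),
        transcript_id = ids[keep])
    }
    seg <- models@segments
    segGR <- function(type) {
      s <- seg[seg$type == type, , drop = FALSE]
      GenomicRanges::GRanges(
        seqnames = s$contig_id,
        ranges = IRanges::IRanges(start = s$start0 + 1L, end = s$end0),
        transcript_id = s$transcript_id)
    }
    layers <- list(
      TSS_included = featGR(tssw, tr$transcript_id),
      CDS_internal = segGR("cds"),
      exon = segGR("exon"),
      SD_region = featGR(sdw, tr$transcript_id))
    assigned <- rep(FALSE, length(rows))
    for (cls in names(layers)) {
      ov <- GenomicRanges::findOverlaps(hgr, layers[[cls]])
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      take <- !assigned[qh]
      if (!any(take)) next
      ids_by_hit <- split(layers[[cls]]$transcript_id[sh[take]], qh[take])
      for (key in names(ids_by_hit)) {
        j <- as.integer(key)
        out$overlap_class[rows[j]] <- cls
        out$gene_ids[rows[j]] <- paste(sort(unique(ids_by_hit[[key]])),
                                       collapse = ",")
      }
      assigned[unique(qh)] <- TRUE
    }
    out$tss_included[rows] <- out$overlap_class[rows] == "TSS_included"
  }
  out
}

#' Scan queries across a holo-genome and summarise per genome
#'
#' Runs [findExactMatches()] and [annotateHits()] over every supplied
#' genome+annotation pair (for example an endosymbiont and its host insect,
#' scanned jointly) and reports both the concatenated annotated hits and a
#' per-(query, genome) summary: `n_hits`, `n_TSS_included`, and
#' `n_genes_cds_overlap`, the number of distinct genes whose CDS the query
#' overlaps in either orientation. The summary has one row per (query,
#' genome-set entry), including all-zero rows for queries absent from a
#' genome, so passing the same genome twice doubles every count.
#'
#' @param queries as for [findExactMatches()].
#' @param genomeSets list of [AnnotatedGenome] (a single one is accepted).
#' @param sdWindow,tssRule passed to [annotateHits()].
#' @param iupacGenome passed to [findExactMatches()].
#' @return list with elements `hits` (annotated hit data.frame) and
#'   `summary` (data.frame `query_id`, `genome_id`, `n_hits`,
#'   `n_TSS_included`, `n_genes_cds_overlap`).
#' @export
scanHoloGenome <- function(queries, genomeSets, sdWindow = c(-15L, -5L),
                           tssRule = "first-base", iupacGenome = FALSE) {
  if (is(genomeSets, "AnnotatedGenome")) genomeSets <- list(genomeSets)
  if (!length(genomeSets))
    stop("at least one annotated genome is required")
  ok <- vapply(genomeSets, is, logical(1), "AnnotatedGenome")
  if (!all(ok))
    stop("genomeSets must be AnnotatedGenome objects (see readAnnotatedGenome)")
  q <- .queryVector(queries)
  hit_list <- list()
  sum_list <- list()
  for (ag in genomeSets) {
    hits <- findExactMatches(q, ag, iupacGenome = iupacGenome)
    ann <- annotateHits(hits, ag, sdWindow = sdWindow, tssRule = tssRule)
    hit_list[[length(hit_list) + 1L]] <- ann
    # distinct genes with CDS overlap, either orientation, any class
    seg <- ag@models@segments
    cds <- seg[seg$type == "cds", , drop = FALSE]
    tr <- ag@models@transcripts
    for (qi in names(q)) {
      h <- ann[ann$query_id == qi, , drop = FALSE]
      genes <- character()
      if (nrow(h) && nrow(cds)) {
        hgr <- GenomicRanges::GRanges(
          seqnames = h$contig_id,
          ranges = IRanges::IRanges(start = h$start + 1L, end = h$end))
        cgr <- GenomicRanges::GRanges(
          seqnames = cds$contig_id,
          ranges = IRanges::IRanges(start = cds$start0 + 1L, end = cds$end0))
        ov <- GenomicRanges::findOverlaps(hgr, cgr)
        tids <- unique(cds$transcript_id[S4Vectors::subjectHits(ov)])
        genes <- unique(tr$gene_id[match(tids, tr$transcript_id)])
      }
      sum_list[[length(sum_list) + 1L]] <- data.frame(
        query_id = qi, genome_id = genomeId(ag),
        n_hits = nrow(h),
        n_TSS_included = sum(h$tss_included),
        n_genes_cds_overlap = length(genes),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hit_list)
  hits <- .sortHits(hits)
  list(hits = hits, summary = do.call(rbind, sum_list))
}
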