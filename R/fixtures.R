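## Deterministic synthetic annotated genomes with planted query occurrences
## and machine-readable ground truth. Background bases are i.i.d. at a
## stated GC fraction (no repeat structure); planted-site uniqueness is
## verified by scanning, not assumed — the builder redraws the background a
## bounded number of times if a planted query recurs by chance, then errors.

#' Declare a synthetic-genome fixture
#'
#' See [FixtureSpec-class] for the field layout. All coordinates are
#' 1-based, matching the emitted GFF3.
#'
#' @param seed integer RNG seed (required; reproducibility demands no
#'   wall-clock default).
#' @param contigs data.frame `genome_id`, `contig_id`, `length`, `gc`.
#' @param genes data.frame `gene_id`, `transcript_id`, `genome_id`,
#'   `contig_id`, `strand`, `tss1`, `cds_length`; optional `intron_offset`,
#'   `intron_length`, `emit_exons`.
#' @param plants data.frame `query`, `genome_id`, `contig_id`, `pos1`,
#'   `orientation`, `intended_class`; may be empty.
#' @param absentQueries character vector of queries guaranteed absent from
#'   every emitted genome, in both orientations.
#' @return a [FixtureSpec].
#' @export
fixtureSpec <- function(seed, contigs, genes, plants = NULL,
                        absentQueries = character()) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required")
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(plants))
    plants <- data.frame(query = character(), genome_id = character(),
                         contig_id = character(), pos1 = integer(),
                         orientation = character(),
                         intended_class = character(),
                         stringsAsFactors = FALSE)
  plants <- as.data.frame(plants, stringsAsFactors = FALSE)
  for (col in c("intron_offset", "intron_length"))
    if (!col %in% names(genes)) genes[[col]] <- NA_integer_
  if (!"emit_exons" %in% names(genes)) genes$emit_exons <- FALSE
  if (any(genes$cds_length %% 3L != 0L))
    stop("every cds_length must be a multiple of 3")
  if (any(genes$cds_length < 6L))
    stop("cds_length must be >= 6 (start plus stop codon)")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (nrow(plants)) {
    if (!all(plants$orientation %in% c("forward", "revcomp")))
      stop("plant orientation must be 'forward' or 'revcomp'")
    if (!all(plants$intended_class %in% OVERLAP_CLASSES))
      stop("plant intended_class must be one of: ",
           paste(OVERLAP_CLASSES, collapse = ", "))
    # pairwise-disjoint planted intervals
    iv <- data.frame(key = paste(plants$genome_id, plants$contig_id),
                     s = plants$pos1, e = plants$pos1 + nchar(plants$query) - 1L)
    for (k in unique(iv$key)) {
      sub <- iv[iv$key == k, , drop = FALSE]
      sub <- sub[order(sub$s), , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$s[-1L] <= sub$e[-nrow(sub)]))
        stop(sprintf("colliding plants on %s", k))
    }
  }
  ckey <- paste(contigs$genome_id, contigs$contig_id)
  for (df in list(genes, plants)) {
    if (!nrow(df)) next
    bad <- setdiff(paste(df$genome_id, df$contig_id), ckey)
    if (length(bad))
      stop(sprintf("reference to undeclared contig: %s", bad[1L]))
  }
  new("FixtureSpec", seed = as.integer(seed), contigs = contigs,
      genes = genes, plants = plants,
      absentQueries = toupper(as.character(absentQueries)))
}

# CDS genomic segments (1-based inclusive, genomic order) for one gene row
.geneSegments1 <- function(g) {
  L <- g$cds_length
  off <- g$intron_offset
  il <- g$intron_length
  spliced <- !is.na(off) && !is.na(il) && il > 0L
  if (g$strand == "+") {
    if (!spliced) return(data.frame(s = g$tss1, e = g$tss1 + L - 1L))
    data.frame(s = c(g$tss1, g$tss1 + off + il),
               e = c(g$tss1 + off - 1L, g$tss1 + L + il - 1L))
  } else {
    if (!spliced) return(data.frame(s = g$tss1 - L + 1L, e = g$tss1))
    # transcription runs downward; first coding chunk at the top
    data.frame(s = c(g$tss1 - L - il + 1L, g$tss1 - off + 1L),
               e = c(g$tss1 - off - il, g$tss1))
  }
}

.randomCoding <- function(len, gc) {
  body <- if (len > 6L)
    paste(sample(c("A", "C", "G", "T"), len - 6L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  else ""
  paste0("ATG", body, "TAA")
}

.replaceAt <- function(text, pos1, replacement) {
  paste0(substr(text, 1L, pos1 - 1L), replacement,
         substr(text, pos1 + nchar(replacement), nchar(text)))
}

# GeneModels (plus per-genome GenomeSet) from a spec, for class checking
.specModels <- function(spec, genome_id) {
  genes <- spec@genes[spec@genes$genome_id == genome_id, , drop = FALSE]
  segs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sg <- .geneSegments1(g)
    segs[[i]] <- data.frame(transcript_id = g$transcript_id, type = "cds",
                            contig_id = g$contig_id, strand = g$strand,
                            start0 = sg$s - 1L, end0 = sg$e,
                            stringsAsFactors = FALSE)
  }
  tr <- data.frame(transcript_id = genes$transcript_id,
                   gene_id = genes$gene_id, contig_id = genes$contig_id,
                   strand = genes$strand, stringsAsFactors = FALSE)
  seg <- if (length(segs)) do.call(rbind, segs) else
    data.frame(transcript_id = character(), type = character(),
               contig_id = character(), strand = character(),
               start0 = integer(), end0 = integer(),
               stringsAsFactors = FALSE)
  makeGeneModels(genome_id, tr, seg)
}

#' Build a fixture: FASTA + GFF3 + ground truth
#'
#' Draws the background, splices in gene coding sequences (each CDS begins
#' with ATG and ends with TAA on its coding strand) and planted query
#' occurrences, verifies that every planted query occurs exactly where
#' planted (and absent queries nowhere) in either orientation, checks each
#' plant's `intended_class` by brute-force classification against the gene
#' models, and writes one FASTA and one GFF3 per genome plus a ground-truth
#' TSV. Identical spec + seed gives byte-identical outputs. Nothing is
#' written if validation fails.
#'
#' @param spec a [FixtureSpec].
#' @param outDir output directory (created if needed).
#' @param maxRetries background redraws allowed when a planted or absent
#'   query collides with the random background (default 25).
#' @return list: `genomes` (data.frame `genome_id`, `fasta`, `gff`),
#'   `ground_truth` (TSV path), `dir`.
#' @examples
#' \donttest{
#' fx <- buildFixture(defaultFixtureSpec(), tempfile("fx"))
#' read.delim(fx$ground_truth)
#' }
#' @export
buildFixture <- function(spec, outDir, maxRetries = 25L) {
  stopifnot(is(spec, "FixtureSpec"))
  set.seed(spec@seed, kind = "Mersenne-Twister")
  contigs <- spec@contigs
  genes <- spec@genes
  plants <- spec@plants

  final <- NULL
  for (attempt in seq_len(maxRetries)) {
    texts <- list()  # texts[[genome]][[contig]]
    ok <- TRUE
    for (i in seq_len(nrow(contigs))) {
      co <- contigs[i, ]
      gc <- co$gc
      bg <- paste(sample(c("A", "C", "G", "T"), co$length, replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                  (1 - gc) / 2)),
                  collapse = "")
      texts[[co$genome_id]][[co$contig_id]] <- bg
    }
    # splice in coding sequences
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      sg <- .geneSegments1(g)
      clen <- contigs$length[contigs$genome_id == g$genome_id &
                               contigs$contig_id == g$contig_id]
      if (min(sg$s) < 1L || max(sg$e) > clen)
        stop(sprintf("gene '%s' extends beyond contig '%s' (1..%d)",
                     g$gene_id, g$contig_id, clen))
      coding <- .randomCoding(g$cds_length,
                              contigs$gc[contigs$genome_id == g$genome_id &
                                           contigs$contig_id == g$contig_id])
      genomic <- if (g$strand == "+") coding else revComp(coding)
      # distribute the genomic-order text across segments
      offset <- 0L
      txt <- texts[[g$genome_id]][[g$contig_id]]
      for (j in seq_len(nrow(sg))) {
        w <- sg$e[j] - sg$s[j] + 1L
        txt <- .replaceAt(txt, sg$s[j],
                          substr(genomic, offset + 1L, offset + w))
        offset <- offset + w
      }
      texts[[g$genome_id]][[g$contig_id]] <- txt
    }
    # plants overwrite background (and, when intended, gene bases)
    for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      ptext <- if (p$orientation == "forward") toupper(p$query) else
        revComp(p$query)
      clen <- contigs$length[contigs$genome_id == p$genome_id &
                               contigs$contig_id == p$contig_id]
      if (p$pos1 < 1L || p$pos1 + nchar(ptext) - 1L > clen)
        stop(sprintf("plant of '%s' out of bounds on %s", p$query,
                     p$contig_id))
      texts[[p$genome_id]][[p$contig_id]] <-
        .replaceAt(texts[[p$genome_id]][[p$contig_id]], p$pos1, ptext)
    }
    # every gene must still open with its start codon
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      sg <- .geneSegments1(g)
      txt <- texts[[g$genome_id]][[g$contig_id]]
      codon <- if (g$strand == "+")
        substr(txt, g$tss1, g$tss1 + 2L)
      else revComp(substr(txt, g$tss1 - 2L, g$tss1))
      if (codon != "ATG")
        stop(sprintf("a plant destroyed the start codon of gene '%s'",
                     g$gene_id))
    }
    # occurrence verification: planted exactly where planted, absent absent
    expected <- list()
    if (nrow(plants)) for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      q <- toupper(p$query)
      ori <- if (q == revComp(q)) "forward" else p$orientation
      expected[[i]] <- data.frame(query = q, genome_id = p$genome_id,
                                  contig_id = p$contig_id,
                                  start0 = p$pos1 - 1L,
                                  orientation = ori,
                                  stringsAsFactors = FALSE)
    }
    expected <- if (length(expected)) do.call(rbind, expected) else NULL
    queries <- unique(c(toupper(plants$query), spec@absentQueries))
    found <- list()
    for (q in queries) {
      rc <- revComp(q)
      for (gid in names(texts)) for (cid in names(texts[[gid]])) {
        graw <- charToRaw(texts[[gid]][[cid]])
        f <- .scanExact(graw, charToRaw(q))
        r <- if (rc == q) integer(0) else .scanExact(graw, charToRaw(rc))
        if (length(f))
          found[[length(found) + 1L]] <- data.frame(
            query = q, genome_id = gid, contig_id = cid, start0 = f,
            orientation = "forward", stringsAsFactors = FALSE)
        if (length(r))
          found[[length(found) + 1L]] <- data.frame(
            query = q, genome_id = gid, contig_id = cid, start0 = r,
            orientation = "revcomp", stringsAsFactors = FALSE)
      }
    }
    found <- if (length(found)) do.call(rbind, found) else
      data.frame(query = character(), genome_id = character(),
                 contig_id = character(), start0 = integer(),
                 orientation = character(), stringsAsFactors = FALSE)
    key <- function(df) if (is.null(df) || !nrow(df)) character() else
      sort(paste(df$query, df$genome_id, df$contig_id, df$start0,
                 df$orientation))
    if (identical(key(expected), key(found))) {
      final <- texts
      break
    }
    # else: accidental background occurrence — redraw
  }
  if (is.null(final))
    stop(sprintf(
      "could not realise fixture in %d attempts: a planted or absent query keeps recurring; adjust the spec",
      maxRetries))

  # intended_class check (deterministic; a mismatch is a spec error)
  gt_rows <- list()
  for (gid in unique(contigs$genome_id)) {
    models <- .specModels(spec, gid)
    pl <- plants[plants$genome_id == gid, , drop = FALSE]
    if (!nrow(pl)) next
    hits <- data.frame(query_id = toupper(pl$query), genome_id = gid,
                       contig_id = pl$contig_id, start = pl$pos1 - 1L,
                       end = pl$pos1 - 1L + nchar(pl$query),
                       orientation = ifelse(
                         toupper(pl$query) ==
                           vapply(pl$query, revComp, character(1)),
                         "forward", pl$orientation),
                       stringsAsFactors = FALSE)
    ann <- annotateHits(hits, models)
    bad <- ann$overlap_class != pl$intended_class
    if (any(bad))
      stop(sprintf(
        "plant of '%s' at %s:%d classifies as %s, not the intended %s",
        pl$query[bad][1L], pl$contig_id[bad][1L], pl$pos1[bad][1L],
        ann$overlap_class[bad][1L], pl$intended_class[bad][1L]))
    ann$start <- ann$start + 1L  # ground truth is 1-based inclusive
    gt_rows[[length(gt_rows) + 1L]] <-
      ann[, c("query_id", "genome_id", "contig_id", "start", "end",
              "orientation", "overlap_class")]
  }
  gt <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(query_id = character(), genome_id = character(),
               contig_id = character(), start = integer(), end = integer(),
               orientation = character(), overlap_class = character(),
               stringsAsFactors = FALSE)
  gt <- gt[order(gt$genome_id, gt$contig_id, gt$start, gt$orientation), ,
           drop = FALSE]

  # ---- write files ----
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  genome_ids <- unique(contigs$genome_id)
  paths <- data.frame(genome_id = genome_ids,
                      fasta = file.path(outDir,
                                        paste0(genome_ids, ".fasta")),
                      gff = file.path(outDir, paste0(genome_ids, ".gff3")),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(paths))) {
    gid <- paths$genome_id[i]
    seqs <- Biostrings::DNAStringSet(unlist(final[[gid]]))
    Biostrings::writeXStringSet(seqs, paths$fasta[i], width = 70L)
    .writeFixtureGff(spec, gid, paths$gff[i])
  }
  gt_path <- file.path(outDir, "ground_truth.tsv")
  utils::write.table(gt, gt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  list(genomes = paths, ground_truth = gt_path, dir = outDir)
}

.writeFixtureGff <- function(spec, genome_id, path) {
  contigs <- spec@contigs[spec@contigs$genome_id == genome_id, , drop = FALSE]
  genes <- spec@genes[spec@genes$genome_id == genome_id, , drop = FALSE]
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(contigs)))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              contigs$contig_id[i], contigs$length[i]))
  fmt <- function(contig, type, s, e, strand, phase, attrs)
    sprintf("%s\tpnaScreen\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            contig, type, s, e, strand, phase, attrs)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sg <- .geneSegments1(g)
    span_s <- min(sg$s)
    span_e <- max(sg$e)
    lines <- c(lines,
               fmt(g$contig_id, "gene", span_s, span_e, g$strand, ".",
                   sprintf("ID=%s;Name=%s", g$gene_id, g$gene_id)),
               fmt(g$contig_id, "mRNA", span_s, span_e, g$strand, ".",
                   sprintf("ID=%s;Parent=%s", g$transcript_id, g$gene_id)))
    # CDS phase: bases of preceding coding sequence mod 3, per segment in
    # transcription order
    ord <- if (g$strand == "+") order(sg$s) else order(-sg$s)
    done <- 0L
    phase <- integer(nrow(sg))
    for (j in ord) {
      phase[j] <- (3L - done %% 3L) %% 3L
      done <- done + sg$e[j] - sg$s[j] + 1L
    }
    if (isTRUE(g$emit_exons))
      for (j in seq_len(nrow(sg)))
        lines <- c(lines,
                   fmt(g$contig_id, "exon", sg$s[j], sg$e[j], g$strand, ".",
                       sprintf("ID=%s.exon%d;Parent=%s", g$transcript_id, j,
                               g$transcript_id)))
    for (j in seq_len(nrow(sg)))
      lines <- c(lines,
                 fmt(g$contig_id, "CDS", sg$s[j], sg$e[j], g$strand,
                     phase[j],
                     sprintf("ID=%s.cds;Parent=%s", g$transcript_id,
                             g$transcript_id)))
  }
  writeLines(lines, path)
}

#' Default two-genome demonstration fixture
#'
#' A small "symbiont" genome (one 5 kb AT-rich contig, three genes) paired
#' with a "host" genome (one 20 kb contig, five genes, one of them spliced).
#' The symbiont carries a groEL-like target gene whose -5..+5 start window
#' reads GTCAAATGGC on the coding strand — so the designed antisense PNA is
#' GCCATTTGAC — and a pyrG-like gene carrying the same 10-mer in mid-CDS,
#' reproducing the geometry in which a perfect off-target match falls inside
#' a coding region rather than on a start site. The host carries a decoy
#' start-site occurrence for the 1-mismatch variant ACCATTTGAC,
#' demonstrating why single-base-mismatch controls are unsafe. The
#' two-mismatch control GCGATTTGTC is guaranteed absent from both genomes.
#'
#' @param seed RNG seed for the background (default 20240817).
#' @return a [FixtureSpec].
#' @export
defaultFixtureSpec <- function(seed = 20240817L) {
  contigs <- data.frame(
    genome_id = c("symbiont", "host"),
    contig_id = c("sym1", "host1"),
    length = c(5000L, 20000L),
    gc = c(0.30, 0.35),
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("groL", "pyrG", "ybaX", "hg1", "hg2", "hg3", "hg4", "hg5"),
    transcript_id = c("groL_t1", "pyrG_t1", "ybaX_t1", "hg1_t1", "hg2_t1",
                      "hg3_t1", "hg4_t1", "hg5_t1"),
    genome_id = c(rep("symbiont", 3L), rep("host", 5L)),
    contig_id = c(rep("sym1", 3L), rep("host1", 5L)),
    strand = c("+", "+", "-", "+", "-", "+", "+", "-"),
    tss1 = c(1200L, 2800L, 4500L, 2000L, 6000L, 9000L, 13000L, 17000L),
    cds_length = c(900L, 600L, 600L, 900L, 900L, 600L, 900L, 900L),
    intron_offset = c(NA, NA, NA, NA, NA, 300L, NA, NA),
    intron_length = c(NA, NA, NA, NA, NA, 200L, NA, NA),
    emit_exons = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  plants <- data.frame(
    query = c("GCCATTTGAC", "GCCATTTGAC", "ACCATTTGAC"),
    genome_id = c("symbiont", "symbiont", "host"),
    contig_id = c("sym1", "sym1", "host1"),
    pos1 = c(1195L, 3100L, 12995L),
    orientation = c("revcomp", "revcomp", "revcomp"),
    intended_class = c("TSS_included", "CDS_internal", "TSS_included"),
    stringsAsFactors = FALSE)
  fixtureSpec(seed, contigs, genes, plants,
              absentQueries = "GCGATTTGTC")
}

#' Synthetic stand-in for the Buchnera aphidicola reference record
#'
#' A single 21 kb contig, labelled synthetic throughout, whose groEL gene
#' model reproduces the published gene geometry of the *Buchnera aphidicola*
#' str. APS chromosome: CDS from 18,715 to 20,361 (1,647 bp) on the plus
#' strand, with the -5..+5 start window reading GTCAAATGGC. A pyrG gene
#' carries the anti-groEL 10-mer in mid-CDS. The sequence outside the
#' planted windows is random, NOT the real genome — this fixture exercises
#' coordinate and classification fidelity offline; it is not a substitute
#' for scanning the real record.
#'
#' @param seed RNG seed (default 4021).
#' @return a [FixtureSpec] with genome_id `"Buchnera_synthetic"`.
#' @export
syntheticBuchneraFixtureSpec <- function(seed = 4021L) {
  contigs <- data.frame(
    genome_id = "Buchnera_synthetic", contig_id = "chr_synthetic",
    length = 21000L, gc = 0.26, stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("pyrG", "rpoB", "groEL"),
    transcript_id = c("pyrG_t1", "rpoB_t1", "groEL_t1"),
    genome_id = "Buchnera_synthetic", contig_id = "chr_synthetic",
    strand = c("+", "-", "+"),
    tss1 = c(5000L, 12000L, 18715L),
    cds_length = c(1629L, 900L, 1647L),
    stringsAsFactors = FALSE)
  plants <- data.frame(
    query = c("GCCATTTGAC", "GCCATTTGAC"),
    genome_id = "Buchnera_synthetic", contig_id = "chr_synthetic",
    pos1 = c(5600L, 18710L),
    orientation = "revcomp",
    intended_class = c("CDS_internal", "TSS_included"),
    stringsAsFactors = FALSE)
  fixtureSpec(seed, contigs, genes, plants,
              absentQueries = "GCGATTTGTC")
}
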