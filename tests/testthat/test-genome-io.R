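test_that("FASTA records are parsed, uppercased and keyed by header token", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1 some description", "acgtACGT"), fa)
  gs <- readGenomeFasta(fa, "g")
  expect_identical(contigIds(gs), "chr1")
  expect_identical(contigSeq(gs, "chr1"), "ACGTACGT")
  expect_identical(unname(contigLengths(gs)), 8L)
  expect_identical(genomeId(gs), "g")
})

test_that("multi-record and wrapped FASTA round-trips through write-then-read", {
  fx <- default_fixture()
  for (i in seq_len(nrow(fx$genomes))) {
    gs <- readGenomeFasta(fx$genomes$fasta[i], fx$genomes$genome_id[i])
    out <- withr::local_tempfile(fileext = ".fasta")
    Biostrings::writeXStringSet(genomeSequences(gs), out, width = 60L)
    gs2 <- readGenomeFasta(out, fx$genomes$genome_id[i])
    expect_identical(contigIds(gs2), contigIds(gs))
    for (cid in contigIds(gs))
      expect_identical(contigSeq(gs2, cid), contigSeq(gs, cid))
  }
})

test_that("malformed FASTA is rejected with the offending record named", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
  expect_error(readGenomeFasta(fa, "g"), "duplicate contig_id 'c1'")

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "ACQT"), fa2)
  expect_error(readGenomeFasta(fa2, "g"), "'bad'.*non-IUPAC|record 2")

  fa3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">empty", "", ">c2", "ACGT"), fa3)
  expect_error(readGenomeFasta(fa3, "g"), "empty")
})

make_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF 1-based inclusive coordinates become 0-based half-open", {
  g <- genomeSet("g", c(c1 = random_dna(400)))
  gff <- make_gff(c(
    "c1\tsrc\tgene\t101\t160\t.\t+\t.\tID=gene1",
    "c1\tsrc\tmRNA\t101\t160\t.\t+\t.\tID=t1;Parent=gene1",
    "c1\tsrc\tCDS\t101\t160\t.\t+\t0\tID=t1.cds;Parent=t1"))
  m <- readGeneModels(gff, g)
  seg <- segmentTable(m)
  cds <- seg[seg$type == "cds", ]
  expect_identical(c(cds$start0, cds$end0), c(100L, 160L))
  expect_identical(transcripts(m)$tss0, 100L)
  expect_identical(transcripts(m)$gene_id, "gene1")
})

test_that("the minus-strand start site is the largest CDS end minus one", {
  g <- genomeSet("g", c(c1 = random_dna(400)))
  gff <- make_gff(c(
    "c1\tsrc\tgene\t101\t160\t.\t-\t.\tID=gene1",
    "c1\tsrc\tmRNA\t101\t160\t.\t-\t.\tID=t1;Parent=gene1",
    "c1\tsrc\tCDS\t101\t160\t.\t-\t0\tID=t1.cds;Parent=t1"))
  m <- readGeneModels(gff, g)
  expect_identical(transcripts(m)$tss0, 159L)
})

test_that("two mRNAs of one gene give two transcripts sharing a gene_id", {
  g <- genomeSet("g", c(c1 = random_dna(600)))
  gff <- make_gff(c(
    "c1\tsrc\tgene\t101\t460\t.\t+\t.\tID=geneA",
    "c1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=tA1;Parent=geneA",
    "c1\tsrc\tCDS\t101\t220\t.\t+\t0\tParent=tA1",
    "c1\tsrc\tmRNA\t101\t460\t.\t+\t.\tID=tA2;Parent=geneA",
    "c1\tsrc\tCDS\t101\t190\t.\t+\t0\tParent=tA2",
    "c1\tsrc\tCDS\t301\t460\t.\t+\t2\tParent=tA2"))
  m <- readGeneModels(gff, g)
  tr <- transcripts(m)
  expect_setequal(tr$transcript_id, c("tA1", "tA2"))
  expect_identical(unique(tr$gene_id), "geneA")
  # spliced transcript keeps both CDS segments in genomic order
  seg <- segmentTable(m)
  ta2 <- seg[seg$transcript_id == "tA2" & seg$type == "cds", ]
  expect_identical(ta2$start0, c(100L, 300L))
})

test_that("transcripts without exon rows inherit exons from their CDS", {
  g <- genomeSet("g", c(c1 = random_dna(400)))
  gff <- make_gff(c(
    "c1\tsrc\tmRNA\t101\t160\t.\t+\t.\tID=t1",
    "c1\tsrc\tCDS\t101\t160\t.\t+\t0\tParent=t1"))
  m <- readGeneModels(gff, g)
  seg <- segmentTable(m)
  ex <- seg[seg$type == "exon", ]
  expect_identical(nrow(ex), 1L)
  expect_identical(c(ex$start0, ex$end0), c(100L, 160L))
})

test_that("degenerate annotations error or warn as contracted", {
  g <- genomeSet("g", c(c1 = random_dna(200)))
  # CDS beyond contig bounds
  gff <- make_gff("c1\tsrc\tCDS\t150\t260\t.\t+\t0\tID=t1")
  expect_error(suppressMessages(readGeneModels(gff, g)), "beyond contig")
  # CDS with undefined strand
  gff2 <- make_gff("c1\tsrc\tCDS\t10\t60\t.\t.\t0\tID=t1")
  expect_error(readGeneModels(gff2, g), "strand")
  # transcript with exons but no CDS is skipped with a warning
  gff3 <- make_gff(c(
    "c1\tsrc\tmRNA\t10\t90\t.\t+\t.\tID=tnc",
    "c1\tsrc\texon\t10\t90\t.\t+\t.\tParent=tnc",
    "c1\tsrc\tmRNA\t100\t159\t.\t+\t.\tID=tok",
    "c1\tsrc\tCDS\t100\t159\t.\t+\t0\tParent=tok"))
  expect_warning(m <- readGeneModels(gff3, g), "lacking CDS")
  expect_identical(transcripts(m)$transcript_id, "tok")
})

test_that("hit report is 1-based inclusive, sorted, and round-trips", {
  hits <- data.frame(
    query_id = c("q", "q"), genome_id = c("g", "g"),
    contig_id = c("c1", "c1"), start = c(99L, 9L), end = c(109L, 19L),
    orientation = c("revcomp", "forward"),
    overlap_class = c("TSS_included", "intergenic"),
    gene_ids = c("t1", ""), tss_included = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- withr::local_tempfile(fileext = ".tsv")
  writeHitReport(hits, out)
  raw <- read.delim(out, colClasses = "character")
  # sorted by start, reported 1-based inclusive: [9,19) -> 10..19
  expect_identical(raw$start, c("10", "100"))
  expect_identical(raw$end, c("19", "109"))
  expect_identical(raw$tss_included, c("no", "yes"))
  back <- readHitReport(out)
  expect_identical(back$start, c(9L, 99L))
  expect_identical(back$end, c(19L, 109L))
  expect_identical(back$gene_ids, c("", "t1"))
  expect_identical(back$tss_included, c(FALSE, TRUE))
})

test_that("an empty hit list still writes a header row", {
  out <- withr::local_tempfile(fileext = ".tsv")
  writeHitReport(NULL, out)
  lines <- readLines(out)
  expect_length(lines, 1L)
  expect_match(lines, "^query_id\tgenome_id")
  expect_identical(nrow(readHitReport(out)), 0L)
})

test_that("GFF->internal->report coordinate conversion is self-inverse", {
  set.seed(11)
  for (i in 1:50) {
    a <- sample.int(1000, 1)
    b <- a + sample.int(50, 1) - 1L
    s0 <- a - 1L          # GFF 1-based inclusive -> internal half-open
    e0 <- b
    expect_identical(c(s0 + 1L, e0), c(a, b))  # internal -> reported
  }
})

test_that("interval-index overlap queries equal a linear scan", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:100, 1)
    tr_ids <- paste0("t", seq_len(n))
    starts <- sample.int(5000, n)
    widths <- sample(5:200, n, replace = TRUE)
    seg <- data.frame(transcript_id = tr_ids,
                      type = sample(c("cds", "exon"), n, replace = TRUE),
                      contig_id = sample(c("c1", "c2"), n, replace = TRUE),
                      strand = "+",
                      start0 = starts, end0 = starts + widths,
                      stringsAsFactors = FALSE)
    # one transcript per segment keeps the validity rules trivially true
    seg$type <- "exon"
    tr <- data.frame(transcript_id = tr_ids, gene_id = tr_ids,
                     contig_id = seg$contig_id, strand = "+",
                     stringsAsFactors = FALSE)
    m <- makeGeneModels("g", tr, seg)
    for (q in 1:20) {
      qs <- sample.int(5200, 1) - 1L
      qe <- qs + sample.int(60, 1)
      qc <- sample(c("c1", "c2"), 1)
      gr <- GenomicRanges::GRanges(qc, IRanges::IRanges(qs + 1L, qe))
      idx_hit <- sort(unique(
        m@index$transcript_id[S4Vectors::subjectHits(
          GenomicRanges::findOverlaps(gr, m@index))]))
      lin_hit <- sort(unique(seg$transcript_id[
        seg$contig_id == qc & seg$start0 < qe & seg$end0 > qs]))
      expect_identical(idx_hit, lin_hit)
    }
  }
})
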