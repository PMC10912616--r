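# Independent oracles and tiny generators used across the suite.
# The oracles deliberately take different routes from the package internals:
# exact search uses the PCRE regex engine (lookahead for overlapping
# occurrences), mismatch search and annotation use plain position-by-position
# loops over character vectors.

# 0-based start offsets of all (overlapping) literal occurrences
oracle_exact_starts <- function(text, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# full exact-scan oracle over a named list of genomes
# (genome_id -> named character vector of contigs)
oracle_exact_scan <- function(query, genomes, query_id = "q") {
  rc <- oracle_revcomp(query)
  palindrome <- rc == query
  rows <- list()
  for (gid in names(genomes)) for (cid in names(genomes[[gid]])) {
    text <- genomes[[gid]][[cid]]
    for (ori in c("forward", "revcomp")) {
      if (ori == "revcomp" && palindrome) next
      pat <- if (ori == "forward") query else rc
      st <- oracle_exact_starts(text, pat)
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query_id, genome_id = gid, contig_id = cid,
          start = st, end = st + nchar(query), orientation = ori,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), genome_id = character(),
               contig_id = character(), start = integer(), end = integer(),
               orientation = character(), stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$contig_id, out$start,
                   out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# complement via explicit lookup table, reverse via rev()
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# per-position Hamming scan (slow; for small inputs)
oracle_mismatch_starts <- function(text, pattern, k) {
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(tc); m <- length(pc)
  if (m > n) return(list(starts = integer(0), mism = integer(0)))
  starts <- integer(0); mism <- integer(0)
  for (s in 0:(n - m)) {
    d <- sum(tc[(s + 1):(s + m)] != pc)
    if (d <= k) { starts <- c(starts, s); mism <- c(mism, d) }
  }
  list(starts = starts, mism = mism)
}

# brute-force classifier over plain coordinate tables (no GRanges):
# transcripts: transcript_id, strand, contig_id, tss0
# segments: transcript_id, type, contig_id, start0, end0
oracle_classify <- function(s, e, contig, transcripts, segments,
                            sd_window = c(-15L, -5L),
                            tss_rule = "first-base") {
  overlaps <- function(a0, a1) a0 < e && a1 > s
  hit_tr <- function(pred) {
    ids <- character(0)
    for (i in seq_len(nrow(transcripts)))
      if (transcripts$contig_id[i] == contig && pred(transcripts[i, ]))
        ids <- c(ids, transcripts$transcript_id[i])
    ids
  }
  tss_ids <- hit_tr(function(tr) {
    if (tss_rule == "first-base") tr$tss0 >= s && tr$tss0 < e
    else {
      cs <- if (tr$strand == "+") tr$tss0 else tr$tss0 - 2L
      overlaps(cs, cs + 3L)
    }
  })
  if (length(tss_ids))
    return(list(class = "TSS_included", ids = sort(unique(tss_ids))))
  seg_ids <- function(type) {
    ids <- character(0)
    for (i in seq_len(nrow(segments)))
      if (segments$type[i] == type && segments$contig_id[i] == contig &&
          overlaps(segments$start0[i], segments$end0[i]))
        ids <- c(ids, segments$transcript_id[i])
    sort(unique(ids))
  }
  cds <- seg_ids("cds")
  if (length(cds)) return(list(class = "CDS_internal", ids = cds))
  ex <- seg_ids("exon")
  if (length(ex)) return(list(class = "exon", ids = ex))
  sd_ids <- hit_tr(function(tr) {
    a <- sd_window[1]; b <- sd_window[2]
    if (tr$strand == "+") overlaps(tr$tss0 + a, tr$tss0 + b + 1L)
    else overlaps(tr$tss0 - b, tr$tss0 - a + 1L)
  })
  if (length(sd_ids)) return(list(class = "SD_region", ids = sd_ids))
  list(class = "intergenic", ids = character(0))
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# GeneModels with no transcripts at all (an unannotated genome)
empty_models <- function(genome_id) {
  makeGeneModels(
    genome_id,
    data.frame(transcript_id = character(), gene_id = character(),
               contig_id = character(), strand = character(),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = character(), type = character(),
               contig_id = character(), strand = character(),
               start0 = integer(), end0 = integer(),
               stringsAsFactors = FALSE))
}

annotated_genome <- function(genome, models) {
  methods::new("AnnotatedGenome", genome = genome, models = models)
}

# build the default demonstration fixture once per test run
fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    dir <- file.path(tempdir(), "pnaScreen-default-fixture")
    fixture_cache$fx <- buildFixture(defaultFixtureSpec(), dir)
  }
  fixture_cache$fx
}
default_holo <- function() {
  if (is.null(fixture_cache$holo)) {
    fx <- default_fixture()
    g <- fx$genomes
    fixture_cache$holo <- lapply(seq_len(nrow(g)), function(i)
      readAnnotatedGenome(g$fasta[i], g$gff[i], g$genome_id[i]))
  }
  fixture_cache$holo
}
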