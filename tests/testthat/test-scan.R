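test_that("a planted reverse-complement site is found once, exactly", {
  g <- genomeSet("g", c(c1 = "TTGTCAAATGGCTT"))
  hits <- findExactMatches(c(q = "GCCATTTGAC"), g)
  expect_identical(nrow(hits), 1L)
  expect_identical(c(hits$start, hits$end), c(2L, 12L))
  expect_identical(hits$orientation, "revcomp")
})

test_that("overlapping occurrences are all reported in both orientations", {
  g <- genomeSet("g", c(c1 = "ATATATATAT"))
  hits <- findExactMatches(c(q = "ATATA"), g)
  expect_identical(nrow(hits), 6L)
  fwd <- hits[hits$orientation == "forward", ]
  rev <- hits[hits$orientation == "revcomp", ]
  expect_identical(fwd$start, c(0L, 2L, 4L))
  expect_identical(rev$start, c(1L, 3L, 5L))
})

test_that("absent queries return an empty frame, not an error", {
  g <- genomeSet("g", c(c1 = "AAAAAAAA"))
  hits <- findExactMatches(c(q = "GGGGG"), g)
  expect_identical(nrow(hits), 0L)
  # query longer than every contig is empty too
  expect_identical(nrow(findExactMatches(c(q = strrep("AC", 10)), g)), 0L)
})

test_that("palindromic queries are deduplicated to forward orientation", {
  g <- genomeSet("g", c(c1 = "TTACGTTT"))
  hits <- findExactMatches(c(q = "ACGT"), g)  # ACGT is its own revcomp
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$orientation, "forward")
})

test_that("genome N never matches in exact mode; IUPAC mode is opt-in", {
  g <- genomeSet("g", c(c1 = "AANAA"))
  hits <- findExactMatches(c(q = "AA"), g)
  expect_identical(hits$start, c(0L, 3L))
  gi <- genomeSet("g", c(c1 = "ARN"))
  expect_identical(nrow(findExactMatches(c(q = "AA"), gi)), 0L)
  iu <- findExactMatches(c(q = "AA"), gi, iupacGenome = TRUE)
  expect_identical(iu$start, c(0L, 1L))
  expect_identical(iu$orientation, c("forward", "forward"))
})

test_that("empty or non-ACGT queries are rejected", {
  g <- genomeSet("g", c(c1 = "ACGT"))
  expect_error(findExactMatches(c(q = ""), g), "empty")
  expect_error(findExactMatches(c(q = "ACNGT"), g), "outside")
})

test_that("the scanner agrees with the regex oracle on random genomes", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(200:3000, 1)
    text <- random_dna(n, gc = runif(1, 0.25, 0.6))
    qlen <- sample(6:15, 1)
    query <- if (i %% 4 == 0) {
      paste(rep(c("AT", "TA", "GC")[sample.int(3, 1)], qlen %/% 2),
            collapse = "")  # repetitive, often palindromic
    } else random_dna(qlen)
    # plant one forward and one reverse occurrence to guarantee signal
    p1 <- sample.int(n - nchar(query), 1)
    text <- paste0(substr(text, 1, p1 - 1), query,
                   substr(text, p1 + nchar(query), n))
    p2 <- sample.int(n - nchar(query), 1)
    text <- paste0(substr(text, 1, p2 - 1), oracle_revcomp(query),
                   substr(text, p2 + nchar(query), n))
    g <- genomeSet("g", c(c1 = text))
    got <- findExactMatches(stats::setNames(query, "q"), g)
    want <- oracle_exact_scan(query, list(g = c(c1 = text)))
    expect_identical(got[, c("start", "end", "orientation")],
                     want[, c("start", "end", "orientation")])
    expect_gte(nrow(got), 1L)
  }
})

test_that("hits map to [L-e, L-s) with flipped orientation on the revcomp genome", {
  set.seed(102)
  for (i in 1:20) {
    n <- sample(300:2000, 1)
    text <- random_dna(n, gc = 0.4)
    query <- random_dna(sample(6:12, 1))
    p <- sample.int(n - nchar(query), 1)
    text <- paste0(substr(text, 1, p - 1), query,
                   substr(text, p + nchar(query), n))
    fwd <- findExactMatches(c(q = query), genomeSet("g", c(c1 = text)))
    rev <- findExactMatches(c(q = query),
                            genomeSet("g", c(c1 = oracle_revcomp(text))))
    flip <- function(df) {
      out <- data.frame(start = n - df$end, end = n - df$start,
                        orientation = ifelse(df$orientation == "forward",
                                             "revcomp", "forward"),
                        stringsAsFactors = FALSE)
      out[order(out$start, out$orientation), , drop = FALSE]
    }
    a <- flip(fwd)
    b <- rev[order(rev$start, rev$orientation),
             c("start", "end", "orientation")]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})

test_that("k = 0 mismatch search reproduces the exact search", {
  set.seed(103)
  for (i in 1:15) {
    text <- random_dna(sample(500:3000, 1))
    query <- random_dna(sample(6:12, 1))
    p <- sample.int(nchar(text) - nchar(query), 1)
    text <- paste0(substr(text, 1, p - 1), query,
                   substr(text, p + nchar(query), nchar(text)))
    g <- genomeSet("g", c(c1 = text))
    ex <- findExactMatches(c(q = query), g)
    k0 <- findMismatchMatches(c(q = query), g, 0)
    expect_identical(ex, k0[, names(ex)])
    expect_true(all(k0$mismatches == 0L))
  }
})

test_that("one-mismatch hits on a homopolymer match the hand enumeration", {
  g <- genomeSet("g", c(c1 = "AAAAAAAAAA"))
  hits <- findMismatchMatches(c(q = "AAAAT"), g, 1)
  fwd <- hits[hits$orientation == "forward", ]
  expect_identical(fwd$start, 0:5)
  expect_identical(fwd$mismatches, rep(1L, 6))
  # revcomp ATTTT is 4 mismatches everywhere: absent at k = 1
  expect_identical(nrow(hits[hits$orientation == "revcomp", ]), 0L)
})

test_that("a doubly substituted site appears at k = 2 but not k = 1", {
  set.seed(104)
  query <- "GCCATTTGAC"
  site <- "GCGATTTGTC"  # two substitutions, positions 3 and 9
  text <- paste0(random_dna(200), site, random_dna(200))
  while (nrow(findMismatchMatches(c(q = query),
                                  genomeSet("g", c(c1 = text)), 2)) != 1L)
    text <- paste0(random_dna(200), site, random_dna(200))
  g <- genomeSet("g", c(c1 = text))
  expect_identical(nrow(findMismatchMatches(c(q = query), g, 1)), 0L)
  h2 <- findMismatchMatches(c(q = query), g, 2)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$start, 200L)
  expect_identical(h2$mismatches, 2L)
})

test_that("the mismatch hit set is monotone in k and matches the loop oracle", {
  set.seed(105)
  for (i in 1:10) {
    text <- random_dna(400)
    query <- random_dna(8)
    g <- genomeSet("g", c(c1 = text))
    prev <- 0L
    for (k in 0:3) {
      hits <- findMismatchMatches(c(q = query), g, k)
      expect_gte(nrow(hits), prev)
      prev <- nrow(hits)
      fwd <- hits[hits$orientation == "forward", ]
      want <- oracle_mismatch_starts(text, query, k)
      expect_identical(fwd$start, want$starts)
      expect_identical(fwd$mismatches, want$mism)
    }
  }
})

test_that("mismatch budgets at or above the query length are rejected", {
  g <- genomeSet("g", c(c1 = "ACGTACGT"))
  expect_error(findMismatchMatches(c(q = "ACGT"), g, 4), "query length")
  expect_error(findMismatchMatches(c(q = "ACGT"), g, -1), "maxMismatches")
})

test_that("hits are sorted by genome, contig, start, orientation", {
  g1 <- genomeSet("b_genome", c(c2 = "ATATATAT", c1 = "TATATATA"))
  g2 <- genomeSet("a_genome", c(c1 = "ATATATAT"))
  hits <- findExactMatches(c(q = "ATAT"), list(g1, g2))
  key <- paste(hits$genome_id, hits$contig_id,
               formatC(hits$start, width = 6, flag = "0"),
               hits$orientation)
  expect_identical(key, sort(key))
})
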