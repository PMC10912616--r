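## Query scanning: every occurrence of a query and its reverse complement
## across one or more genomes. Matching is defined against the + strand text:
## orientation "forward" means the query string itself occurs; "revcomp"
## means its reverse complement occurs. The engine is a vectorised byte
## comparison over the whole contig (O(n*m) word-parallel work), which for
## short antisense queries outperforms per-position loops by orders of
## magnitude in R; a naive per-position scan defines correctness in the
## test-suite oracle.

# 4-bit IUPAC class masks (A=1, C=2, G=4, T=8)
.IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                 W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                 V = 7L, N = 15L)

# 0-based start offsets of exact occurrences of qraw in graw
.scanExact <- function(graw, qraw) {
  n <- length(graw)
  m <- length(qraw)
  if (m > n) return(integer(0))
  ok <- graw[seq_len(n - m + 1L)] == qraw[1L]
  if (m > 1L) for (j in 2:m)
    ok <- ok & (graw[j:(n - m + j)] == qraw[j])
  which(ok) - 1L
}

# exact scan treating genome IUPAC codes as character classes
.scanExactIupac <- function(gmask, qmask) {
  n <- length(gmask)
  m <- length(qmask)
  if (m > n) return(integer(0))
  ok <- bitwAnd(gmask[seq_len(n - m + 1L)], qmask[1L]) > 0L
  if (m > 1L) for (j in 2:m)
    ok <- ok & (bitwAnd(gmask[j:(n - m + j)], qmask[j]) > 0L)
  which(ok) - 1L
}

# 0-based starts with Hamming distance <= k (any non-identical byte,
# including genome ambiguity codes, counts as a mismatch)
.scanMismatch <- function(graw, qraw, k) {
  n <- length(graw)
  m <- length(qraw)
  if (m > n) return(list(starts = integer(0), mism = integer(0)))
  mism <- as.integer(graw[seq_len(n - m + 1L)] != qraw[1L])
  if (m > 1L) for (j in 2:m)
    mism <- mism + (graw[j:(n - m + j)] != qraw[j])
  keep <- which(mism <= k)
  list(starts = keep - 1L, mism = mism[keep])
}

.checkQuery <- function(q, id) {
  if (is.na(q) || !nzchar(q))
    stop(sprintf("query '%s' is empty", id))
  if (!grepl("^[ACGT]+$", q))
    stop(sprintf("query '%s' contains characters outside {A,C,G,T}", id))
}

# normalise queries argument to a named uppercase character vector
.queryVector <- function(queries) {
  if (is(queries, "PNAOligo"))
    return(stats::setNames(pnaSequence(queries), pnaId(queries)))
  if (is.list(queries) && all(vapply(queries, is, logical(1), "PNAOligo")))
    return(stats::setNames(vapply(queries, pnaSequence, character(1)),
                           vapply(queries, pnaId, character(1))))
  nm <- names(queries)
  q <- toupper(as.character(queries))
  if (is.null(nm)) nm <- rep("", length(q))
  nm[!nzchar(nm)] <- paste0("query", which(!nzchar(nm)))
  stats::setNames(q, nm)
}

.genomeList <- function(genomes) {
  if (is(genomes, "GenomeSet")) return(list(genomes))
  if (is(genomes, "AnnotatedGenome")) return(list(genomes@genome))
  if (is.list(genomes))
    return(lapply(genomes, function(g) {
      if (is(g, "AnnotatedGenome")) g@genome
      else if (is(g, "GenomeSet")) g
      else stop("genomes must be GenomeSet or AnnotatedGenome objects")
    }))
  stop("genomes must be a GenomeSet or a list of GenomeSet objects")
}

.emptyHits <- function(mismatch = FALSE) {
  df <- data.frame(query_id = character(), genome_id = character(),
                   contig_id = character(), start = integer(),
                   end = integer(), orientation = character(),
                   stringsAsFactors = FALSE)
  if (mismatch) df$mismatches <- integer()
  df
}

.sortHits <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order(df$genome_id, df$contig_id, df$start, df$orientation), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find every exact occurrence of queries and their reverse complements
#'
#' Scans the + strand text of every contig for the query as written
#' (orientation `forward`) and for its reverse complement (orientation
#' `revcomp`). All occurrences are reported, including overlapping and
#' self-overlapping ones; a palindromic query (equal to its own reverse
#' complement) is reported once per position, with orientation `forward`.
#' Genome positions containing `N` (or any non-ACGT code) never match in the
#' default exact mode; `iupacGenome = TRUE` opts into treating genome
#' ambiguity codes as character classes (an `R` matches a query `A` or `G`,
#' an `N` matches anything).
#'
#' @param queries a [PNAOligo], a list of them, or a (optionally named)
#'   character vector of sequences over {A,C,G,T}.
#' @param genomes a [GenomeSet], [AnnotatedGenome], or list of either.
#' @param iupacGenome treat genome IUPAC codes as character classes.
#' @return data.frame of hits: `query_id`, `genome_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `orientation`, sorted by
#'   (genome_id, contig_id, start, orientation).
#' @examples
#' g <- genomeSet("demo", c(chr = "TTGTCAAATGGCTT"))
#' findExactMatches(c(pna = "GCCATTTGAC"), g)  # one revcomp hit at [2,12)
#' @export
findExactMatches <- function(queries, genomes, iupacGenome = FALSE) {
  q <- .queryVector(queries)
  gl <- .genomeList(genomes)
  out <- list(.emptyHits())
  for (i in seq_along(q)) {
    .checkQuery(q[[i]], names(q)[i])
    rc <- revComp(q[[i]])
    palindrome <- rc == q[[i]]
    for (g in gl) {
      for (contig in contigIds(g)) {
        text <- contigSeq(g, contig)
        if (iupacGenome) {
          gm <- .IUPAC_MASK[strsplit(text, "", fixed = TRUE)[[1L]]]
          gm[is.na(gm)] <- 0L
          qm <- .IUPAC_MASK[strsplit(q[[i]], "", fixed = TRUE)[[1L]]]
          fwd <- .scanExactIupac(gm, qm)
          rev <- if (palindrome) integer(0) else
            .scanExactIupac(gm, .IUPAC_MASK[strsplit(rc, "",
                                                     fixed = TRUE)[[1L]]])
        } else {
          graw <- charToRaw(text)
          fwd <- .scanExact(graw, charToRaw(q[[i]]))
          rev <- if (palindrome) integer(0) else
            .scanExact(graw, charToRaw(rc))
        }
        m <- nchar(q[[i]])
        if (length(fwd))
          out[[length(out) + 1L]] <- data.frame(
            query_id = names(q)[i], genome_id = genomeId(g),
            contig_id = contig, start = fwd, end = fwd + m,
            orientation = "forward", stringsAsFactors = FALSE)
        if (length(rev))
          out[[length(out) + 1L]] <- data.frame(
            query_id = names(q)[i], genome_id = genomeId(g),
            contig_id = contig, start = rev, end = rev + m,
            orientation = "revcomp", stringsAsFactors = FALSE)
      }
    }
  }
  .sortHits(do.call(rbind, out))
}

#' Find occurrences within a Hamming-distance budget
#'
#' Reports every position, in both orientations, where the genome slice
#' differs from the query (or its reverse complement) at no more than
#' `maxMismatches` positions. Substitutions only — no indels, matching the
#' substitutional nature of PNA:RNA duplex mismatches. At
#' `maxMismatches = 0` the result equals [findExactMatches()] exactly.
#' Genome ambiguity codes count as mismatches.
#'
#' @param query a single sequence over {A,C,G,T} (or a [PNAOligo]).
#' @param genomes a [GenomeSet], [AnnotatedGenome], or list of either.
#' @param maxMismatches allowed substitutions, `0 <= k < nchar(query)`.
#' @return hit data.frame as in [findExactMatches()] plus a `mismatches`
#'   column.
#' @export
findMismatchMatches <- function(query, genomes, maxMismatches = 0L) {
  q <- .queryVector(query)
  if (length(q) != 1L)
    stop("findMismatchMatches takes a single query")
  .checkQuery(q[[1L]], names(q)[1L])
  k <- as.integer(maxMismatches)
  if (is.na(k) || k < 0L || k >= nchar(q[[1L]]))
    stop(sprintf("maxMismatches must satisfy 0 <= k < query length (%d)",
                 nchar(q[[1L]])))
  gl <- .genomeList(genomes)
  rc <- revComp(q[[1L]])
  palindrome <- rc == q[[1L]]
  m <- nchar(q[[1L]])
  out <- list(.emptyHits(mismatch = TRUE))
  for (g in gl) {
    for (contig in contigIds(g)) {
      graw <- charToRaw(contigSeq(g, contig))
      fwd <- .scanMismatch(graw, charToRaw(q[[1L]]), k)
      if (length(fwd$starts))
        out[[length(out) + 1L]] <- data.frame(
          query_id = names(q)[1L], genome_id = genomeId(g),
          contig_id = contig, start = fwd$starts, end = fwd$starts + m,
          orientation = "forward", mismatches = fwd$mism,
          stringsAsFactors = FALSE)
      if (!palindrome) {
        rev <- .scanMismatch(graw, charToRaw(rc), k)
        if (length(rev$starts))
          out[[length(out) + 1L]] <- data.frame(
            query_id = names(q)[1L], genome_id = genomeId(g),
            contig_id = contig, start = rev$starts, end = rev$starts + m,
            orientation = "revcomp", mismatches = rev$mism,
            stringsAsFactors = FALSE)
      }
    }
  }
  .sortHits(do.call(rbind, out))
}

#' Construct a GenomeSet from in-memory sequences
#'
#' Convenience constructor mirroring [readGenomeFasta()] for sequences built
#' in code (tests, examples, fixtures).
#'
#' @param genomeId genome label.
#' @param sequences named character vector of contig sequences.
#' @return a [GenomeSet].
#' @export
genomeSet <- function(genomeId, sequences) {
  g <- new("GenomeSet", genomeId = as.character(genomeId),
           sequences = Biostrings::DNAStringSet(toupper(sequences)))
  validObject(g)
  g
}
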