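#' Hamming distance between two equal-length sequences
#'
#' @param a,b character strings of equal length.
#' @return integer count of differing positions.
#' @examples
#' hammingDistance("GCCATTTGAC", "GCGATTTGTC")  # 2
#' @export
hammingDistance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop(sprintf("sequences have unequal lengths (%d vs %d)",
                 nchar(a), nchar(b)))
  sum(charToRaw(toupper(a)) != charToRaw(toupper(b)))
}

#' Positions at which two equal-length sequences differ
#'
#' @param a,b character strings of equal length.
#' @return 1-based integer vector of mismatch positions.
#' @examples
#' mismatchPositions("GCCATTTGAC", "GCGATTTGTC")  # 3 9
#' @export
mismatchPositions <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop(sprintf("sequences have unequal lengths (%d vs %d)",
                 nchar(a), nchar(b)))
  which(charToRaw(toupper(a)) != charToRaw(toupper(b)))
}

.gcCount <- function(seq) {
  sum(strsplit(toupper(seq), "", fixed = TRUE)[[1L]] %in% c("G", "C"))
}

#' Generate mismatch-control candidates for a parent PNA
#'
#' Enumerates every sequence at Hamming distance exactly `minMismatches`
#' from the parent (all position combinations, all three alternative bases
#' per mutated position; a single-base mismatch may still permit binding, so
#' the default distance is 2). With `atLeast = TRUE` the distance policy is
#' relaxed to "at least", enumerating increasing distances until
#' `maxCandidates` is filled. The parent itself is never emitted.
#'
#' Candidates are returned in a deterministic rank order: GC content closest
#' to the parent first (a crude proxy for a similar melting temperature),
#' then lexicographic sequence. [validateControls()] refines this ranking
#' with scan results.
#'
#' @param parent a [PNAOligo] or a sequence over {A,C,G,T}.
#' @param minMismatches required Hamming distance (default 2; must be
#'   `>= 1` and `< nchar(parent)`).
#' @param maxCandidates truncate the ranked list (default 20; `Inf` keeps
#'   the full enumeration, not permitted with `atLeast = TRUE`).
#' @param atLeast relax the distance policy from "exactly" to "at least".
#' @return data.frame: `parent_id`, `candidate_seq`, `mismatch_positions`
#'   (comma-separated 1-based), `hamming`, `gc_delta`, `validation`
#'   (`"unvalidated"`).
#' @examples
#' ctrl <- generateControls("GCCATTTGAC", maxCandidates = Inf)
#' "GCGATTTGTC" %in% ctrl$candidate_seq  # TRUE
#' @export
generateControls <- function(parent, minMismatches = 2L, maxCandidates = 20L,
                             atLeast = FALSE) {
  pid <- if (is(parent, "PNAOligo")) pnaId(parent) else "parent"
  pseq <- if (is(parent, "PNAOligo")) pnaSequence(parent) else
    toupper(as.character(parent))
  .checkQuery(pseq, pid)
  L <- nchar(pseq)
  m0 <- as.integer(minMismatches)
  if (is.na(m0) || m0 < 1L)
    stop("minMismatches must be >= 1 (0 would return the parent itself)")
  if (m0 >= L)
    stop(sprintf("minMismatches must be < parent length (%d)", L))
  if (atLeast && !is.finite(maxCandidates))
    stop("atLeast = TRUE requires a finite maxCandidates")
  pchars <- strsplit(pseq, "", fixed = TRUE)[[1L]]
  pgc <- .gcCount(pseq)
  bases <- c("A", "C", "G", "T")

  enumerate <- function(m) {
    pos_sets <- utils::combn(L, m, simplify = FALSE)
    rows <- list()
    for (pos in pos_sets) {
      alts <- lapply(pos, function(p) setdiff(bases, pchars[p]))
      grid <- expand.grid(alts, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        cand <- pchars
        cand[pos] <- as.character(grid[r, ])
        rows[[length(rows) + 1L]] <- data.frame(
          parent_id = pid, candidate_seq = paste(cand, collapse = ""),
          mismatch_positions = paste(pos, collapse = ","),
          hamming = m, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  dists <- if (atLeast) seq.int(m0, L - 1L) else m0
  out <- NULL
  for (m in dists) {
    df <- enumerate(m)
    df$gc_delta <- abs(vapply(df$candidate_seq, .gcCount, integer(1)) - pgc)
    df <- df[order(df$gc_delta, df$candidate_seq), , drop = FALSE]
    out <- rbind(out, df)
    if (is.finite(maxCandidates) && nrow(out) >= maxCandidates) break
  }
  if (is.finite(maxCandidates) && nrow(out) > maxCandidates)
    out <- out[seq_len(maxCandidates), , drop = FALSE]
  out$validation <- "unvalidated"
  rownames(out) <- NULL
  out
}

#' Validate a control candidate against a holo-genome
#'
#' A candidate passes iff an exact scan ([scanHoloGenome()]) reports zero
#' `TSS_included` hits in every scanned genome — i.e. no perfect match of
#' the candidate or its reverse complement at any translational start site.
#' CDS-interior perfect matches do not fail a candidate (a mid-CDS match is
#' far less sensitive to antisense inhibition than the start site) but are
#' counted for ranking.
#'
#' @param candidate a sequence, [PNAOligo], or one row of
#'   [generateControls()] output.
#' @param genomeSets list of [AnnotatedGenome].
#' @param sdWindow,tssRule passed to [annotateHits()].
#' @return a one-row data.frame: `candidate_seq`, `hamming` (NA when the
#'   candidate was not generated from a parent), `validation`
#'   (`"pass"`/`"fail"`), `fail_reason` (first offending
#'   genome/gene/position, or `""`), `n_tss_hits`, `n_cds_hits`.
#' @export
validateControl <- function(candidate, genomeSets, sdWindow = c(-15L, -5L),
                            tssRule = "first-base") {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    seq <- candidate$candidate_seq
    ham <- candidate$hamming
    pos <- candidate$mismatch_positions
    pid <- candidate$parent_id
  } else if (is(candidate, "PNAOligo")) {
    seq <- pnaSequence(candidate)
    ham <- NA_integer_
    pos <- ""
    pid <- pnaId(candidate)
  } else {
    seq <- toupper(as.character(candidate))
    ham <- NA_integer_
    pos <- ""
    pid <- "candidate"
  }
  res <- scanHoloGenome(stats::setNames(seq, "candidate"), genomeSets,
                        sdWindow = sdWindow, tssRule = tssRule)
  tss_hits <- res$hits[res$hits$tss_included, , drop = FALSE]
  n_cds <- sum(res$hits$overlap_class == "CDS_internal")
  fail_reason <- ""
  if (nrow(tss_hits)) {
    h <- tss_hits[1L, ]
    fail_reason <- sprintf(
      "perfect match at translational start site of %s (%s:%s:%d)",
      h$gene_ids, h$genome_id, h$contig_id, h$start + 1L)
  }
  data.frame(parent_id = pid, candidate_seq = seq,
             mismatch_positions = pos, hamming = ham,
             validation = if (nrow(tss_hits)) "fail" else "pass",
             fail_reason = fail_reason,
             n_tss_hits = nrow(tss_hits), n_cds_hits = n_cds,
             stringsAsFactors = FALSE)
}

#' Validate and rank a set of control candidates
#'
#' Applies [validateControl()] to every row and re-ranks by: passing
#' candidates first, then fewer CDS-interior perfect hits across the
#' scanned genomes, then GC content closest to the parent, then
#' lexicographic sequence (a deterministic tie-break).
#'
#' @param candidates output of [generateControls()].
#' @param parent the parent PNA (sequence or [PNAOligo]) used for the GC
#'   tie-break; defaults to reconstructing GC from `gc_delta` if present.
#' @param genomeSets,sdWindow,tssRule as in [validateControl()].
#' @return the candidates with validation columns, ranked.
#' @export
validateControls <- function(candidates, genomeSets, parent = NULL,
                             sdWindow = c(-15L, -5L),
                             tssRule = "first-base") {
  rows <- lapply(seq_len(nrow(candidates)), function(i)
    validateControl(candidates[i, , drop = FALSE], genomeSets,
                    sdWindow = sdWindow, tssRule = tssRule))
  out <- do.call(rbind, rows)
  out$gc_delta <- if ("gc_delta" %in% names(candidates))
    candidates$gc_delta
  else if (!is.null(parent)) {
    pseq <- if (is(parent, "PNAOligo")) pnaSequence(parent) else
      toupper(as.character(parent))
    abs(vapply(out$candidate_seq, .gcCount, integer(1)) - .gcCount(pseq))
  } else NA_integer_
  o <- order(out$validation != "pass", out$n_cds_hits, out$gc_delta,
             out$candidate_seq)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
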