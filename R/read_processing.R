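#' Primer-trimming specification
#'
#' Encodes the positional trimming rule applied to raw terminus-capture
#' reads: a primer/adaptor is recognised at a read end only if it starts
#' within `max_offset` bases of that end, and on recognition the primer plus
#' everything between it and the end is removed.
#'
#' @param primers character vector of primer/adaptor sequences (A/C/G/T).
#' @param max_offset maximum distance (bp) of the primer start from the read
#'   end for the match to count (default 5).
#' @param max_mismatches mismatches tolerated in the primer match (default 0,
#'   exact matching).
#' @param min_len minimum read length retained downstream (default 18 bp).
#' @return object of class `trim_spec`.
#' @export
trim_spec <- function(primers, max_offset = 5L, max_mismatches = 0L,
                      min_len = 18L) {
  if (length(primers) == 0L || any(!nzchar(primers)))
    stop("'primers' must contain at least one non-empty sequence")
  if (max_offset < 0) stop("'max_offset' must be >= 0")
  if (max_mismatches < 0) stop("'max_mismatches' must be >= 0")
  if (min_len < 1) stop("'min_len' must be >= 1")
  structure(list(primers = toupper(primers),
                 max_offset = as.integer(max_offset),
                 max_mismatches = as.integer(max_mismatches),
                 min_len = as.integer(min_len)),
            class = "trim_spec")
}

# All (start, end) matches of pattern in subjects with <= mm mismatches.
find_matches <- function(pattern, subjects, mm) {
  Biostrings::vmatchPattern(pattern, subjects, max.mismatch = mm,
                            fixed = TRUE)
}

#' Trim primers from read ends under the positional rule
#'
#' Scans both read ends for each primer and its reverse complement.  A 5' hit
#' must start within `max_offset` bases of the read start; a 3' hit must end
#' within `max_offset` bases of the read end.  On a hit the primer and
#' everything outside it are removed; both ends can be trimmed.  When several
#' hits qualify at one end, the one closest to that end wins (ties broken by
#' primer order).  Reads with no qualifying hit pass through untouched.
#'
#' @param reads named character vector of sequences, a `DNAStringSet`, or a
#'   data.frame with columns `read_id` and `sequence`.
#' @param spec a [trim_spec()].
#' @return data.frame: read_id, sequence (trimmed), trim5, trim3 (bases
#'   removed from each end).
#' @export
trim_primers <- function(reads, spec) {
  stopifnot(inherits(spec, "trim_spec"))
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- Biostrings::DNAStringSet(reads$sequence)
  } else if (methods::is(reads, "DNAStringSet")) {
    ids <- names(reads)
    seqs <- reads
  } else {
    ids <- names(reads)
    seqs <- Biostrings::DNAStringSet(reads)
  }
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(seqs))
  n <- length(seqs)
  w <- Biostrings::width(seqs)

  pats <- character(0)
  for (p in spec$primers) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(p)))
    pats <- c(pats, p, rc)
  }
  pats <- unique(pats)

  # per read: rightmost coordinate removed at 5' end, leftmost removed at 3'
  cut5 <- integer(n)          # 0 = nothing removed
  off5 <- rep(Inf, n)         # offset of the winning 5' hit
  cut3 <- w + 1L              # w+1 = nothing removed
  off3 <- rep(Inf, n)

  for (p in pats) {
    m <- find_matches(p, seqs, spec$max_mismatches)
    st <- BiocGenerics::start(m)
    en <- BiocGenerics::end(m)
    for (i in seq_len(n)) {
      if (length(st[[i]]) == 0L) next
      s <- st[[i]]; e <- en[[i]]
      ok <- s >= 1L & e <= w[i]
      s <- s[ok]; e <- e[ok]
      if (!length(s)) next
      o5 <- s - 1L
      q5 <- which(o5 <= spec$max_offset)
      if (length(q5)) {
        j <- q5[which.min(o5[q5])]
        if (o5[j] < off5[i]) { off5[i] <- o5[j]; cut5[i] <- e[j] }
      }
      o3 <- w[i] - e
      q3 <- which(o3 <= spec$max_offset)
      if (length(q3)) {
        j <- q3[which.min(o3[q3])]
        if (o3[j] < off3[i]) { off3[i] <- o3[j]; cut3[i] <- s[j] }
      }
    }
  }

  from <- cut5 + 1L
  to <- cut3 - 1L
  out <- character(n)
  keepable <- to >= from
  out[keepable] <- substr(as.character(seqs)[keepable],
                          from[keepable], to[keepable])
  data.frame(read_id = ids, sequence = out,
             trim5 = cut5, trim3 = pmax(w - cut3 + 1L, 0L),
             stringsAsFactors = FALSE)
}

#' Drop reads shorter than a length threshold
#'
#' Reads shorter than `min_len` bases are removed (the standard cut-off is
#' 18 bp); order of the survivors is preserved and the number dropped is
#' reported.
#'
#' @param reads data.frame with a `sequence` column (e.g. from
#'   [trim_primers()]) or a character vector.
#' @param min_len minimum length retained, inclusive.
#' @return list with `kept` (same shape as input) and `dropped` (count).
#' @export
filter_short <- function(reads, min_len = 18L) {
  if (min_len < 1) stop("'min_len' must be >= 1")
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  keep <- nchar(seqs) >= min_len
  kept <- if (is.data.frame(reads)) reads[keep, , drop = FALSE]
          else reads[keep]
  if (is.data.frame(kept)) rownames(kept) <- NULL
  list(kept = kept, dropped = sum(!keep))
}

#' Load mapped read intervals from a BED-like file
#'
#' Reads a 6-column BED (or the equivalent tab-separated minimal alignment
#' format), validates coordinates against the chromosome sizes, and infers
#' which interval end carries the DSB cut from the strand column: on `+`
#' alignments the cut is the left (5'-most) coordinate, on `-` the right.
#' The convention is configurable because deposited data may encode it the
#' other way round.
#'
#' @param path BED file (0-based half-open).  Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @param chrom_sizes named vector of chromosome lengths (or 2-column
#'   data.frame).
#' @param cut_side_convention `"plus_left"` (default) or `"plus_right"`.
#' @return data.frame of mapped reads: chrom, start, end, strand, cut_side
#'   (`"left"`/`"right"`), read_id.
#' @export
load_alignments <- function(path, chrom_sizes,
                            cut_side_convention = c("plus_left",
                                                    "plus_right")) {
  cut_side_convention <- match.arg(cut_side_convention)
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      cut_side = character(0), read_id = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("line %d: fewer than 3 BED fields", lineno[which(nf < 3L)[1L]]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  name <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""),
                 sprintf("aln%06d", seq_along(parts)))
  strand <- ifelse(nf >= 6L, vapply(parts, function(p) p[min(6L, length(p))], ""),
                   "+")
  strand[!strand %in% c("+", "-")] <- "+"

  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop(sprintf("line %d: non-numeric coordinates", lineno[bad[1L]]))
  unknown <- which(!chrom %in% names(chrom_sizes))
  if (length(unknown))
    stop(sprintf("line %d: unknown chromosome '%s'",
                 lineno[unknown[1L]], chrom[unknown[1L]]))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("line %d: end <= start", lineno[bad[1L]]))
  oob <- which(start < 0 | end > chrom_sizes[chrom])
  if (length(oob))
    stop(sprintf("line %d: interval outside chromosome bounds",
                 lineno[oob[1L]]))

  left_on_plus <- cut_side_convention == "plus_left"
  cut_side <- ifelse((strand == "+") == left_on_plus, "left", "right")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             cut_side = cut_side, read_id = name, stringsAsFactors = FALSE)
}
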