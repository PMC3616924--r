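# Independent brute-force oracles, kept free of the package's internals.

# O(n^2) pairwise-overlap merge: repeatedly fuse any two intervals that
# overlap by >= 1 bp (0-based half-open) until a fixed point.
oracle_merge <- function(df) {
  out <- list()
  for (chrom in sort(unique(df$chrom))) {
    iv <- df[df$chrom == chrom, c("start", "end"), drop = FALSE]
    iv <- as.list(as.data.frame(t(as.matrix(iv))))
    repeat {
      fused <- FALSE
      for (i in seq_along(iv)) {
        if (is.null(iv[[i]])) next
        for (j in seq_along(iv)) {
          if (i == j || is.null(iv[[j]])) next
          a <- iv[[i]]; b <- iv[[j]]
          if (a[1] < b[2] && b[1] < a[2]) {
            iv[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
            iv[[j]] <- NULL
            fused <- TRUE
            break
          }
        }
        if (fused) break
      }
      if (!fused) break
    }
    iv <- iv[!vapply(iv, is.null, TRUE)]
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1]), , drop = FALSE]
    out[[chrom]] <- data.frame(chrom = chrom, start = m[, 1], end = m[, 2])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exhaustive sliding-match primer trimmer: scan every start offset
# 0..max_offset at the 5' end and every end offset at the 3' end for an
# exact primer (or reverse-complement) occurrence; closest-to-end wins.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_trim_one <- function(seq, primers, max_offset = 5) {
  pats <- unique(c(primers, vapply(primers, oracle_revcomp, "")))
  w <- nchar(seq)
  cut5 <- 0; cut3 <- w + 1
  for (off in 0:max_offset) {            # 5' end: first offset with a hit
    hit <- FALSE
    for (p in pats) {
      pl <- nchar(p)
      if (off + pl <= w && substr(seq, off + 1, off + pl) == p) {
        cut5 <- off + pl; hit <- TRUE; break
      }
    }
    if (hit) break
  }
  for (off in 0:max_offset) {            # 3' end, scanning inward
    hit <- FALSE
    for (p in pats) {
      pl <- nchar(p)
      st <- w - off - pl + 1
      if (st >= 1 && substr(seq, st, st + pl - 1) == p) {
        cut3 <- st; hit <- TRUE; break
      }
    }
    if (hit) break
  }
  if (cut3 - 1 < cut5 + 1) "" else substr(seq, cut5 + 1, cut3 - 1)
}

# Brute-force fragment builder on an explicit site list (0-based points).
oracle_fragment <- function(cut, side, sites, chrom_len, max_len) {
  if (side == "left") {
    cand <- sites[sites < cut]
    s <- if (length(cand)) max(cand) else 0
    s <- max(s, cut - max_len, 0)
    if (s >= cut) NULL else c(s, cut)
  } else {
    cand <- sites[sites > cut]
    e <- if (length(cand)) min(cand) else chrom_len
    e <- min(e, cut + max_len, chrom_len)
    if (e <= cut) NULL else c(cut, e)
  }
}

# Brute-force window counts by midpoint membership.
oracle_density <- function(mids, chrom_len, window, step) {
  ws <- seq(0, max(0, chrom_len - 1), by = step)
  vapply(ws, function(s) sum(mids >= s & mids < s + window), 0)
}

# Convert simulator truth alignments to the mapped-read data frame the
# FT caller consumes ('+' alignments carry the cut at the left coordinate).
truth_to_mapped <- function(aln) {
  data.frame(chrom = aln$chrom, start = aln$start, end = aln$end,
             strand = aln$strand,
             cut_side = ifelse(aln$strand == "+", "left", "right"),
             read_id = aln$name, stringsAsFactors = FALSE)
}
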