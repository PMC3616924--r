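#' Collapse mapped reads into forum-domain termini (FT)
#'
#' An FT is the maximal union of overlapping mapped reads around a DSB: one
#' side of each read is the blunt cut, the other a Sau3A site.  Reads on a
#' chromosome are merged when they overlap by at least one base, or when they
#' lie within `min_gap` bases of each other (`min_gap = 0`, the default,
#' merges strict overlaps only).  Reads from either strand merge together: FT
#' flank a break from both sides.
#'
#' @param reads data.frame of mapped reads as returned by
#'   [load_alignments()] (columns chrom, start, end, cut_side; extra columns
#'   ignored).
#' @param min_gap merge reads separated by fewer than `min_gap` bases
#'   (default 0 = overlap required).
#' @return data.frame of class `forum_ft`, sorted and non-overlapping:
#'   ft_id, chrom, start, end (0-based half-open), read_count,
#'   n_cut_positions, cut_span (bp between extreme distinct cut positions),
#'   hotspot (all `FALSE`; see [classify_hotspots()]), and a list column
#'   `cut_positions` of the distinct DSB-end coordinates of merged reads.
#' @export
call_ft <- function(reads, min_gap = 0L) {
  empty <- data.frame(ft_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      read_count = integer(0), n_cut_positions = integer(0),
                      cut_span = numeric(0), hotspot = logical(0))
  empty$cut_positions <- list()
  if (is.null(reads) || nrow(reads) == 0L)
    return(structure(empty, class = c("forum_ft", "data.frame")))
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  if (is.null(reads$cut_side))
    reads$cut_side <- "left"

  res <- list()
  for (chrom in sort(unique(reads$chrom))) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    red <- IRanges::reduce(ir, min.gapwidth = max(0L, as.integer(min_gap)),
                           with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    cuts <- ifelse(r$cut_side == "left", r$start, r$end)
    for (k in seq_along(red)) {
      idx <- revmap[[k]]
      cp <- sort(unique(cuts[idx]))
      res[[length(res) + 1L]] <- list(
        chrom = chrom,
        start = BiocGenerics::start(red)[k] - 1L,
        end = BiocGenerics::end(red)[k],
        read_count = length(idx),
        cut_positions = cp)
    }
  }
  ft <- data.frame(
    ft_id = sprintf("ft%05d", seq_along(res)),
    chrom = vapply(res, `[[`, "", "chrom"),
    start = vapply(res, `[[`, 0, "start"),
    end = vapply(res, `[[`, 0, "end"),
    read_count = vapply(res, function(x) as.integer(x$read_count), 0L),
    n_cut_positions = vapply(res, function(x) length(x$cut_positions), 0L),
    cut_span = vapply(res, function(x)
      diff(range(x$cut_positions)), 0),
    hotspot = FALSE,
    stringsAsFactors = FALSE)
  ft$cut_positions <- lapply(res, `[[`, "cut_positions")
  ord <- order(ft$chrom, ft$start)
  ft <- ft[ord, , drop = FALSE]
  ft$ft_id <- sprintf("ft%05d", seq_len(nrow(ft)))
  rownames(ft) <- NULL
  structure(ft, class = c("forum_ft", "data.frame"))
}

#' Flag FT supported by multiple overlapping reads as DSB hot spots
#'
#' Recurrent breakage shows up as an FT built from several overlapping
#' reads; the read count is the evidence unit.  FT with
#' `read_count >= min_support` get `hotspot = TRUE`; the rest are retained
#' unflagged.
#'
#' @param ft a `forum_ft` from [call_ft()].
#' @param min_support minimum merged-read count (default 2).
#' @param quiet suppress the flag-count message.
#' @return the input with the `hotspot` column set.
#' @export
classify_hotspots <- function(ft, min_support = 2L, quiet = FALSE) {
  if (min_support < 1) stop("'min_support' must be >= 1")
  ft$hotspot <- ft$read_count >= min_support
  if (!quiet)
    message(sprintf("classify_hotspots: %d/%d FT flagged (min_support=%d)",
                    sum(ft$hotspot), nrow(ft), as.integer(min_support)))
  ft
}

#' Write FT to BED6
#'
#' BED is 0-based half-open; name = ft_id, score = read_count, strand `.`;
#' a trailing column carries the hot-spot flag so the file round-trips.
#'
#' @param ft a `forum_ft`.
#' @param path output path.
#' @export
write_ft_bed <- function(ft, path) {
  df <- data.frame(ft$chrom, as.integer(ft$start), as.integer(ft$end),
                   ft$ft_id, ft$read_count, ".",
                   as.integer(ft$hotspot))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read FT from a BED file written by [write_ft_bed()]
#' @param path BED path.
#' @return `forum_ft` data.frame (cut-position detail is not stored in BED;
#'   `cut_positions` comes back empty with `n_cut_positions = NA`).
#' @export
read_ft_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  ft <- data.frame(ft_id = as.character(df[[4L]]), chrom = df[[1L]],
                   start = as.numeric(df[[2L]]), end = as.numeric(df[[3L]]),
                   read_count = as.integer(df[[5L]]),
                   n_cut_positions = NA_integer_, cut_span = NA_real_,
                   hotspot = if (ncol(df) >= 7L) df[[7L]] == 1L else FALSE,
                   stringsAsFactors = FALSE)
  ft$cut_positions <- rep(list(numeric(0)), nrow(ft))
  structure(ft, class = c("forum_ft", "data.frame"))
}

#' Write FT to GFF3
#'
#' GFF uses 1-based inclusive coordinates: an FT `[100, 350)` in BED space
#' becomes `101 350` here.
#'
#' @param ft a `forum_ft`.
#' @param path output path.
#' @export
write_ft_gff <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ft)) {
    attr_col <- sprintf("ID=%s;read_count=%d;hotspot=%d",
                        ft$ft_id, ft$read_count, as.integer(ft$hotspot))
    lines <- sprintf("%s\tforumdomains\tforum_terminus\t%d\t%d\t%d\t.\t.\t%s",
                     ft$chrom, as.integer(ft$start) + 1L, as.integer(ft$end),
                     ft$read_count, attr_col)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read FT from a GFF3 file written by [write_ft_gff()]
#' @param path GFF path.
#' @return `forum_ft` data.frame.
#' @export
read_ft_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(call_ft(NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  getattr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    sub(paste0(key, "="), "", m)
  }
  attrs <- vapply(parts, `[[`, "", 9L)
  ft <- data.frame(
    ft_id = vapply(attrs, getattr, "", key = "ID", USE.NAMES = FALSE),
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 4L)) - 1,
    end = as.numeric(vapply(parts, `[[`, "", 5L)),
    read_count = as.integer(vapply(attrs, getattr, "", key = "read_count",
                                   USE.NAMES = FALSE)),
    n_cut_positions = NA_integer_, cut_span = NA_real_,
    hotspot = vapply(attrs, getattr, "", key = "hotspot",
                     USE.NAMES = FALSE) == "1",
    stringsAsFactors = FALSE)
  ft$cut_positions <- rep(list(numeric(0)), nrow(ft))
  structure(ft, class = c("forum_ft", "data.frame"))
}
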