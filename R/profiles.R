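#' FT density in sliding windows along chromosomes
#'
#' Counts FT per window of width `window`, advancing by `step` (defaults:
#' 500 kb windows, 100 kb step).  An FT is counted in a window when its
#' midpoint lies in `[window_start, window_start + window)`, so overlapping
#' windows never double-count an FT boundary; the last windows of a
#' chromosome are truncated at its end.
#'
#' @param ft a `forum_ft` data.frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window window width, bp.
#' @param step window step, bp (must be <= window).
#' @return data.frame of class `ft_density_track`: chrom, window_start,
#'   count; attributes `window` and `step`.
#' @export
ft_density <- function(ft, chrom_sizes, window = 500000, step = 100000) {
  if (window <= 0 || step <= 0) stop("'window' and 'step' must be positive")
  if (step > window) stop("'step' must not exceed 'window'")
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  out <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    ws <- seq(0, max(0, len - 1), by = step)
    x <- ft[ft$chrom == chrom, , drop = FALSE]
    mids <- sort(interval_midpoint(x$start, x$end))
    # count in [ws, ws+window) via the empirical CDF of sorted midpoints
    cnt <- findInterval(pmin(ws + window, len) - 0.5, mids) -
      findInterval(ws - 0.5, mids)
    out[[chrom]] <- data.frame(chrom = chrom, window_start = ws,
                               count = as.integer(cnt),
                               stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  structure(track, window = window, step = step,
            class = c("ft_density_track", "data.frame"))
}

#' Export a density track as fixedStep WIG
#'
#' WIG is 1-based: each window contributes one value anchored at
#' `window_start + 1` with `span = step` (the window count is assigned to
#' the fresh `step`-sized stretch each window adds, keeping spans
#' non-overlapping as WIG requires).
#'
#' @param track a `ft_density_track` from [ft_density()].
#' @param path output path.
#' @export
export_wig <- function(track, path) {
  step <- attr(track, "step")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=ft_density description=\"FT density window=%d step=%d\"",
                     as.integer(attr(track, "window")), as.integer(step)),
             con)
  for (chrom in unique(track$chrom)) {
    x <- track[track$chrom == chrom, , drop = FALSE]
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       chrom, as.integer(x$window_start[1L]) + 1L,
                       as.integer(step), as.integer(step)), con)
    writeLines(format(x$count, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Re-parse a fixedStep WIG written by [export_wig()]
#' @param path WIG path.
#' @return data.frame: chrom, window_start (0-based), count.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines) & nzchar(lines)]
  out <- list()
  chrom <- NULL; at <- 0; step <- 1
  for (ln in lines) {
    if (grepl("^fixedStep", ln)) {
      chrom <- sub("chrom=", "",
                   regmatches(ln, regexpr("chrom=\\S+", ln)))
      at <- as.numeric(sub("start=", "",
                           regmatches(ln, regexpr("start=\\S+", ln)))) - 1
      step <- as.numeric(sub("step=", "",
                             regmatches(ln, regexpr("step=\\S+", ln))))
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, window_start = at, count = as.numeric(ln),
        stringsAsFactors = FALSE)
      at <- at + step
    }
  }
  do.call(rbind, out)
}

#' Read-subsampling saturation curve for FT recovery
#'
#' Estimates whether sequencing depth saturated FT discovery: for each
#' percentage in the schedule, reads are subsampled without replacement
#' (seeded), FT are re-called, and the percentage of full-data FT recovered
#' is recorded; a full-data FT counts as recovered when any subsample FT
#' overlaps it.  The default schedule steps by 1% from 100% down to 70% and
#' by 5% down to 10%.  The 100% point is the identity subsample, (100, 100).
#'
#' @param reads data.frame of mapped reads.
#' @param schedule percentages in (0, 100].
#' @param seed master seed; each schedule point derives its own stream.
#' @param min_gap passed to [call_ft()].
#' @return data.frame of class `saturation_curve`: read_fraction,
#'   ft_fraction (both percent), n_reads, n_ft.
#' @export
saturation_curve <- function(reads,
                             schedule = c(seq(100, 70, by = -1),
                                          seq(65, 10, by = -5)),
                             seed = 1L, min_gap = 0L) {
  if (any(schedule <= 0 | schedule > 100))
    stop("'schedule' percentages must lie in (0, 100]")
  full <- call_ft(reads, min_gap = min_gap)
  n_full <- nrow(full)
  n <- nrow(reads)
  rows <- lapply(schedule, function(pct) {
    if (pct == 100) {
      sub <- reads
    } else {
      k <- max(1L, floor(n * pct / 100))
      idx <- with_seed(derive_seed(seed, paste0("saturate_", pct)),
                       sample.int(n, k))
      sub <- reads[idx, , drop = FALSE]
    }
    subft <- call_ft(sub, min_gap = min_gap)
    rec <- 0L
    for (chrom in unique(full$chrom)) {
      a <- full[full$chrom == chrom, , drop = FALSE]
      b <- subft[subft$chrom == chrom, , drop = FALSE]
      if (!nrow(b)) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(a$start + 1L, a$end),
        IRanges::IRanges(b$start + 1L, b$end))
      rec <- rec + sum(ov > 0)
    }
    data.frame(read_fraction = pct,
               ft_fraction = if (pct == 100) 100 else 100 * rec / n_full,
               n_reads = nrow(sub), n_ft = nrow(subft))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$read_fraction), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, seed = seed,
            class = c("saturation_curve", "data.frame"))
}
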