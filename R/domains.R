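#' Segment chromosomes into forum domains
#'
#' Forum domains are the protected stretches of DNA lying between
#' consecutive forum-domain termini: per chromosome, each gap between two
#' successive boundary FT becomes a bounded domain running from the end of
#' the left FT to the start of the right one (the FT themselves are
#' excluded — domains are the DNA between breaks).  The terminal stretches
#' from the chromosome ends to the first/last FT are emitted with
#' `bounded = FALSE`; zero-length gaps between abutting FT are skipped.
#' By default only hot-spot-flagged FT act as boundaries.
#'
#' @param ft a `forum_ft` (sorted, non-overlapping).
#' @param chrom_sizes named vector of chromosome lengths (or 2-column
#'   data.frame).  Every chromosome listed gets at least one segment, even
#'   with no FT on it.
#' @param hotspots_only use only `hotspot = TRUE` FT as boundaries
#'   (default); set `FALSE` to use every FT.
#' @return data.frame of class `forum_domains`: domain_id, chrom, start, end
#'   (0-based half-open), size, left_ft_id, right_ft_id (`NA` at chromosome
#'   ends), bounded.
#' @export
segment_domains <- function(ft, chrom_sizes, hotspots_only = TRUE) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  if (nrow(ft)) {
    missing_chrom <- setdiff(unique(ft$chrom), names(chrom_sizes))
    if (length(missing_chrom))
      stop("chromosome(s) absent from chrom_sizes: ",
           paste(missing_chrom, collapse = ", "))
  }
  b <- if (hotspots_only) ft[ft$hotspot, , drop = FALSE] else ft
  segs <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    x <- b[b$chrom == chrom, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) == 0L) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = 0, end = len,
        left_ft_id = NA_character_, right_ft_id = NA_character_,
        bounded = FALSE, stringsAsFactors = FALSE)
      next
    }
    if (x$start[1L] > 0)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = 0, end = x$start[1L],
        left_ft_id = NA_character_, right_ft_id = x$ft_id[1L],
        bounded = FALSE, stringsAsFactors = FALSE)
    if (nrow(x) >= 2L) {
      gs <- x$end[-nrow(x)]
      ge <- x$start[-1L]
      keep <- ge > gs  # zero-length gaps between abutting FT are skipped
      if (any(keep))
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = chrom, start = gs[keep], end = ge[keep],
          left_ft_id = x$ft_id[-nrow(x)][keep],
          right_ft_id = x$ft_id[-1L][keep],
          bounded = TRUE, stringsAsFactors = FALSE)
    }
    if (x$end[nrow(x)] < len)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = x$end[nrow(x)], end = len,
        left_ft_id = x$ft_id[nrow(x)], right_ft_id = NA_character_,
        bounded = FALSE, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, segs)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d <- cbind(domain_id = sprintf("fd%05d", seq_len(nrow(d))), d,
             stringsAsFactors = FALSE)
  d$size <- d$end - d$start
  structure(d, class = c("forum_domains", "data.frame"))
}

#' Summary statistics of forum-domain sizes
#'
#' @param domains a `forum_domains` data.frame.
#' @param bounded_only restrict to domains flanked by FT on both sides
#'   (default; terminal segments would bias the extremes).
#' @param n_bins number of log-spaced histogram bins.
#' @return list: n, min, max, median (mean-of-middles for even counts, i.e.
#'   [stats::median()]), and `histogram` (data.frame with log-spaced bin
#'   edges and counts).
#' @export
domain_size_stats <- function(domains, bounded_only = TRUE, n_bins = 20L) {
  sz <- if (bounded_only) domains$size[domains$bounded] else domains$size
  if (!length(sz)) stop("no domains to summarize")
  edges <- exp(seq(log(max(min(sz), 1)), log(max(sz) + 1),
                   length.out = n_bins + 1L))
  edges[1L] <- min(sz)
  edges[length(edges)] <- max(sz) + 1
  counts <- graphics::hist(sz, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  list(n = length(sz), min = min(sz), max = max(sz),
       median = stats::median(sz),
       histogram = data.frame(bin_start = edges[-length(edges)],
                              bin_end = edges[-1L], count = counts))
}

# Midpoint of a 0-based half-open interval (floor for odd widths).
interval_midpoint <- function(start, end) floor((start + end) / 2)

#' Assign genes to forum domains by midpoint and summarise gene content
#'
#' A gene belongs to the domain containing its interval midpoint, so a gene
#' straddling a boundary counts once, in the side holding more of it.  The
#' summary reports the fraction of domains carrying k genes and, explicitly,
#' the fraction carrying three to seven genes.
#'
#' @param domains a `forum_domains` data.frame.
#' @param genes data.frame with columns gene_id, chrom, start, end.
#' @return list: `domains` (input plus list column `gene_ids` and integer
#'   `n_genes`) and `stats` (data.frame k / n_domains / fraction, plus
#'   attribute-free scalar `frac_3_7` returned as list element).
#' @export
annotate_gene_content <- function(domains, genes) {
  n <- nrow(domains)
  gene_ids <- rep(list(character(0)), n)
  if (!is.null(genes) && nrow(genes)) {
    mid <- interval_midpoint(genes$start, genes$end)
    for (chrom in unique(genes$chrom)) {
      gi <- which(genes$chrom == chrom)
      di <- which(domains$chrom == chrom)
      if (!length(di)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = mid[gi] + 1L, width = 1L),
        IRanges::IRanges(start = domains$start[di] + 1L,
                         end = domains$end[di]))
      for (h in seq_along(S4Vectors::queryHits(hits))) {
        q <- gi[S4Vectors::queryHits(hits)[h]]
        s <- di[S4Vectors::subjectHits(hits)[h]]
        gene_ids[[s]] <- c(gene_ids[[s]], genes$gene_id[q])
      }
    }
  }
  domains$gene_ids <- gene_ids
  domains$n_genes <- lengths(gene_ids)
  tab <- table(factor(domains$n_genes, levels = 0:max(domains$n_genes)))
  stats <- data.frame(k = as.integer(names(tab)),
                      n_domains = as.integer(tab),
                      fraction = as.numeric(tab) / n)
  list(domains = domains, stats = stats,
       frac_3_7 = mean(domains$n_genes >= 3 & domains$n_genes <= 7))
}

#' Write forum domains to BED
#'
#' name = domain_id, score = gene count when present (0 otherwise), strand
#' `.`; a trailing column flags bounded domains.
#'
#' @param domains a `forum_domains` data.frame.
#' @param path output path.
#' @export
write_domains_bed <- function(domains, path) {
  score <- if (!is.null(domains$n_genes)) domains$n_genes else 0L
  df <- data.frame(domains$chrom, as.integer(domains$start),
                   as.integer(domains$end), domains$domain_id, score, ".",
                   as.integer(domains$bounded))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
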