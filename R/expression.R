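#' Collapse exon-level signals to per-gene median expression
#'
#' Each gene's expression value is the median of its exon (coding-region)
#' signals — mean of the two middle values for even counts — followed by a
#' log2(x + 1) transform by default.
#'
#' @param exon_signals data.frame with columns `gene_id` and `value`
#'   (one row per exon signal); optional columns chrom/start/end are carried
#'   through from `genes`.
#' @param genes optional data.frame (gene_id, chrom, start, end) supplying
#'   coordinates for the output table.
#' @param transform `"log2p1"` (default) applies log2(x + 1); `"identity"`
#'   leaves values as supplied (use when signals are already log scale).
#' @return expression table data.frame: gene_id [, chrom, start, end], value.
#' @export
gene_median_expression <- function(exon_signals, genes = NULL,
                                   transform = c("log2p1", "identity")) {
  transform <- match.arg(transform)
  stopifnot(all(c("gene_id", "value") %in% names(exon_signals)))
  x <- exon_signals[is.finite(exon_signals$value), , drop = FALSE]
  dropped <- setdiff(unique(exon_signals$gene_id), unique(x$gene_id))
  if (length(dropped))
    warning(sprintf("%d gene(s) had no finite signal and were dropped",
                    length(dropped)))
  med <- tapply(x$value, x$gene_id, stats::median)
  out <- data.frame(gene_id = names(med), value = as.numeric(med),
                    stringsAsFactors = FALSE)
  if (transform == "log2p1") out$value <- log2(out$value + 1)
  if (!is.null(genes)) {
    m <- match(out$gene_id, genes$gene_id)
    out <- data.frame(gene_id = out$gene_id, chrom = genes$chrom[m],
                      start = genes$start[m], end = genes$end[m],
                      value = out$value, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Midpoint-assign expression rows to domains; returns the expression table
# with a domain_id column (NA when the midpoint falls into no domain).
assign_genes_to_domains <- function(expr, domains) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(expr)))
  expr$domain_id <- NA_character_
  mid <- interval_midpoint(expr$start, expr$end)
  for (chrom in unique(expr$chrom)) {
    gi <- which(expr$chrom == chrom)
    di <- which(domains$chrom == chrom)
    if (!length(di)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = mid[gi] + 1L, width = 1L),
      IRanges::IRanges(start = domains$start[di] + 1L,
                       end = domains$end[di]))
    expr$domain_id[gi[S4Vectors::queryHits(hits)]] <-
      domains$domain_id[di[S4Vectors::subjectHits(hits)]]
  }
  expr
}

#' Per-domain expression summaries and activity classification
#'
#' Genes are assigned to domains by interval midpoint; each domain's
#' expression is the median of its genes' values.  A domain is classed
#' `active` when its median exceeds the chromosome average — the arithmetic
#' mean of the per-domain medians of gene-bearing domains on that
#' chromosome — and `low_or_silent` otherwise.  Domains without genes have
#' no median, are classed `low_or_silent`, and are excluded from the
#' chromosome average.
#'
#' @param domains a `forum_domains` data.frame.
#' @param expr expression table (gene_id, chrom, start, end, value).
#' @return list of class `domain_expression`: `domains` (domain_id, chrom,
#'   start, end, n_genes, median_value, chrom_average, class) and
#'   `chrom_summary` (chrom, chrom_average, n_domains, n_gene_bearing,
#'   active_fraction over gene-bearing domains).
#' @export
domain_expression <- function(domains, expr) {
  expr <- assign_genes_to_domains(expr, domains)
  med <- tapply(expr$value, expr$domain_id, stats::median)
  d <- data.frame(domain_id = domains$domain_id, chrom = domains$chrom,
                  start = domains$start, end = domains$end,
                  stringsAsFactors = FALSE)
  d$n_genes <- as.integer(table(factor(expr$domain_id,
                                       levels = d$domain_id)))
  d$median_value <- as.numeric(med[d$domain_id])

  avg <- tapply(d$median_value[d$n_genes > 0], d$chrom[d$n_genes > 0], mean)
  d$chrom_average <- as.numeric(avg[d$chrom])
  d$class <- ifelse(d$n_genes > 0 & !is.na(d$chrom_average) &
                      d$median_value > d$chrom_average,
                    "active", "low_or_silent")

  gb <- d[d$n_genes > 0, , drop = FALSE]
  chrom_summary <- do.call(rbind, lapply(unique(d$chrom), function(ch) {
    dd <- d[d$chrom == ch, , drop = FALSE]
    gg <- gb[gb$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch,
               chrom_average = if (nrow(gg)) mean(gg$median_value) else NA,
               n_domains = nrow(dd), n_gene_bearing = nrow(gg),
               active_fraction = if (nrow(gg))
                 mean(gg$class == "active") else NA,
               stringsAsFactors = FALSE)
  }))
  rownames(chrom_summary) <- NULL
  structure(list(domains = d, chrom_summary = chrom_summary),
            class = "domain_expression")
}

#' Percentage of low-expressing or silent forum domains
#'
#' The complement of the active fraction, per chromosome; accepts one
#' `domain_expression` result or a named list of them (one per dataset /
#' cell line).
#'
#' @param domains_expr a `domain_expression` or named list of them.
#' @param gene_bearing_only compute over gene-bearing domains only
#'   (default), matching the active-fraction denominator; `FALSE` counts
#'   empty domains as silent.
#' @return data.frame: dataset, chrom, pct_low_or_silent.
#' @export
silent_fraction <- function(domains_expr, gene_bearing_only = TRUE) {
  if (inherits(domains_expr, "domain_expression"))
    domains_expr <- list(dataset1 = domains_expr)
  out <- list()
  for (nm in names(domains_expr)) {
    d <- domains_expr[[nm]]$domains
    if (gene_bearing_only) d <- d[d$n_genes > 0, , drop = FALSE]
    for (ch in unique(d$chrom)) {
      dd <- d[d$chrom == ch, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        dataset = nm, chrom = ch,
        pct_low_or_silent = 100 * mean(dd$class == "low_or_silent"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Mean within-domain dispersion of values v grouped by g (>=2-gene domains).
# statistic: "variance" or "mad_median" (mean absolute deviation from the
# domain median).
dispersion_stat <- function(v, g, statistic) {
  ord <- order(g)
  v <- v[ord]; g <- g[ord]
  n_per <- as.integer(table(g)[unique(g)])
  keep <- rep(n_per >= 2L, n_per)
  v <- v[keep]; g <- g[keep]
  if (!length(v)) return(NA_real_)
  if (statistic == "variance") {
    s1 <- rowsum(v, g)
    s2 <- rowsum(v * v, g)
    nn <- as.integer(table(g)[rownames(s1)])
    mean((s2 - s1 * s1 / nn) / (nn - 1L))
  } else {
    med <- tapply(v, g, stats::median)
    mean(tapply(abs(v - med[as.character(g)]), g, mean))
  }
}

#' Circular-shift test of within-domain expression coordination
#'
#' Tests whether genes sharing a forum domain have more similar expression
#' than expected from their chromosomal arrangement.  The statistic D is the
#' mean, over domains with at least two genes, of the within-domain
#' dispersion of gene expression values (variance by default).  The null
#' preserves the gene order and the domain membership pattern along each
#' chromosome but rotates the vector of gene expression values by a random
#' offset in gene-rank space (circular shift), independently per chromosome
#' and replicate; this keeps any autocorrelation of expression along the
#' chromosome while breaking its alignment with domain boundaries.  Offsets
#' are drawn uniformly from the n - 1 nonzero rotations of each chromosome
#' (the identity rotation is not a null draw; the +1 pseudocount accounts
#' for the observed arrangement).
#' Coordination shows up as a small observed D, so the test is one-sided:
#' `p = (1 + #(D_null <= D_obs)) / (1 + reps)`.
#'
#' With `exact = TRUE` (single-chromosome data only) all n rotations are
#' enumerated instead, and `p = #(D_rot <= D_obs) / n` with the identity
#' rotation included.
#'
#' @param expr expression table (gene_id, chrom, start, end, value).
#' @param domains a `forum_domains` data.frame (genes are midpoint-assigned
#'   to domains internally).
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @param statistic `"variance"` (default) or `"mad_median"`.
#' @param exact enumerate all rotations (single chromosome only).
#' @return object of class `coexpression_test`: statistic_observed,
#'   null_stats, p_value, reps, seed, statistic, n_genes,
#'   n_multigene_domains.
#' @export
circular_shift_test <- function(expr, domains, reps = 10000L, seed = 1L,
                                statistic = c("variance", "mad_median"),
                                exact = FALSE) {
  statistic <- match.arg(statistic)
  if (reps < 1) stop("'reps' must be >= 1")
  expr <- assign_genes_to_domains(expr, domains)
  expr <- expr[!is.na(expr$domain_id), , drop = FALSE]
  expr <- expr[order(expr$chrom, expr$start), , drop = FALSE]

  chroms <- unique(expr$chrom)
  vals <- split(expr$value, factor(expr$chrom, levels = chroms))
  doms <- split(expr$domain_id, factor(expr$chrom, levels = chroms))

  tab <- table(expr$domain_id)
  n_multi <- sum(tab >= 2L)
  if (n_multi == 0L)
    stop("circular-shift test undefined: no domain holds two or more genes")

  stat_all <- function(vlist) {
    v <- unlist(vlist, use.names = FALSE)
    g <- unlist(doms, use.names = FALSE)
    dispersion_stat(v, g, statistic)
  }
  d_obs <- stat_all(vals)

  rotate <- function(v, k) if (k == 0L) v else c(v[-seq_len(k)],
                                                 v[seq_len(k)])
  if (exact) {
    if (length(chroms) != 1L)
      stop("'exact = TRUE' supports a single chromosome only")
    v <- vals[[1L]]
    n <- length(v)
    null_stats <- vapply(0:(n - 1L), function(k)
      stat_all(list(rotate(v, k))), 0)
    p <- sum(null_stats <= d_obs) / n
    reps <- n
  } else {
    ns <- lengths(vals)
    null_stats <- with_seed(seed, vapply(seq_len(reps), function(i) {
      shifted <- lapply(seq_along(vals), function(ci)
        if (ns[ci] < 2L) vals[[ci]]
        else rotate(vals[[ci]], sample.int(ns[ci] - 1L, 1L)))
      stat_all(shifted)
    }, 0))
    p <- (1 + sum(null_stats <= d_obs)) / (1 + reps)
  }
  structure(list(statistic_observed = d_obs, null_stats = null_stats,
                 p_value = p, reps = as.integer(reps), seed = seed,
                 statistic = statistic, n_genes = nrow(expr),
                 n_multigene_domains = n_multi),
            class = "coexpression_test")
}

#' @export
print.coexpression_test <- function(x, ...) {
  cat("Circular-shift test of within-domain expression coordination\n")
  cat(sprintf("  genes: %d in %d multi-gene domains; statistic: %s\n",
              x$n_genes, x$n_multigene_domains, x$statistic))
  cat(sprintf("  observed D = %.4g; null mean = %.4g (%d shifts)\n",
              x$statistic_observed, mean(x$null_stats), x$reps))
  cat(sprintf("  one-sided p-value = %.3g\n", x$p_value))
  invisible(x)
}
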