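#' Simulation configuration for synthetic DSB-mapping data
#'
#' Builds a validated configuration for the synthetic-data generator.  The
#' generator emulates the terminus-capture construct: recurrent blunt
#' double-strand breaks (DSB hot spots) spaced tens to hundreds of kb apart
#' delimit protected domains; each break releases up to two fragments, each
#' running from the cut to the nearest Sau3A (GATC) site on that side; gene
#' expression is coordinated at the domain level, with roughly 30% of domains
#' active and the rest silent or low.
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length (bp).
#' @param hotspot_spacing_median median inter-hot-spot gap in bp.  Gaps are
#'   drawn log-normal, which reproduces both the stated median (about 110 kb
#'   genome-wide) and the long right tail of observed domain sizes.
#' @param hotspot_spacing_logsd log-scale SD of the gap distribution
#'   (dimensionless).
#' @param reads_per_hotspot_mean mean number of breaks sampled per hot spot.
#' @param background_break_rate rate of isolated background breaks, breaks/bp.
#' @param cut_jitter_sd SD (bp) of cut positions around a hot-spot centre.
#' @param sau3a_spacing_mean mean spacing of Sau3A sites in bp; 256 = 4^4 is
#'   the expectation for the 4-base GATC motif in random sequence.
#' @param read_min_len,read_max_len typical fragment length bounds in bp
#'   (captured fragments mostly run 50-300 bp); fragments longer than
#'   `read_max_len` are truncated from the cut end.
#' @param frac_active_domains fraction of domains carrying an active
#'   (elevated) expression baseline; about 0.30 in the data this emulates.
#' @param domain_effect_sd SD (log2 units) of the active-domain expression
#'   effect.
#' @param gene_noise_sd per-gene noise SD in log2 units.
#' @param genes_per_domain_mean mean gene count per domain (Poisson).
#' @param seed master seed; all generator stages derive their streams from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chrom_lengths = c(chrS1 = 2e6),
                       hotspot_spacing_median = 110000,
                       hotspot_spacing_logsd = 1.1,
                       reads_per_hotspot_mean = 10,
                       background_break_rate = 5e-7,
                       cut_jitter_sd = 15,
                       sau3a_spacing_mean = 256,
                       read_min_len = 50,
                       read_max_len = 300,
                       frac_active_domains = 0.30,
                       domain_effect_sd = 2,
                       gene_noise_sd = 0.5,
                       genes_per_domain_mean = 3,
                       seed = 1L) {
  cfg <- list(
    chrom_lengths = check_chrom_sizes(chrom_lengths),
    hotspot_spacing_median = hotspot_spacing_median,
    hotspot_spacing_logsd = hotspot_spacing_logsd,
    reads_per_hotspot_mean = reads_per_hotspot_mean,
    background_break_rate = background_break_rate,
    cut_jitter_sd = cut_jitter_sd,
    sau3a_spacing_mean = sau3a_spacing_mean,
    read_min_len = read_min_len,
    read_max_len = read_max_len,
    frac_active_domains = frac_active_domains,
    domain_effect_sd = domain_effect_sd,
    gene_noise_sd = gene_noise_sd,
    genes_per_domain_mean = genes_per_domain_mean,
    seed = as.integer(seed)
  )
  pos <- c("hotspot_spacing_median", "hotspot_spacing_logsd",
           "reads_per_hotspot_mean", "cut_jitter_sd", "sau3a_spacing_mean",
           "read_min_len", "read_max_len", "genes_per_domain_mean")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("'%s' must be a single positive number", f))
  for (f in c("background_break_rate", "domain_effect_sd", "gene_noise_sd"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("'%s' must be non-negative", f))
  if (cfg$frac_active_domains < 0 || cfg$frac_active_domains > 1)
    stop("'frac_active_domains' must lie in [0, 1]")
  if (cfg$read_min_len >= cfg$read_max_len)
    stop("'read_min_len' must be smaller than 'read_max_len'")
  structure(cfg, class = "sim_config")
}

#' Adaptor sequences used by the read simulator
#'
#' The DSB-end adaptor is ligated to the blunt cut; the Sau3A adaptor carries
#' the GATC overhang at the restriction end.  Synthetic sequences, used only
#' to decorate simulated reads and exercise the trimming stage.
#'
#' @return named list with elements `dsb` and `sau3a`.
#' @export
raft_adaptors <- function() {
  list(dsb = "GTAATACGACTCACTATAGGGC",
       sau3a = "GATCGTCGGACTGTAGAACTCT")
}

# Draw point positions on [1, len) with geometric gaps of the given mean.
draw_point_process <- function(len, mean_gap) {
  n_guess <- max(16L, ceiling(len / mean_gap * 1.5))
  pos <- numeric(0)
  at <- 0
  repeat {
    gaps <- stats::rgeom(n_guess, prob = 1 / mean_gap) + 1
    pos <- c(pos, at + cumsum(gaps))
    at <- pos[length(pos)]
    if (at >= len) break
  }
  pos[pos < len]
}

#' Simulate a genome with planted DSB hot spots
#'
#' Places Sau3A (GATC) sites as a point process with geometric spacing, plants
#' DSB hot spots with log-normal inter-hot-spot gaps, tiles the gaps between
#' consecutive hot spots with ground-truth domains (each classed active or
#' silent), and drops genes into the domains.  Everything is deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param sequence if `TRUE`, also generate random chromosome sequence and
#'   derive Sau3A sites from actual GATC occurrences (slower; useful when
#'   read sequences must be genome-consistent).
#' @return list with elements `genome` (class `raft_genome`: chromosome
#'   lengths, per-chromosome Sau3A site positions, optional sequences) and
#'   `truth` (class `sim_truth`: `hotspots`, `domains`, `genes` data frames).
#' @export
simulate_genome <- function(config, sequence = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- names(config$chrom_lengths)
    sau3a <- vector("list", length(chroms))
    names(sau3a) <- chroms
    seqs <- if (sequence) character(length(chroms)) else NULL

    hs <- list(); dom <- list(); gen <- list()
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      len <- config$chrom_lengths[[ci]]

      if (sequence) {
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        seqs[ci] <- s
        # 0-based cut point = position just after the G|GATC stagger start;
        # we use the motif start as the site coordinate.
        m <- gregexpr("GATC", s, fixed = TRUE)[[1L]]
        sau3a[[ci]] <- if (m[1L] == -1L) numeric(0) else as.numeric(m) - 1
      } else {
        sau3a[[ci]] <- draw_point_process(len, config$sau3a_spacing_mean)
      }

      if (len < 2 * config$hotspot_spacing_median) {
        warning(sprintf(
          "chromosome '%s' (%d bp) is shorter than twice the hot-spot spacing median; no hot spots planted",
          chrom, as.integer(len)))
        next
      }
      meanlog <- log(config$hotspot_spacing_median)
      pos <- numeric(0)
      at <- 0
      repeat {
        at <- at + stats::rlnorm(1, meanlog, config$hotspot_spacing_logsd)
        if (at >= len) break
        pos <- c(pos, floor(at))
      }
      if (length(pos) == 0L) next
      hs[[chrom]] <- data.frame(
        chrom = chrom, position = pos,
        intensity = config$reads_per_hotspot_mean,
        stringsAsFactors = FALSE)

      if (length(pos) >= 2L) {
        ds <- pos[-length(pos)]
        de <- pos[-1L]
        active <- stats::runif(length(ds)) < config$frac_active_domains
        effect <- ifelse(active,
                         abs(stats::rnorm(length(ds), 0,
                                          config$domain_effect_sd)),
                         0)
        d <- data.frame(
          chrom = chrom, start = ds, end = de,
          activity = ifelse(active, "active", "silent"),
          baseline = effect, stringsAsFactors = FALSE)
        dom[[chrom]] <- d

        # genes: k ~ Pois(mean) per domain, laid out in disjoint equal slots
        glist <- vector("list", nrow(d))
        for (di in seq_len(nrow(d))) {
          k <- stats::rpois(1, config$genes_per_domain_mean)
          if (k == 0L) next
          width <- d$end[di] - d$start[di]
          slot <- width / k
          gs <- floor(d$start[di] + (seq_len(k) - 1) * slot + 0.25 * slot)
          ge <- floor(gs + 0.5 * slot)
          ge <- pmax(ge, gs + 1)
          glist[[di]] <- data.frame(
            chrom = chrom, start = gs, end = ge,
            true_log_expression = d$baseline[di],
            stringsAsFactors = FALSE)
        }
        glist <- glist[!vapply(glist, is.null, TRUE)]
        if (length(glist)) gen[[chrom]] <- do.call(rbind, glist)
      }
    }

    hotspots <- if (length(hs)) do.call(rbind, hs) else
      data.frame(chrom = character(0), position = numeric(0),
                 intensity = numeric(0))
    domains <- if (length(dom)) do.call(rbind, dom) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 activity = character(0), baseline = numeric(0))
    genes <- if (length(gen)) do.call(rbind, gen) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 true_log_expression = numeric(0))
    rownames(hotspots) <- rownames(domains) <- rownames(genes) <- NULL
    if (nrow(domains)) domains$domain_id <- sprintf("d%04d",
                                                    seq_len(nrow(domains)))
    if (nrow(genes)) genes <- cbind(
      gene_id = sprintf("g%05d", seq_len(nrow(genes))), genes,
      stringsAsFactors = FALSE)

    genome <- structure(
      list(chrom_lengths = config$chrom_lengths, sau3a = sau3a,
           sequences = seqs),
      class = "raft_genome")
    truth <- structure(
      list(hotspots = hotspots, domains = domains, genes = genes),
      class = "sim_truth")
    list(genome = genome, truth = truth)
  })
}

# Fragment from a cut to the nearest Sau3A site on one side, truncated to
# max_len from the cut.  Returns c(start, end, truncated) in 0-based
# half-open coordinates, or NULL when empty.
fragment_one_side <- function(cut, side, sites, chrom_len, max_len) {
  if (side == "left") {
    s <- sites[sites < cut]
    near <- if (length(s)) max(s) else 0
    start <- max(near, cut - max_len, 0)
    trunc <- near < cut - max_len
    if (start >= cut) return(NULL)
    c(start, cut, as.numeric(trunc))
  } else {
    s <- sites[sites > cut]
    near <- if (length(s)) min(s) else chrom_len
    end <- min(near, cut + max_len, chrom_len)
    trunc <- near > cut + max_len
    if (end <= cut) return(NULL)
    c(cut, end, as.numeric(trunc))
  }
}

#' Simulate terminus-capture reads from planted breaks
#'
#' Each hot spot receives a Poisson number of breaks whose cut positions are
#' jittered around the hot-spot centre; isolated background breaks are added
#' at `background_break_rate`.  Each break emits up to two fragments, one per
#' side, each captured independently with probability 0.5; a fragment runs
#' from the cut position to the nearest Sau3A site on its side, truncated to
#' `read_max_len` measured from the cut (sequencing starts at the ligated cut
#' end).  Fragments shorter than 18 bp are still emitted: length filtering is
#' the pipeline's job, not the simulator's.
#'
#' Read sequences are oriented cut-end first and decorated with the DSB-end
#' adaptor at the cut end and the Sau3A adaptor at the other end (omitted when
#' the fragment was truncated before reaching a site).  Truth alignments are
#' 0-based half-open; strand `+` means the cut is at the left (5'-most)
#' coordinate, `-` at the right.
#'
#' @param genome,truth output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list with `reads` (data.frame: read_id, sequence) and `alignments`
#'   (BED-like data.frame: chrom, start, end, name, score = truncation flag,
#'   strand encoding the cut side).
#' @export
simulate_raft_reads <- function(genome, truth, config) {
  stopifnot(inherits(genome, "raft_genome"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  ad <- raft_adaptors()
  with_seed(derive_seed(config$seed, "reads"), {
    out <- list()
    for (chrom in names(genome$chrom_lengths)) {
      len <- genome$chrom_lengths[[chrom]]
      sites <- genome$sau3a[[chrom]]
      hs <- truth$hotspots[truth$hotspots$chrom == chrom, , drop = FALSE]

      cuts <- numeric(0)
      if (nrow(hs)) {
        for (hi in seq_len(nrow(hs))) {
          nb <- stats::rpois(1, hs$intensity[hi])
          if (nb == 0L) next
          cc <- round(stats::rnorm(nb, hs$position[hi], config$cut_jitter_sd))
          # cut positions falling outside the chromosome are resampled
          bad <- cc < 1 | cc >= len
          while (any(bad)) {
            cc[bad] <- round(stats::rnorm(sum(bad), hs$position[hi],
                                          config$cut_jitter_sd))
            bad <- cc < 1 | cc >= len
          }
          cuts <- c(cuts, cc)
        }
      }
      nbg <- stats::rpois(1, config$background_break_rate * len)
      if (nbg > 0L) cuts <- c(cuts, floor(stats::runif(nbg, 1, len)))
      if (!length(cuts)) next

      frags <- list()
      for (bi in seq_along(cuts)) {
        for (side in c("left", "right")) {
          if (stats::runif(1) >= 0.5) next  # per-side capture dropout
          fr <- fragment_one_side(cuts[bi], side, sites, len,
                                  config$read_max_len)
          if (is.null(fr)) next
          frags[[length(frags) + 1L]] <- data.frame(
            chrom = chrom, start = fr[1L], end = fr[2L],
            name = sprintf("%s_b%05d_%s", chrom, bi,
                           if (side == "left") "L" else "R"),
            score = fr[3L],
            strand = if (side == "right") "+" else "-",
            stringsAsFactors = FALSE)
        }
      }
      if (length(frags)) out[[chrom]] <- do.call(rbind, frags)
    }
    if (!length(out)) {
      aln <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), name = character(0),
                        score = numeric(0), strand = character(0))
      return(list(reads = data.frame(read_id = character(0),
                                     sequence = character(0)),
                  alignments = aln))
    }
    aln <- do.call(rbind, out)
    rownames(aln) <- NULL

    seqs <- character(nrow(aln))
    for (i in seq_len(nrow(aln))) {
      w <- aln$end[i] - aln$start[i]
      if (!is.null(genome$sequences)) {
        frag <- substr(genome$sequences[[match(aln$chrom[i],
                                               names(genome$chrom_lengths))]],
                       aln$start[i] + 1, aln$end[i])
      } else {
        frag <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                      collapse = "")
      }
      # orient cut-first: '-' alignments carry the cut at the right end
      if (aln$strand[i] == "-")
        frag <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(frag)))
      seqs[i] <- if (aln$score[i] > 0)
        paste0(ad$dsb, frag)            # truncated: never reached a site
      else
        paste0(ad$dsb, frag, ad$sau3a)
    }
    list(reads = data.frame(read_id = aln$name, sequence = seqs,
                            stringsAsFactors = FALSE),
         alignments = aln)
  })
}

#' Simulate a domain-coordinated gene expression table
#'
#' Per-gene log2 expression = the domain baseline recorded in the truth
#' (active domains carry a positive effect; silent domains sit at the floor
#' of 0 on the log2(signal+1) scale) plus independent gene noise with SD
#' `gene_noise_sd`.  Deterministic given `config$seed`.
#'
#' @param truth a `sim_truth` from [simulate_genome()].
#' @param config the same [sim_config()].
#' @return data.frame: gene_id, chrom, start, end, value (log2 scale).
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  g <- truth$genes
  if (!nrow(g)) {
    warning("truth contains no genes; returning an empty expression table")
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      value = numeric(0)))
  }
  with_seed(derive_seed(config$seed, "expression"), {
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = g$start, end = g$end,
               value = g$true_log_expression +
                 stats::rnorm(nrow(g), 0, config$gene_noise_sd),
               stringsAsFactors = FALSE)
  })
}

#' Write simulated reads as FASTA
#' @param reads data.frame with `read_id` and `sequence`.
#' @param path output FASTA path.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write truth alignments as BED6
#' @param alignments data.frame from [simulate_raft_reads()].
#' @param path output BED path.
#' @export
write_truth_bed <- function(alignments, path) {
  utils::write.table(
    alignments[, c("chrom", "start", "end", "name", "score", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize simulation ground truth to JSON
#' @param truth a `sim_truth`.
#' @param path output JSON path.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
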