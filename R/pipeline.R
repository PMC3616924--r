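#' Build a pipeline configuration
#'
#' Collects stage parameters, the master seed and the output directory into
#' a validated configuration.  Unknown parameter names are rejected.  Every
#' run writes an effective-config snapshot next to its artifacts.
#'
#' @param outdir output directory for artifacts.
#' @param sim a [sim_config()] driving the simulate stage.
#' @param min_gap,min_support FT-calling parameters.
#' @param hotspots_only segmentation boundary choice.
#' @param window,step density-track parameters, bp.
#' @param region optional `c(start, end)` on `enrich_chrom` for the
#'   enrichment stage; `NULL` skips that stage.
#' @param enrich_chrom chromosome name for the enrichment stage.
#' @param reps Monte-Carlo replicates for enrichment/coexpression stages.
#' @param seed master seed; each stage derives its own stream from it.
#' @param ... rejected (guards against typos).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("forumdomains_run"),
                            sim = sim_config(),
                            min_gap = 0L, min_support = 2L,
                            hotspots_only = TRUE,
                            window = 500000, step = 100000,
                            region = NULL, enrich_chrom = NULL,
                            reps = 10000L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline_config field(s): ",
         paste(names(extra), collapse = ", "))
  structure(list(outdir = outdir, sim = sim, min_gap = min_gap,
                 min_support = min_support, hotspots_only = hotspots_only,
                 window = window, step = step, region = region,
                 enrich_chrom = enrich_chrom, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the forum-domain pipeline
#'
#' Executes the requested stages in dependency order:
#' simulate -> trim -> callft -> domains -> density -> saturate ->
#' enrich -> express -> coexpress.  Later stages consume the in-memory
#' products of earlier ones; artifacts (FASTA, BED, GFF, WIG, TSV, JSON)
#' are written under `config$outdir`, each TSV stamped with a header
#' carrying the package version, stage seed and parameters.  Stage counts
#' are logged via `message()`.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of the stage names above (default: all).
#' @return invisibly, a named list of in-memory stage products.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "trim", "callft", "domains",
                                    "density", "saturate", "enrich",
                                    "express", "coexpress")) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "trim", "callft", "domains", "density",
                 "saturate", "enrich", "express", "coexpress")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  snap <- config
  snap$sim <- unclass(snap$sim)
  jsonlite::write_json(unclass(snap),
                       file.path(config$outdir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  state <- list()
  need <- function(what, from) {
    if (is.null(state[[what]]))
      stop(sprintf("stage '%s' requires '%s' from an earlier stage",
                   from, what))
    state[[what]]
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        g <- simulate_genome(config$sim)
        rr <- simulate_raft_reads(g$genome, g$truth, config$sim)
        state$genome <- g$genome; state$truth <- g$truth
        state$reads <- rr$reads; state$alignments <- rr$alignments
        state$expression <- suppressWarnings(
          simulate_expression(g$truth, config$sim))
        write_reads_fasta(rr$reads, file.path(config$outdir, "reads.fasta"))
        write_truth_bed(rr$alignments,
                        file.path(config$outdir, "truth.bed"))
        write_sim_truth(g$truth, file.path(config$outdir, "truth.json"))
        write_tsv_with_header(state$expression,
                              file.path(config$outdir, "expression.tsv"),
                              artifact_header("simulate", config$sim$seed))
        message(sprintf("simulate: %d reads, %d hot spots, %d genes",
                        nrow(rr$reads), nrow(g$truth$hotspots),
                        nrow(g$truth$genes)))
      },
      trim = {
        reads <- need("reads", "trim")
        ad <- raft_adaptors()
        trimmed <- trim_primers(reads, trim_spec(unlist(ad)))
        flt <- filter_short(trimmed, 18L)
        state$trimmed <- flt$kept
        write_tsv_with_header(
          trimmed, file.path(config$outdir, "trim_report.tsv"),
          artifact_header("trim", params = list(min_len = 18)))
        message(sprintf("trim: %d reads in, %d kept, %d dropped (<18 bp)",
                        nrow(trimmed), nrow(flt$kept), flt$dropped))
      },
      callft = {
        aln <- need("alignments", "callft")
        mapped <- data.frame(chrom = aln$chrom, start = aln$start,
                             end = aln$end, strand = aln$strand,
                             cut_side = ifelse(aln$strand == "+", "left",
                                               "right"),
                             read_id = aln$name, stringsAsFactors = FALSE)
        ft <- call_ft(mapped, min_gap = config$min_gap)
        ft <- classify_hotspots(ft, config$min_support, quiet = TRUE)
        state$mapped <- mapped; state$ft <- ft
        write_ft_bed(ft, file.path(config$outdir, "ft.bed"))
        write_ft_gff(ft, file.path(config$outdir, "ft.gff"))
        message(sprintf("callft: %d FT (%d hot spots) from %d reads",
                        nrow(ft), sum(ft$hotspot), nrow(mapped)))
      },
      domains = {
        ft <- need("ft", "domains")
        chrom_sizes <- if (!is.null(state$genome))
          state$genome$chrom_lengths else config$sim$chrom_lengths
        dom <- segment_domains(ft, chrom_sizes, config$hotspots_only)
        state$domains <- dom
        write_domains_bed(dom, file.path(config$outdir, "domains.bed"))
        message(sprintf("domains: %d segments (%d bounded)",
                        nrow(dom), sum(dom$bounded)))
      },
      density = {
        ft <- need("ft", "density")
        chrom_sizes <- if (!is.null(state$genome))
          state$genome$chrom_lengths else config$sim$chrom_lengths
        trk <- ft_density(ft, chrom_sizes, config$window, config$step)
        state$density <- trk
        export_wig(trk, file.path(config$outdir, "ft_density.wig"))
        message(sprintf("density: %d windows", nrow(trk)))
      },
      saturate = {
        mapped <- need("mapped", "saturate")
        sat <- saturation_curve(mapped,
                                seed = derive_seed(config$seed, "saturate"))
        state$saturation <- sat
        write_tsv_with_header(
          as.data.frame(sat),
          file.path(config$outdir, "saturation.tsv"),
          artifact_header("saturate", attr(sat, "seed")))
        message(sprintf("saturate: %d schedule points", nrow(sat)))
      },
      enrich = {
        if (is.null(config$region) || is.null(config$enrich_chrom)) {
          message("enrich: no region configured, skipped")
          next
        }
        ft <- need("ft", "enrich")
        chrom_sizes <- if (!is.null(state$genome))
          state$genome$chrom_lengths else config$sim$chrom_lengths
        enr <- mc_enrichment(
          ft[ft$chrom == config$enrich_chrom, , drop = FALSE],
          config$region, chrom_sizes[[config$enrich_chrom]],
          reps = config$reps, seed = derive_seed(config$seed, "enrich"))
        state$enrichment <- enr
        jsonlite::write_json(unclass(enr),
                             file.path(config$outdir, "enrichment.json"),
                             auto_unbox = TRUE, digits = NA)
        message(sprintf("enrich: observed %d FT, p_mc=%.3g",
                        enr$observed, enr$p_mc))
      },
      express = {
        dom <- need("domains", "express")
        expr <- need("expression", "express")
        de <- domain_expression(dom, expr)
        state$domain_expression <- de
        write_tsv_with_header(
          de$domains, file.path(config$outdir, "domain_expression.tsv"),
          artifact_header("express"))
        write_tsv_with_header(
          de$chrom_summary,
          file.path(config$outdir, "chrom_expression_summary.tsv"),
          artifact_header("express"))
        message(sprintf("express: %d domains summarised", nrow(de$domains)))
      },
      coexpress = {
        dom <- need("domains", "coexpress")
        expr <- need("expression", "coexpress")
        ct <- circular_shift_test(expr, dom, reps = config$reps,
                                  seed = derive_seed(config$seed,
                                                     "coexpress"))
        state$coexpression <- ct
        jsonlite::write_json(
          list(statistic_observed = ct$statistic_observed,
               p_value = ct$p_value, reps = ct$reps, seed = ct$seed,
               statistic = ct$statistic, n_genes = ct$n_genes,
               n_multigene_domains = ct$n_multigene_domains),
          file.path(config$outdir, "coexpression.json"),
          auto_unbox = TRUE, digits = NA)
        message(sprintf("coexpress: D=%.4g, p=%.3g",
                        ct$statistic_observed, ct$p_value))
      })
  }
  invisible(state)
}

#' Read / write a flat key=value pipeline config file
#'
#' The on-disk format is one `key=value` pair per line (`#` comments
#' allowed); nested simulation fields use a `sim.` prefix, e.g.
#' `sim.hotspot_spacing_median=110000`.  Chromosome lengths are encoded as
#' `sim.chrom_lengths=name:bp,name:bp`.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  valsv <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  simargs <- list(); topargs <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- valsv[i]
    if (startsWith(k, "sim.")) {
      f <- sub("^sim\\.", "", k)
      if (f == "chrom_lengths") {
        pairs <- strsplit(strsplit(v, ",")[[1L]], ":")
        simargs[[f]] <- stats::setNames(
          as.numeric(vapply(pairs, `[[`, "", 2L)),
          vapply(pairs, `[[`, "", 1L))
      } else simargs[[f]] <- as.numeric(v)
    } else if (k == "region") {
      topargs[[k]] <- as.numeric(strsplit(v, ",")[[1L]])
    } else if (k %in% c("outdir", "enrich_chrom")) {
      topargs[[k]] <- v
    } else if (k == "hotspots_only") {
      topargs[[k]] <- toupper(v) %in% c("TRUE", "1", "YES")
    } else {
      topargs[[k]] <- as.numeric(v)
    }
  }
  topargs$sim <- do.call(sim_config, simargs)
  do.call(pipeline_config, topargs)
}
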