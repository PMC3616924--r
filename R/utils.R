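# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Per-stage seeds are derived from the master seed by a stable string hash of
#' the stage name, so adding or reordering stages never perturbs the random
#' stream of another stage.  The result is always a positive integer below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"callft"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  p <- 2147483647  # 2^31 - 1, Mersenne prime; all products stay < 2^53
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% p
  h <- (h * 16807 + (abs(master) %% p)) %% p
  as.integer(h %% (p - 1L) + 1L)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Validate a named chromosome-size vector.
check_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(ncol(chrom_sizes) >= 2L)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2L]]),
                                   as.character(chrom_sizes[[1L]]))
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector (name -> length in bp)")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes < 1))
    stop("chromosome lengths must be positive")
  chrom_sizes
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length in bp.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  check_chrom_sizes(df)
}

# Comment header stamped on top of pipeline artifacts (version, seed, params).
artifact_header <- function(stage, seed = NULL, params = list()) {
  kv <- if (length(params))
    paste(names(params), vapply(params, function(x) paste(x, collapse = ","),
                                ""), sep = "=", collapse = "; ")
  else ""
  paste0("# forumdomains ",
         as.character(utils::packageVersion("forumdomains")),
         " | stage=", stage,
         if (!is.null(seed)) paste0(" | seed=", seed) else "",
         if (nzchar(kv)) paste0(" | ", kv) else "")
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
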