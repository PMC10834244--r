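logit <- function(p) log(p) - log1p(-p)
expit <- function(x) 1 / (1 + exp(-x))

#' Derive a per-stage seed from a global seed
#'
#' Stages of the pipeline draw from independent streams so that each stage is
#' reproducible on its own. The per-stage seed is the global seed plus a fixed
#' stage offset, kept within the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (one of the pipeline stage labels).
#' @return An integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, expression = 211L, allele = 307L,
               isoform = 401L, factors = 503L, viral = 601L,
               eqtl = 701L, finemap = 809L, analysis = 907L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}

#' Write a TSV result table with a provenance header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed used to produce the table (recorded in the header).
#' @param params Named list of stage parameters recorded in the header.
#' @return Invisibly, `path`.
#' @keywords internal
write_result_tsv <- function(df, path, seed = NULL, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("csfqtl"))
  writeLines(sprintf("# csfqtl %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (length(params))
    writeLines(sprintf("# params: %s",
                       paste(names(params), unlist(params), sep = "=",
                             collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
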