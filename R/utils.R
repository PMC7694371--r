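#' @keywords internal
"_PACKAGE"

# Numeric columns are rendered with 6 significant digits so repeated runs of
# the same seeded pipeline produce byte-identical TSVs.
format_num <- function(x) {
  out <- formatC(signif(x, 6L), digits = 6L, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a data frame as a byte-stable TSV
#'
#' Numeric columns are rendered with 6 significant digits; no quoting, no
#' row names, Unix line endings. Used for every pipeline artifact so that
#' identical configuration + seed yields byte-identical output files.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_stable <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- format_num(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Deterministic fan-out of the single top-level seed into per-stage seeds.
# Offsets are fixed constants; results stay below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(lfc = 101L, expression = 211L, sets = 307L, reference = 401L,
               enrich_transcript = 503L, enrich_protein = 601L)
  off <- offsets[[stage]]
  (as.integer(seed) + off) %% .Machine$integer.max
}

stop_stage <- function(stage, msg) {
  stop(sprintf("%s stage: %s", stage, msg), call. = FALSE)
}
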