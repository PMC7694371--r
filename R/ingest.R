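#' Read a differential-expression table
#'
#' Reads a tab-separated table of per-feature log2 fold changes. Column
#' names are configurable so platform exports (probe tables, protein-group
#' tables) can be consumed without renaming. Rows whose fold-change field
#' is missing or non-numeric are dropped and counted; duplicated feature
#' identifiers are retained (collapsing is a later, explicit step, see
#' [collapse_duplicates()]).
#'
#' @param path path to a TSV file with a header row.
#' @param columns named list giving the header names to use for
#'   `feature_id`, `lfc` and (optionally present) `adj_p`.
#' @return data frame with columns `feature_id`, `lfc` and, when present in
#'   the input, `adj_p`; attribute `n_dropped` counts rows removed for a
#'   missing/non-numeric fold change.
#' @export
read_lfc_table <- function(path,
                           columns = list(feature_id = "feature_id",
                                          lfc = "lfc",
                                          adj_p = "adj_p")) {
  if (!file.exists(path)) {
    stop("LFC table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("feature_id", "lfc")) {
    if (!columns[[col]] %in% names(raw)) {
      stop("configured column '", columns[[col]], "' (", col,
           ") absent from header of ", path, call. = FALSE)
    }
  }
  out <- data.frame(feature_id = raw[[columns$feature_id]],
                    lfc = suppressWarnings(as.numeric(raw[[columns$lfc]])),
                    stringsAsFactors = FALSE)
  if (!is.null(columns$adj_p) && columns$adj_p %in% names(raw)) {
    out$adj_p <- suppressWarnings(as.numeric(raw[[columns$adj_p]]))
  }
  keep <- is.finite(out$lfc) & nzchar(out$feature_id)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Read a feature-to-gene identifier mapping table
#'
#' Two-column TSV `feature_id<TAB>gene_id`. Many-to-many mappings are
#' permitted; exact duplicate pairs are removed; pairs with an empty gene
#' identifier are rejected.
#'
#' @param path path to the mapping TSV (header optional: a header line named
#'   `feature_id`/`gene_id` is detected and skipped).
#' @return data frame with columns `feature_id`, `gene_id`.
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop("mapping table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("mapping table needs two columns", call. = FALSE)
  map <- data.frame(feature_id = raw[[1L]], gene_id = raw[[2L]],
                    stringsAsFactors = FALSE)
  if (nrow(map) > 0L && map$feature_id[1L] == "feature_id") {
    map <- map[-1L, , drop = FALSE]
  }
  if (any(!nzchar(map$gene_id))) {
    stop("mapping table contains empty gene_id entries", call. = FALSE)
  }
  map <- unique(map)
  rownames(map) <- NULL
  map
}

#' Harmonise feature identifiers to gene identifiers
#'
#' Annotates each record with a gene identifier via a primary mapping,
#' falling back to a secondary mapping for features the primary one does
#' not cover (mirroring a direct-database-then-nomenclature-registry
#' conversion route). A feature mapping to k genes yields k records;
#' features absent from both mappings are dropped and counted, never
#' silently discarded.
#'
#' @param records data frame from [read_lfc_table()].
#' @param mapping primary mapping data frame (`feature_id`, `gene_id`).
#' @param fallback optional secondary mapping used for features the primary
#'   mapping misses.
#' @return data frame with columns `feature_id`, `gene_id`, `lfc` (plus
#'   `adj_p` if present); attribute `n_unmapped` counts dropped features.
#' @export
map_to_gene_ids <- function(records, mapping, fallback = NULL) {
  if (is.null(mapping) || nrow(mapping) == 0L) {
    stop("primary mapping is empty", call. = FALSE)
  }
  hit_primary <- records$feature_id %in% mapping$feature_id
  mapped <- merge(records[hit_primary, , drop = FALSE], mapping,
                  by = "feature_id", sort = FALSE)
  rest <- records[!hit_primary, , drop = FALSE]
  n_unmapped <- 0L
  if (nrow(rest) > 0L && !is.null(fallback) && nrow(fallback) > 0L) {
    hit_fb <- rest$feature_id %in% fallback$feature_id
    fb_mapped <- merge(rest[hit_fb, , drop = FALSE], fallback,
                       by = "feature_id", sort = FALSE)
    n_unmapped <- sum(!hit_fb)
    mapped <- rbind(mapped, fb_mapped)
  } else {
    n_unmapped <- nrow(rest)
  }
  cols <- c("feature_id", "gene_id", "lfc",
            intersect("adj_p", names(mapped)))
  mapped <- mapped[, cols, drop = FALSE]
  mapped <- mapped[order(mapped$gene_id, mapped$feature_id), , drop = FALSE]
  rownames(mapped) <- NULL
  attr(mapped, "n_unmapped") <- n_unmapped
  mapped
}

#' Collapse multiple features per gene to a single record
#'
#' Several probes or protein groups can map to one gene; a rank statistic
#' needs exactly one fold change per gene. Under `max_abs` the record with
#' the largest absolute fold change is retained (ties broken towards the
#' larger signed value); under `mean` the arithmetic mean is taken. The
#' operation is idempotent.
#'
#' @param records data frame with columns `gene_id`, `lfc`.
#' @param rule `"max_abs"` (default) or `"mean"`.
#' @return data frame with one row per `gene_id`, columns `gene_id`, `lfc`,
#'   sorted by `gene_id`.
#' @export
collapse_duplicates <- function(records, rule = c("max_abs", "mean")) {
  rule <- match.arg(rule)
  if (is.null(records$gene_id) || any(is.na(records$gene_id))) {
    stop("all records must carry a gene_id before collapsing", call. = FALSE)
  }
  if (rule == "max_abs") {
    ord <- order(records$gene_id, -abs(records$lfc), -records$lfc)
    sorted <- records[ord, , drop = FALSE]
    out <- sorted[!duplicated(sorted$gene_id), c("gene_id", "lfc"),
                  drop = FALSE]
  } else {
    agg <- tapply(records$lfc, records$gene_id, mean)
    out <- data.frame(gene_id = names(agg), lfc = as.numeric(agg),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect transcript- and protein-level gene lists
#'
#' Restricts both collapsed tables to the genes quantified at both omic
#' levels and pairs the two fold changes per gene. An empty intersection is
#' a hard error: nothing downstream can run.
#'
#' @param transcripts,proteins collapsed data frames (`gene_id`, `lfc`),
#'   unique `gene_id` each.
#' @return data frame with columns `gene_id`, `lfc_transcript`,
#'   `lfc_protein`, sorted by `gene_id`.
#' @export
intersect_levels <- function(transcripts, proteins) {
  if (anyDuplicated(transcripts$gene_id) || anyDuplicated(proteins$gene_id)) {
    stop("inputs must be collapsed to unique gene_id first", call. = FALSE)
  }
  shared <- intersect(transcripts$gene_id, proteins$gene_id)
  if (length(shared) == 0L) {
    stop("no genes shared between the transcript and protein tables",
         call. = FALSE)
  }
  out <- data.frame(
    gene_id = sort(shared),
    stringsAsFactors = FALSE
  )
  out$lfc_transcript <- transcripts$lfc[match(out$gene_id, transcripts$gene_id)]
  out$lfc_protein <- proteins$lfc[match(out$gene_id, proteins$gene_id)]
  rownames(out) <- NULL
  out
}

#' Compute log2 fold changes from a log-scale expression matrix
#'
#' Plain group-mean difference on an already log2-scale matrix:
#' `lfc = mean(group_a) - mean(group_b)` per gene, so positive values mean
#' higher expression in `group_a`. Genes with any missing value in either
#' group are dropped (listwise deletion) and counted.
#'
#' @param matrix numeric matrix, genes in rows (rownames = feature ids),
#'   samples in columns.
#' @param groups named character vector or two-column data frame
#'   (`sample`, `group`) assigning each column to a group.
#' @param group_a,group_b group labels; the contrast is `a - b`.
#' @return data frame with columns `feature_id`, `lfc`; attribute
#'   `n_dropped` counts genes removed for missing values.
#' @export
compute_lfc <- function(matrix, groups, group_a, group_b) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2L]]),
                              as.character(groups[[1L]]))
  }
  groups <- groups[colnames(matrix)]
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) stop("unknown group label: ", g, call. = FALSE)
  }
  a_cols <- names(groups)[groups == group_a]
  b_cols <- names(groups)[groups == group_b]
  sub <- matrix[, c(a_cols, b_cols), drop = FALSE]
  complete <- rowSums(!is.finite(sub)) == 0L
  dropped <- sum(!complete)
  sub <- sub[complete, , drop = FALSE]
  lfc <- rowMeans(sub[, a_cols, drop = FALSE]) -
    rowMeans(sub[, b_cols, drop = FALSE])
  out <- data.frame(feature_id = rownames(sub), lfc = as.numeric(lfc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Read a log-expression matrix and its sample-to-group assignment
#'
#' @param path TSV with genes in rows (first column = feature id) and
#'   samples in columns.
#' @return numeric matrix with feature-id rownames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path,
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- raw[[1L]]
  m
}

#' @rdname read_expression_matrix
#' @param path_groups two-column TSV `sample<TAB>group`.
#' @return `read_group_table`: named character vector sample -> group.
#' @export
read_group_table <- function(path_groups) {
  raw <- utils::read.delim(path_groups, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  stats::setNames(raw[[2L]], raw[[1L]])
}
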