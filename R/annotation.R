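#' Read a reference membership list
#'
#' A plain TSV membership list (first column = gene id; a `gene_id` header
#' is detected and skipped). Used for e.g. a plasma-proteome catalogue.
#'
#' @param path TSV path.
#' @param name reference name.
#' @param source_size nominal full size of the reference (may exceed the
#'   number of members supplied when the list was pre-restricted);
#'   defaults to the member count.
#' @return list with `name`, `members` (unique character vector),
#'   `source_size`.
#' @export
read_reference_set <- function(path, name = basename(path),
                               source_size = NULL) {
  if (!file.exists(path)) stop("reference set not found: ", path,
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  members <- raw[[1L]]
  if (length(members) > 0L && members[1L] == "gene_id") {
    members <- members[-1L]
  }
  reference_set(name, members, source_size)
}

#' @rdname read_reference_set
#' @param members character vector of member gene ids.
#' @export
reference_set <- function(name, members, source_size = NULL) {
  members <- unique(members[nzchar(members)])
  if (length(members) == 0L) stop("reference set '", name, "' is empty",
                                  call. = FALSE)
  list(name = name, members = members,
       source_size = if (is.null(source_size)) length(members)
                     else as.integer(source_size))
}

#' Overlap a top-discordant gene selection with a plasma-proteome reference
#'
#' Flags which of the top discordantly expressed genes (protein up,
#' transcript down) are catalogued as detectable in blood plasma --
#' candidates for proteins acquired by the tumour from circulation rather
#' than synthesised in situ. Hits are returned with their full rank
#' annotation, ordered by `avg_rank_discordant` descending (strongest
#' discordance first) with a gene-id tie-break.
#'
#' @param top_discordant data frame of ranked gene records, typically
#'   `top_k(table, k, "discordant_protein_up")`.
#' @param plasma reference set from [reference_set()]/[read_reference_set()].
#' @return list with `query_size`, `hits` (data frame), `hit_count`.
#' @export
plasma_overlap <- function(top_discordant, plasma) {
  if (length(plasma$members) == 0L) stop("empty plasma reference",
                                         call. = FALSE)
  hits <- top_discordant[top_discordant$gene_id %in% plasma$members, ,
                         drop = FALSE]
  if (!is.null(hits$avg_rank_discordant)) {
    hits <- hits[order(-hits$avg_rank_discordant, hits$gene_id), ,
                 drop = FALSE]
  } else {
    hits <- hits[order(hits$gene_id), , drop = FALSE]
  }
  rownames(hits) <- NULL
  list(query_size = nrow(top_discordant), hits = hits,
       hit_count = nrow(hits))
}

#' Read a drug-gene interaction table
#'
#' Three-column TSV `gene_id<TAB>drug_name<TAB>approved` (approved parsed
#' as logical; header detected and skipped). Duplicate (gene, drug) pairs
#' are removed.
#'
#' @param path TSV path.
#' @return data frame with columns `gene_id`, `drug_name`, `approved`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("drug table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("drug table needs three columns", call. = FALSE)
  tab <- data.frame(gene_id = raw[[1L]], drug_name = raw[[2L]],
                    approved = raw[[3L]], stringsAsFactors = FALSE)
  if (nrow(tab) > 0L && tab$gene_id[1L] == "gene_id") {
    tab <- tab[-1L, , drop = FALSE]
  }
  tab$approved <- toupper(tab$approved) %in% c("TRUE", "T", "1", "YES")
  tab <- tab[!duplicated(tab[, c("gene_id", "drug_name")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Filter the ranked table for druggable, concordantly upregulated genes
#'
#' Two-stage filter: stage 1 keeps genes with at least one (approved)
#' drug interaction; stage 2 keeps the stage-1 subset with a concordant
#' increase, operationalised as strictly positive fold change at both
#' levels (`require = "concordant_up_sign"`, the default) or alternatively
#' as membership in the lowest quantile of `avg_rank_concordant`
#' (`require = "rank_quantile"`).
#'
#' @param table output of [rank_table()].
#' @param interactions data frame from [read_drug_table()] (or with the
#'   same columns).
#' @param approved_only drop non-approved interactions first (default
#'   `TRUE`; set `FALSE` if the table was pre-filtered upstream).
#' @param require stage-2 criterion, see above.
#' @param rank_quantile quantile of `avg_rank_concordant` used when
#'   `require = "rank_quantile"` (default 0.25).
#' @return list with `stage1_count`, `stage2_count`, and `targets`: one row
#'   per retained gene with its fold changes, concordance average rank (if
#'   present) and a semicolon-joined, sorted `drugs` column.
#' @export
drug_target_filter <- function(table, interactions, approved_only = TRUE,
                               require = c("concordant_up_sign",
                                           "rank_quantile"),
                               rank_quantile = 0.25) {
  require <- match.arg(require)
  ints <- interactions
  if (approved_only) ints <- ints[ints$approved, , drop = FALSE]
  stage1 <- table[table$gene_id %in% ints$gene_id, , drop = FALSE]
  stage2 <- if (require == "concordant_up_sign") {
    stage1[stage1$lfc_transcript > 0 & stage1$lfc_protein > 0, ,
           drop = FALSE]
  } else {
    cut <- stats::quantile(table$avg_rank_concordant, rank_quantile)
    stage1[stage1$avg_rank_concordant <= cut, , drop = FALSE]
  }
  drugs <- vapply(stage2$gene_id, function(g) {
    paste(sort(unique(ints$drug_name[ints$gene_id == g])), collapse = ";")
  }, character(1))
  cols <- intersect(c("gene_id", "lfc_transcript", "lfc_protein",
                      "avg_rank_concordant"), names(stage2))
  targets <- stage2[, cols, drop = FALSE]
  targets$drugs <- unname(drugs)
  if ("avg_rank_concordant" %in% names(targets)) {
    targets <- targets[order(targets$avg_rank_concordant,
                             targets$gene_id), , drop = FALSE]
  } else {
    targets <- targets[order(targets$gene_id), , drop = FALSE]
  }
  rownames(targets) <- NULL
  list(stage1_count = nrow(stage1), stage2_count = nrow(stage2),
       targets = targets)
}
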