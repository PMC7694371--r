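#' Rank a numeric vector with a fixed direction and midrank ties
#'
#' Descending order assigns rank 1 to the largest value (the convention used
#' for fold-change ranking throughout the package); ascending assigns rank 1
#' to the smallest. Ties receive the mean of the rank positions they span
#' (midrank), which preserves the rank-sum identity
#' `sum(ranks) == N(N+1)/2`.
#'
#' @param values finite numeric vector, length >= 1.
#' @param order `"descending"` or `"ascending"`.
#' @param ties tie rule; only `"midrank"` is defined.
#' @return numeric vector of ranks in `[1, N]`.
#' @export
rank_values <- function(values, order = c("descending", "ascending"),
                        ties = "midrank") {
  order <- match.arg(order)
  ties <- match.arg(ties, "midrank")
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("values must all be finite", call. = FALSE)
  }
  if (order == "descending") {
    rank(-values, ties.method = "average")
  } else {
    rank(values, ties.method = "average")
  }
}

#' Average of two rank positions
#'
#' The integration statistic: the mean of a gene's transcript-fold-change
#' rank and protein-fold-change rank under direction-specific orderings.
#'
#' @param rank_a,rank_b rank vectors of equal length.
#' @return numeric vector `(rank_a + rank_b) / 2`.
#' @export
average_rank <- function(rank_a, rank_b) {
  (rank_a + rank_b) / 2
}

validate_integrated <- function(table) {
  need <- c("gene_id", "lfc_transcript", "lfc_protein")
  if (!all(need %in% names(table))) {
    stop("integrated table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0L) stop("integrated table is empty", call. = FALSE)
  if (anyDuplicated(table$gene_id)) {
    stop("gene_id values must be unique", call. = FALSE)
  }
  invisible(table)
}

#' Attach all concordance and discordance rank columns
#'
#' Computes the three elementary rankings over the paired fold changes --
#' transcript descending (`rank_t_desc`), protein descending
#' (`rank_p_desc`), protein ascending (`rank_p_asc`) -- and both average
#' ranks. Low `avg_rank_concordant` = concordant upregulation, high =
#' concordant downregulation. High `avg_rank_discordant` = protein up /
#' transcript down; low = protein down / transcript up.
#'
#' @param table data frame with `gene_id`, `lfc_transcript`, `lfc_protein`.
#' @param ties tie rule passed to [rank_values()].
#' @return the table with five added rank columns.
#' @export
rank_table <- function(table, ties = "midrank") {
  validate_integrated(table)
  out <- table
  out$rank_t_desc <- rank_values(out$lfc_transcript, "descending", ties)
  out$rank_p_desc <- rank_values(out$lfc_protein, "descending", ties)
  out$rank_p_asc <- rank_values(out$lfc_protein, "ascending", ties)
  out$avg_rank_concordant <- average_rank(out$rank_t_desc, out$rank_p_desc)
  out$avg_rank_discordant <- average_rank(out$rank_t_desc, out$rank_p_asc)
  out
}

#' Score concordant differential expression
#'
#' Both fold-change columns are ranked in descending order (largest fold
#' change = rank 1) and averaged. Sorting the result by
#' `avg_rank_concordant` ascending puts concordantly upregulated genes
#' first and concordantly downregulated genes last.
#'
#' @inheritParams rank_table
#' @return table with `rank_t_desc`, `rank_p_desc`, `avg_rank_concordant`.
#' @export
score_concordance <- function(table, ties = "midrank") {
  full <- rank_table(table, ties)
  full[, setdiff(names(full), c("rank_p_asc", "avg_rank_discordant")),
       drop = FALSE]
}

#' Score discordant differential expression
#'
#' Protein fold changes are ranked ascending (lowest = rank 1) while
#' transcript fold changes stay in descending order; the average of the two
#' ranks is large for genes with upregulated protein but downregulated
#' transcript, and small for the reverse pattern.
#'
#' @inheritParams rank_table
#' @return table with `rank_t_desc`, `rank_p_asc`, `avg_rank_discordant`.
#' @export
score_discordance <- function(table, ties = "midrank") {
  full <- rank_table(table, ties)
  full[, setdiff(names(full), c("rank_p_desc", "avg_rank_concordant")),
       drop = FALSE]
}

top_k_modes <- c("concordant_up", "concordant_down",
                 "discordant_protein_up", "discordant_protein_down")

#' Select the top-k genes of a ranked table in one direction
#'
#' Selection keys on the relevant average rank: `concordant_up` takes the k
#' smallest `avg_rank_concordant`, `concordant_down` the k largest;
#' `discordant_protein_up` the k largest `avg_rank_discordant`,
#' `discordant_protein_down` the k smallest. With `sign_filter` on,
#' candidates are first restricted to the direction's literal sign pattern
#' (e.g. `discordant_protein_up`: `lfc_protein > 0` and
#' `lfc_transcript < 0`) and the top k of the remainder are taken.
#' Boundary ties are broken by `gene_id` lexicographic order, so the
#' selection is deterministic.
#'
#' @param table output of [rank_table()] (or of the scoring function that
#'   carries the needed average-rank column).
#' @param k number of genes to select, `1 <= k <= nrow(table)`. If the sign
#'   filter leaves fewer than k candidates, all of them are returned.
#' @param mode one of `"concordant_up"`, `"concordant_down"`,
#'   `"discordant_protein_up"`, `"discordant_protein_down"`.
#' @param sign_filter logical; default `TRUE` for the discordant modes and
#'   `FALSE` for the concordant modes (where the rank ordering alone
#'   already expresses the direction).
#' @return the selected rows, ordered best-first.
#' @export
top_k <- function(table, k, mode = top_k_modes, sign_filter = NULL) {
  mode <- match.arg(mode)
  n <- nrow(table)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]", call. = FALSE)
  if (is.null(sign_filter)) sign_filter <- grepl("^discordant", mode)
  spec <- switch(mode,
    concordant_up = list(key = "avg_rank_concordant", decreasing = FALSE,
                         sign = quote(lfc_transcript > 0 & lfc_protein > 0)),
    concordant_down = list(key = "avg_rank_concordant", decreasing = TRUE,
                           sign = quote(lfc_transcript < 0 & lfc_protein < 0)),
    discordant_protein_up = list(key = "avg_rank_discordant",
                                 decreasing = TRUE,
                                 sign = quote(lfc_protein > 0 &
                                                lfc_transcript < 0)),
    discordant_protein_down = list(key = "avg_rank_discordant",
                                   decreasing = FALSE,
                                   sign = quote(lfc_protein < 0 &
                                                  lfc_transcript > 0)))
  if (!spec$key %in% names(table)) {
    stop("table lacks column ", spec$key, "; run rank_table() first",
         call. = FALSE)
  }
  cand <- table
  if (sign_filter) {
    cand <- cand[eval(spec$sign, cand), , drop = FALSE]
  }
  key <- cand[[spec$key]]
  if (spec$decreasing) key <- -key
  ord <- order(key, cand$gene_id)
  out <- cand[ord, , drop = FALSE][seq_len(min(k, nrow(cand))), ,
                                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of the paired fold changes
#'
#' Sample Pearson coefficient over the transcript/protein fold-change
#' pairs with a two-sided p-value from the t-distribution with n - 2
#' degrees of freedom.
#'
#' @param table integrated table with `lfc_transcript`, `lfc_protein`.
#' @return list with elements `r`, `p_value`, `n`.
#' @export
lfc_correlation <- function(table) {
  x <- table$lfc_transcript
  y <- table$lfc_protein
  n <- length(x)
  if (n < 3L) stop("need at least 3 gene pairs for a correlation p-value",
                   call. = FALSE)
  if (stats::sd(x) == 0) stop("lfc_transcript is constant", call. = FALSE)
  if (stats::sd(y) == 0) stop("lfc_protein is constant", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
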