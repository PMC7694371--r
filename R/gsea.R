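#' Read a gene-set collection from a GMT file
#'
#' Thin wrapper around an established GMT parser; enforces unique set names
#' and non-empty sets and attaches a source label used in reports.
#'
#' @param path GMT file (one line per set: name, description, members,
#'   tab-separated).
#' @param source label recorded on the collection (e.g. a database name).
#' @return named list of character vectors with attribute `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in ", path, call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path,
                                     call. = FALSE)
  attr(sets, "source") <- source
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set (GMT column
#'   2); defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# Sort scores for the running sum: descending score, gene id as the
# deterministic tie-break.
sort_ranked <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named vector (names = gene ids)", call. = FALSE)
  }
  scores[order(-scores, names(scores))]
}

# Enrichment score from hit positions only. The running sum rises at hits
# and falls linearly between them, so its extrema occur immediately after a
# hit (maxima) or immediately before one (minima); evaluating only those 2k
# points gives the exact ES in O(k) after the positions are known.
es_from_hits <- function(hit_pos, hit_w, n) {
  k <- length(hit_pos)
  sw <- sum(hit_w)
  if (sw <= 0) {            # all hit scores zero: fall back to equal weights
    hit_w <- rep(1, k)
    sw <- k
  }
  cw <- cumsum(hit_w) / sw
  miss_step <- 1 / (n - k)
  d <- (hit_pos - seq_len(k)) * miss_step   # misses preceding each hit
  after <- cw - d
  before <- c(0, cw[-k]) - d
  max_dev <- max(after, 0)
  min_dev <- min(before, 0)
  if (max_dev >= -min_dev) max_dev else min_dev
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list from the top; at each in-set gene ("hit") the sum
#' advances by `|score|^weight` normalised over the in-set scores, at each
#' out-of-set gene it retreats by `1/(N - N_hit)`. The enrichment score is
#' the running-sum value of largest absolute deviation from zero (signed;
#' an exact positive/negative tie resolves to the positive extremum). The
#' sum returns to zero after the last gene. `weight = 0` reduces the hit
#' increment to `1/N_hit`, recovering the classical Kolmogorov-Smirnov
#' statistic between hit and miss positions.
#'
#' @param scores named numeric vector of per-gene ranking scores (here:
#'   log2 fold changes). Sorted internally by descending score with gene-id
#'   tie-break.
#' @param set_members character vector of gene ids.
#' @param weight non-negative exponent on `|score|` for hit increments
#'   (default 1).
#' @return list with `es` (scalar) and `running_sum` (length-N vector
#'   following the sorted list).
#' @export
enrichment_score <- function(scores, set_members, weight = 1) {
  stopifnot(weight >= 0)
  s <- sort_ranked(scores)
  n <- length(s)
  hit <- names(s) %in% set_members
  n_hit <- sum(hit)
  if (n_hit == 0L) {
    stop("gene set has no members in the ranked universe", call. = FALSE)
  }
  if (n_hit == n) {
    stop("gene set covers the whole universe; miss step undefined",
         call. = FALSE)
  }
  w <- abs(s[hit])^weight
  sw <- sum(w)
  if (sw <= 0) {
    w <- rep(1, n_hit)
    sw <- n_hit
  }
  inc <- rep(-1 / (n - n_hit), n)
  inc[hit] <- w / sw
  running <- cumsum(inc)
  max_dev <- max(running)
  min_dev <- min(running)
  es <- if (max_dev >= -min_dev) max_dev else min_dev
  list(es = es, running_sum = unname(running))
}

#' Gene-set resampling null distribution of the enrichment score
#'
#' Draws `n_perm` uniform random gene subsets of the given size from the
#' ranked universe and records each subset's enrichment score. This is the
#' null model available in pre-ranked mode (no sample labels to permute).
#' Reproducible under a fixed seed.
#'
#' @inheritParams enrichment_score
#' @param set_size size of each resampled set, `1 <= set_size < N`.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed set before drawing.
#' @return numeric vector of `n_perm` enrichment scores.
#' @export
permutation_null <- function(scores, set_size, n_perm = 1000L, weight = 1,
                             seed = NULL) {
  s <- sort_ranked(scores)
  n <- length(s)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (set_size < 1L || set_size >= n) {
    stop("set_size must lie in [1, N-1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  abs_w <- abs(as.numeric(s))^weight
  vapply(seq_len(n_perm), function(i) {
    idx <- sort.int(sample.int(n, set_size))
    es_from_hits(idx, abs_w[idx], n)
  }, numeric(1))
}

#' Normalise an enrichment score and attach its permutation p-value
#'
#' The normalised enrichment score divides the observed ES by the mean
#' magnitude of same-sign null scores; the p-value is the same-sign tail
#' fraction with an add-one pseudocount so it is never exactly zero:
#' `p = (1 + #{|null| >= |es|, same sign}) / (1 + #{same sign})`. When no
#' same-sign null value exists the NES is undefined (`NA`) and the p-value
#' is `1 / (0 + 1) = 1` by the same convention.
#'
#' @param es_obs observed enrichment score. A zero score is treated as
#'   positive-sign.
#' @param es_null numeric vector of null enrichment scores.
#' @return list with `nes`, `p_perm`, `n_same_sign`.
#' @export
normalize_and_test <- function(es_obs, es_null) {
  if (length(es_null) == 0L) stop("empty null distribution", call. = FALSE)
  pool <- if (es_obs >= 0) es_null[es_null > 0] else es_null[es_null < 0]
  m <- length(pool)
  if (m == 0L) {
    return(list(nes = NA_real_, p_perm = 1, n_same_sign = 0L))
  }
  list(nes = es_obs / mean(abs(pool)),
       p_perm = (1 + sum(abs(pool) >= abs(es_obs))) / (1 + m),
       n_same_sign = m)
}

# Normalise a null ES vector against itself (each value divided by the mean
# magnitude of the same-sign values), producing the null NES pool used by
# the FDR estimator.
normalize_null <- function(es_null) {
  pos <- es_null > 0
  neg <- es_null < 0
  out <- es_null
  if (any(pos)) out[pos] <- es_null[pos] / mean(es_null[pos])
  if (any(neg)) out[neg] <- es_null[neg] / mean(abs(es_null[neg]))
  out
}

#' Permutation-based FDR q-values for normalised enrichment scores
#'
#' For each observed NES the q-value is the ratio of the null tail fraction
#' (pooled same-sign null NES at least as extreme) to the observed tail
#' fraction (same-sign observed NES at least as extreme), capped at 1 and
#' then monotonised within each sign class so that q is non-increasing in
#' `|NES|`.
#'
#' @param nes_obs numeric vector of observed NES (one per set; `NA`
#'   allowed for sets with undefined NES and propagated).
#' @param nes_null matrix of null NES values, one row per set (pooled over
#'   all sets and permutations), or a plain numeric vector already pooled.
#' @return numeric vector of q-values in `[0, 1]`.
#' @export
fdr_q <- function(nes_obs, nes_null) {
  pool <- as.vector(nes_null)
  pool <- pool[is.finite(pool)]
  q <- rep(NA_real_, length(nes_obs))
  for (positive in c(TRUE, FALSE)) {
    idx <- which(is.finite(nes_obs) &
                   (if (positive) nes_obs >= 0 else nes_obs < 0))
    if (length(idx) == 0L) next
    obs <- nes_obs[idx]
    pp <- if (positive) pool[pool > 0] else pool[pool < 0]
    raw <- vapply(obs, function(v) {
      num <- if (length(pp) == 0L) 0 else {
        if (positive) mean(pp >= v) else mean(pp <= v)
      }
      den <- if (positive) mean(obs >= v) else mean(obs <= v)
      min(1, num / den)
    }, numeric(1))
    # enforce monotonicity: a more extreme NES never gets a larger q
    ord <- order(-abs(obs))
    adj <- rev(cummin(rev(raw[ord])))
    q[idx[ord]] <- adj
  }
  q
}

#' Pre-ranked gene-set enrichment over one omic level
#'
#' Full pre-ranked analysis built from the primitives above: per-set
#' running-sum ES, a gene-set resampling null shared across sets of the
#' same size, NES, add-one permutation p-values and permutation FDR
#' q-values. Sets are restricted to the ranked universe first; sets smaller
#' than `min_size` after restriction (or named in `blocklist`, e.g.
#' disease-specific pathways) are skipped and recorded in the
#' `n_skipped` attribute.
#'
#' @inheritParams enrichment_score
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param n_perm permutations per distinct set size (default 1000).
#' @param seed integer seed; nulls for a set of size s use sub-seed
#'   `seed + s`, so results do not depend on collection order.
#' @param min_size minimum members-in-universe per set (default 5).
#' @param max_size maximum members-in-universe per set (default unlimited).
#' @param blocklist character vector of set names to exclude.
#' @return data frame with columns `set_name`, `size_in_universe`, `es`,
#'   `nes`, `p_perm`, `q_fdr`, sorted by `set_name`; attributes
#'   `n_skipped` and `skipped_sets`.
#' @export
run_preranked_gsea <- function(scores, collection, n_perm = 1000L,
                               weight = 1, seed = 1L, min_size = 5L,
                               max_size = Inf, blocklist = NULL) {
  s <- sort_ranked(scores)
  universe <- names(s)
  restricted <- lapply(collection, function(g) intersect(g, universe))
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(universe) &
    !(names(collection) %in% blocklist)
  skipped <- names(collection)[!keep]
  restricted <- restricted[keep]
  if (length(restricted) == 0L) {
    out <- data.frame(set_name = character(), size_in_universe = integer(),
                      es = numeric(), nes = numeric(), p_perm = numeric(),
                      q_fdr = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- length(skipped)
    attr(out, "skipped_sets") <- skipped
    return(out)
  }
  restricted <- restricted[order(names(restricted))]
  sizes <- lengths(restricted)

  nulls <- list()
  for (sz in sort(unique(sizes))) {
    nulls[[as.character(sz)]] <- permutation_null(
      s, set_size = sz, n_perm = n_perm, weight = weight,
      seed = (as.integer(seed) + sz) %% .Machine$integer.max)
  }

  es <- vapply(restricted, function(g) enrichment_score(s, g, weight)$es,
               numeric(1))
  norm <- lapply(seq_along(restricted), function(i) {
    normalize_and_test(es[[i]], nulls[[as.character(sizes[[i]])]])
  })
  nes <- vapply(norm, `[[`, numeric(1), "nes")
  p_perm <- vapply(norm, `[[`, numeric(1), "p_perm")
  null_nes <- do.call(rbind, lapply(sizes, function(sz) {
    normalize_null(nulls[[as.character(sz)]])
  }))
  out <- data.frame(set_name = names(restricted),
                    size_in_universe = as.integer(sizes),
                    es = unname(es), nes = unname(nes),
                    p_perm = unname(p_perm),
                    q_fdr = fdr_q(unname(nes), null_nes),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(skipped)
  attr(out, "skipped_sets") <- skipped
  out
}

#' Combine transcript- and protein-level enrichment by the dual-FDR rule
#'
#' A set passes when its FDR q-value is below the threshold at both omic
#' levels and its NES has the same sign at both (direction
#' `concordant_up` / `concordant_down`; opposite or undefined signs are
#' `mixed` and never pass). Because the two enrichment analyses are run on
#' independent datasets, requiring q < t at both levels implies a combined
#' significance threshold of t^2 (multiplicative), recorded in the
#' `combined_threshold` attribute. Sets present on one side only are kept,
#' flagged by `in_both = FALSE`, and never pass.
#'
#' @param transcript_rows,protein_rows data frames from
#'   [run_preranked_gsea()] on the two levels.
#' @param fdr_threshold per-level FDR threshold (default 0.2).
#' @return data frame with columns `set_name`, `nes_transcript`,
#'   `nes_protein`, `q_transcript`, `q_protein`, `combined_nes` (mean of
#'   the two NES), `direction`, `in_both`, `passes_dual_fdr`; attribute
#'   `combined_threshold = fdr_threshold^2`.
#' @export
dual_level_combine <- function(transcript_rows, protein_rows,
                               fdr_threshold = 0.2) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  t_sub <- transcript_rows[, c("set_name", "nes", "q_fdr")]
  names(t_sub) <- c("set_name", "nes_transcript", "q_transcript")
  p_sub <- protein_rows[, c("set_name", "nes", "q_fdr")]
  names(p_sub) <- c("set_name", "nes_protein", "q_protein")
  out <- merge(t_sub, p_sub, by = "set_name", all = TRUE, sort = TRUE)
  out$in_both <- !is.na(out$nes_transcript) & !is.na(out$nes_protein)
  out$combined_nes <- (out$nes_transcript + out$nes_protein) / 2
  sign_t <- sign(out$nes_transcript)
  sign_p <- sign(out$nes_protein)
  out$direction <- ifelse(!out$in_both | is.na(sign_t) | is.na(sign_p),
                          "mixed",
                          ifelse(sign_t > 0 & sign_p > 0, "concordant_up",
                                 ifelse(sign_t < 0 & sign_p < 0,
                                        "concordant_down", "mixed")))
  out$passes_dual_fdr <- out$in_both & out$direction != "mixed" &
    !is.na(out$q_transcript) & !is.na(out$q_protein) &
    out$q_transcript < fdr_threshold & out$q_protein < fdr_threshold
  rownames(out) <- NULL
  attr(out, "combined_threshold") <- fdr_threshold^2
  out
}
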