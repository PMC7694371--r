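# Shared fixtures, built in code at test time.

# A tie-free integrated table with random fold changes.
random_table <- function(n, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%04d", sample(n)),
             lfc_transcript = rnorm(n, sd = 0.5),
             lfc_protein = rnorm(n, 0.4, 1.2),
             stringsAsFactors = FALSE)
}

# 5-gene toy whose concordance average ranks are 1..5 by construction.
toy_table <- function() {
  data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
             lfc_transcript = c(2, 1, 0, -1, -2),
             lfc_protein = c(3, 1, 0, -1, -3),
             stringsAsFactors = FALSE)
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent oracle: enrichment running sum built step by step, no shared
# code with the package implementation.
oracle_running_sum <- function(scores_sorted, members, weight) {
  hit <- names(scores_sorted) %in% members
  nh <- sum(hit)
  n <- length(scores_sorted)
  w <- abs(scores_sorted)^weight
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) w[i] / sum(w[hit]) else -1 / (n - nh)
    run[i] <- acc
  }
  run
}

oracle_es <- function(scores_sorted, members, weight) {
  run <- oracle_running_sum(scores_sorted, members, weight)
  if (max(run) >= -min(run)) max(run) else min(run)
}
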