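test_that("rank_values assigns direction-specific ranks with midrank ties", {
  expect_equal(rank_values(c(2.0, 0.5, -1.0), "descending"), c(1, 2, 3))
  expect_equal(rank_values(c(2.0, 0.5, -1.0), "ascending"), c(3, 2, 1))
  expect_equal(rank_values(c(1.0, 1.0, 0.0), "descending"), c(1.5, 1.5, 3))
  expect_error(rank_values(c(1, NA)), "finite")
  # rank-sum identity holds with and without ties
  for (seed in 1:5) {
    set.seed(seed)
    v <- sample(round(rnorm(20), 1), 20, replace = TRUE)
    n <- length(v)
    expect_equal(sum(rank_values(v, "descending")), n * (n + 1) / 2)
  }
})

test_that("concordance scoring orders the toy table 1..5 and pins the extreme gene", {
  sc <- score_concordance(toy_table())
  expect_equal(sc$avg_rank_concordant, as.numeric(1:5))
  # gene with both largest LFCs is forced to average rank 1
  expect_equal(sc$avg_rank_concordant[sc$gene_id == "gA"], 1)
})

test_that("sign-flipping every LFC mirrors the concordance average rank", {
  for (seed in 1:20) {
    tab <- random_table(50, seed)
    flipped <- tab
    flipped$lfc_transcript <- -flipped$lfc_transcript
    flipped$lfc_protein <- -flipped$lfc_protein
    a <- score_concordance(tab)
    b <- score_concordance(flipped)
    n <- nrow(tab)
    expect_equal(b$avg_rank_concordant, n + 1 - a$avg_rank_concordant)
  }
})

test_that("discordance scoring matches published worked ranks and forced extremes", {
  # a printed worked example: transcript rank 3521, ascending protein rank
  # 3234 average to 3377.5
  expect_equal(average_rank(3521, 3234), 3377.5)

  # largest protein LFC + smallest transcript LFC forces average rank N
  tab <- random_table(40, seed = 3)
  tab$lfc_protein[7] <- max(tab$lfc_protein) + 1
  tab$lfc_transcript[7] <- min(tab$lfc_transcript) - 1
  sd_ <- score_discordance(tab)
  expect_equal(sd_$avg_rank_discordant[7], 40)
})

test_that("ascending and descending protein ranks are complementary on tie-free tables", {
  for (seed in 1:100) {
    tab <- random_table(30, seed)
    rt <- rank_table(tab)
    n <- nrow(tab)
    expect_equal(sort(rt$rank_t_desc), as.numeric(1:n))
    expect_equal(sort(rt$rank_p_desc), as.numeric(1:n))
    expect_equal(rt$rank_p_asc, n + 1 - rt$rank_p_desc)
    expect_equal(rt$avg_rank_concordant + rt$avg_rank_discordant,
                 rt$rank_t_desc + (n + 1) / 2)
  }
})

test_that("average-rank statistics are invariant under monotone transforms", {
  for (seed in 1:10) {
    tab <- random_table(40, seed)
    warped <- tab
    warped$lfc_transcript <- exp(tab$lfc_transcript)
    warped$lfc_protein <- tab$lfc_protein^3  # strictly increasing
    a <- rank_table(tab)
    b <- rank_table(warped)
    expect_equal(b$avg_rank_concordant, a$avg_rank_concordant)
    expect_equal(b$avg_rank_discordant, a$avg_rank_discordant)
  }
})

test_that("top_k selects by average rank with deterministic boundaries", {
  rt <- rank_table(toy_table())
  expect_equal(top_k(rt, 2, "concordant_up")$gene_id, c("gA", "gB"))
  expect_equal(top_k(rt, 2, "concordant_down")$gene_id, c("gE", "gD"))
  expect_equal(nrow(top_k(rt, 5, "concordant_up")), 5L)  # k = N
  expect_error(top_k(rt, 0, "concordant_up"))
  expect_error(top_k(rt, 6, "concordant_up"))
})

test_that("the discordant sign filter replaces non-conforming genes", {
  # gD: protein up (+2), transcript down (-1) -> conforming discordant;
  # gE: extreme discordant rank but transcript LFC positive -> filtered out
  tab <- data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
                    lfc_transcript = c(1.0, 0.5, 0.2, -1.0, 0.1),
                    lfc_protein = c(-2.0, -0.5, 0.3, 2.0, 3.0),
                    stringsAsFactors = FALSE)
  rt <- rank_table(tab)
  unfiltered <- top_k(rt, 2, "discordant_protein_up", sign_filter = FALSE)
  expect_true("gE" %in% unfiltered$gene_id)
  filtered <- top_k(rt, 2, "discordant_protein_up")  # filter is the default
  expect_false("gE" %in% filtered$gene_id)
  expect_equal(filtered$gene_id[1], "gD")

  # brute-force oracle over a random table
  for (seed in 1:5) {
    big <- rank_table(random_table(60, seed))
    got <- top_k(big, 5, "discordant_protein_up", sign_filter = TRUE)
    conform <- big[big$lfc_protein > 0 & big$lfc_transcript < 0, ]
    want <- conform[order(-conform$avg_rank_discordant,
                          conform$gene_id), ][seq_len(min(5, nrow(conform))), ]
    expect_equal(got$gene_id, want$gene_id)
  }
})

test_that("lfc_correlation matches a closed-form covariance/t-CDF oracle", {
  tab <- random_table(10, seed = 11)
  got <- lfc_correlation(tab)
  x <- tab$lfc_transcript
  y <- tab$lfc_protein
  n <- 10
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_stat), df = n - 2)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  expect_equal(got$n, n)

  ident <- tab
  ident$lfc_protein <- ident$lfc_transcript
  expect_equal(lfc_correlation(ident)$r, 1.0)
  ident$lfc_protein <- -ident$lfc_transcript
  expect_equal(lfc_correlation(ident)$r, -1.0)
  const <- tab
  const$lfc_protein <- 1
  expect_error(lfc_correlation(const), "lfc_protein is constant")
})
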