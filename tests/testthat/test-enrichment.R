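scores4 <- setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))

test_that("enrichment_score reproduces hand-computed running sums", {
  # single hit at the top with weight 1: increment 4/4 = 1, no prior misses
  r <- enrichment_score(scores4, "a", weight = 1)
  expect_equal(r$es, 1.0)
  expect_equal(r$running_sum, c(1, 2 / 3, 1 / 3, 0))

  # single hit at the bottom, weight 0, uniform positive scores: the running
  # sum loses 1/(N-1) per miss and reaches -1 at the penultimate position
  r2 <- enrichment_score(scores4, "d", weight = 0)
  expect_equal(r2$es, oracle_es(sort(scores4, decreasing = TRUE), "d", 0))
  expect_equal(r2$es, -1)

  # degenerate sets are errors
  expect_error(enrichment_score(scores4, "zz"), "no members")
  expect_error(enrichment_score(scores4, names(scores4)), "whole universe")
})

test_that("running sum closes to zero and |ES| stays within 1 on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(8:40, 1)
    s <- setNames(rnorm(n), sprintf("g%03d", sample(n)))
    members <- sample(names(s), sample(seq_len(n - 1), 1))
    w <- sample(c(0, 0.5, 1, 2), 1)
    r <- enrichment_score(s, members, weight = w)
    expect_lte(abs(r$es), 1)
    expect_lt(abs(r$running_sum[n]), 1e-9)
    # dual route: step-by-step oracle agrees with the implementation
    sorted <- s[order(-s, names(s))]
    expect_equal(r$es, oracle_es(sorted, members, w), tolerance = 1e-12)
  }
})

test_that("weight 0 equals the two-sample Kolmogorov-Smirnov statistic", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:12, 1)
    s <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%02d", 1:n))
    members <- sample(names(s), sample(seq_len(n - 1), 1))
    es <- enrichment_score(s, members, weight = 0)$es
    # independent oracle: signed max ECDF difference between hit and miss
    # position distributions
    pos_hit <- which(names(s) %in% members)
    pos_miss <- setdiff(seq_len(n), pos_hit)
    diffs <- vapply(seq_len(n), function(i) {
      mean(pos_hit <= i) - mean(pos_miss <= i)
    }, numeric(1))
    ks <- if (max(diffs) >= -min(diffs)) max(diffs) else min(diffs)
    expect_equal(abs(es), abs(ks), tolerance = 1e-9)
    # sign must agree unless the two extrema tie in magnitude (where the
    # resolution is a pure convention, float-sensitive at 1e-16)
    if (abs(max(diffs) + min(diffs)) > 1e-9) {
      expect_equal(sign(es), sign(ks))
    }
  }
})

test_that("weight-1 enrichment scores agree with an established implementation", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    s <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%02d", 1:n))
    members <- sample(names(s), 8)
    ours <- enrichment_score(s, members, weight = 1)$es
    theirs <- fgsea::calcGseaStat(unname(s), which(names(s) %in% members),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("permutation_null is seed-reproducible and rejects degenerate sizes", {
  s <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  one <- permutation_null(s, 5, n_perm = 1, seed = 99)
  expect_identical(one, permutation_null(s, 5, n_perm = 1, seed = 99))
  expect_identical(permutation_null(s, 5, 50, seed = 7),
                   permutation_null(s, 5, 50, seed = 7))
  expect_error(permutation_null(s, 30, 10), "set_size")
  expect_error(permutation_null(s, 0, 10), "set_size")

  # two independent runs agree in location within Monte-Carlo error
  a <- permutation_null(s, 6, 400, seed = 1)
  b <- permutation_null(s, 6, 400, seed = 2)
  se <- sqrt(var(a) / 400 + var(b) / 400)
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-3)
})

test_that("normalisation and permutation p follow the add-one convention", {
  r <- normalize_and_test(0.5, rep(0.5, 10))
  expect_equal(r$nes, 1.0)
  expect_equal(r$p_perm, 1.0)
  r2 <- normalize_and_test(0.9, c(0.3, 0.3, 0.3))
  expect_equal(r2$nes, 3.0)
  expect_equal(r2$p_perm, 1 / 4)  # no null value reaches 0.9
  # no same-sign null: NES undefined, p = 1/(0+1)
  r3 <- normalize_and_test(0.4, c(-0.2, -0.5))
  expect_true(is.na(r3$nes))
  expect_equal(r3$p_perm, 1)
  expect_error(normalize_and_test(0.5, numeric()), "empty")
})

test_that("permutation p agrees with exhaustive subset enumeration", {
  s <- setNames(c(3, 2.5, 2, 1.5, 1, 0.5), sprintf("g%d", 1:6))
  obs_set <- c("g1", "g3")
  es_obs <- enrichment_score(s, obs_set, weight = 1)$es
  pairs <- combn(names(s), 2)
  es_all <- apply(pairs, 2, function(m) enrichment_score(s, m, 1)$es)
  expect_length(es_all, 15L)
  got <- normalize_and_test(es_obs, es_all)
  pool <- es_all[sign(es_all) == sign(es_obs)]
  expect_equal(got$p_perm,
               (1 + sum(abs(pool) >= abs(es_obs))) / (1 + length(pool)))
  expect_equal(got$nes, es_obs / mean(abs(pool)))
})

test_that("fdr_q matches a tail-counting oracle and is monotone in |NES|", {
  # a set beating every null value gets q = 0; a tie with the whole null
  # gets q = 1
  expect_equal(fdr_q(2.0, matrix(runif(20), nrow = 1)), 0)
  expect_equal(fdr_q(1.0, matrix(rep(1, 10), nrow = 1)), 1)

  # 3 sets x 10 permutations fixture, hand tail counts (already monotone)
  nes_obs <- c(2.0, 1.2, 0.8)
  set.seed(5)
  null <- matrix(runif(30, 0.2, 1.6), nrow = 3)
  got <- fdr_q(nes_obs, null)
  pool <- as.vector(null)
  hand <- vapply(seq_along(nes_obs), function(i) {
    num <- mean(pool >= nes_obs[i])
    den <- mean(nes_obs >= nes_obs[i])
    min(1, num / den)
  }, numeric(1))
  hand <- rev(cummin(rev(hand[order(-nes_obs)])))[order(order(-nes_obs))]
  expect_equal(got, hand)
  expect_true(all(diff(got[order(-abs(nes_obs))]) >= 0))

  # mixed signs are handled within their own sign class
  q <- fdr_q(c(1.5, -1.5), matrix(c(runif(10, 0, 1), runif(10, -1, 0)),
                                  nrow = 2, byrow = TRUE))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("run_preranked_gsea skips small sets and ranks a planted set first", {
  set.seed(10)
  n <- 300
  s <- setNames(rnorm(n, sd = 0.5), sprintf("g%03d", 1:n))
  planted <- names(sort(s, decreasing = TRUE))[1:20]
  sets <- list(PLANTED = planted,
               RANDOM1 = sample(names(s), 25),
               RANDOM2 = sample(names(s), 40),
               TINY = sample(names(s), 3),
               OUTSIDE = c("zz1", "zz2", "zz3", "zz4", "zz5"))
  res <- run_preranked_gsea(s, sets, n_perm = 200, seed = 42)
  expect_setequal(res$set_name, c("PLANTED", "RANDOM1", "RANDOM2"))
  expect_equal(attr(res, "n_skipped"), 2L)
  planted_row <- res[res$set_name == "PLANTED", ]
  expect_gt(planted_row$nes, 0)
  expect_lt(planted_row$p_perm, 0.05)
  expect_lt(planted_row$q_fdr, 0.05)
  expect_true(all(res$p_perm >= 1 / 201))
  # blocklist filter removes named sets
  res_b <- run_preranked_gsea(s, sets, n_perm = 50, seed = 42,
                              blocklist = "RANDOM1")
  expect_false("RANDOM1" %in% res_b$set_name)
})

test_that("dual_level_combine applies the two-level FDR and direction rule", {
  t_rows <- data.frame(set_name = c("S1", "S2", "S3", "S4"),
                       size_in_universe = 10L,
                       es = c(0.5, 0.4, 0.5, -0.4),
                       nes = c(1.8, 1.5, 1.9, -1.4),
                       p_perm = 0.01, q_fdr = c(0.1, 0.1, 0.1, 0.1),
                       stringsAsFactors = FALSE)
  p_rows <- data.frame(set_name = c("S1", "S2", "S3", "S5"),
                       size_in_universe = 10L,
                       es = c(0.6, 0.5, -0.3, 0.2),
                       nes = c(2.0, 1.7, -1.2, 1.1),
                       p_perm = 0.01, q_fdr = c(0.15, 0.3, 0.1, 0.1),
                       stringsAsFactors = FALSE)
  dual <- dual_level_combine(t_rows, p_rows, fdr_threshold = 0.2)
  expect_equal(attr(dual, "combined_threshold"), 0.04)
  row <- function(s) dual[dual$set_name == s, ]
  expect_true(row("S1")$passes_dual_fdr)           # q 0.1 / 0.15, both up
  expect_equal(row("S1")$direction, "concordant_up")
  expect_false(row("S2")$passes_dual_fdr)          # q_p = 0.3 fails
  expect_equal(row("S3")$direction, "mixed")       # opposite NES signs
  expect_false(row("S3")$passes_dual_fdr)
  expect_false(row("S4")$in_both)                  # one-sided: flagged
  expect_false(row("S4")$passes_dual_fdr)
  expect_false(row("S5")$in_both)
})

test_that("GMT files round-trip through writer and parser", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g2", "g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[["SET_A"]], sets$SET_A)
  expect_equal(back[["SET_B"]], sets$SET_B)
})
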