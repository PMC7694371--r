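#' Parameters and planted ground truth for a synthetic paired-LFC study
#'
#' Defines the generative conditions the synthetic study emulates: a
#' background of paired transcript/protein log2 fold changes drawn from a
#' bivariate normal with moderate positive correlation, a wider protein
#' margin than transcript margin (and a positive protein mean), plus a
#' minority of planted genes with strong concordant or discordant shifts.
#' Defaults mirror the integrated two-cohort contrast the package targets:
#' 3598 shared genes, correlation 0.35, transcript margin mean 0 / sd 0.5,
#' protein margin mean 0.41 / sd 1.2, planted effect sizes of three
#' marginal standard deviations, and 21 planted discordant genes flagged
#' as plasma-reference members (nominal reference size 1929).
#'
#' @param n_genes universe size (default 3598).
#' @param rho background correlation of the LFC pairs, in (-1, 1).
#' @param mean_t,mean_p marginal means of transcript / protein LFCs.
#' @param scale_t,scale_p marginal standard deviations (> 0).
#' @param n_concordant_up,n_concordant_down,n_discordant planted gene
#'   counts; the universe must hold at least 10x their total.
#' @param effect_t,effect_p additive shift magnitudes for planted genes
#'   (defaults `3 * scale_t`, `3 * scale_p`). Concordant-up genes get
#'   `(+effect_t, +effect_p)`, concordant-down `(-,-)`, discordant
#'   `(-effect_t, +effect_p)` (protein up, transcript down).
#' @param n_plasma_planted how many planted discordant genes are flagged as
#'   plasma-reference members (default 21).
#' @param plasma_source_size nominal size of the plasma reference; members
#'   beyond the planted ones are out-of-universe decoys (default 1929).
#' @param drug_fraction fraction of planted concordant-up genes linked to
#'   at least one approved drug (default 0.5).
#' @param seed integer master seed; every generator derives its own
#'   sub-seed from it.
#' @return list of class `synthetic_truth` with the parameters, the gene
#'   universe (`gene_id` values `g0001`...) and the planted id lists
#'   (`planted_concordant_up`, `planted_concordant_down`,
#'   `planted_discordant`, `plasma_planted`).
#' @export
synthetic_truth <- function(n_genes = 3598L, rho = 0.35,
                            mean_t = 0, mean_p = 0.41,
                            scale_t = 0.5, scale_p = 1.2,
                            n_concordant_up = 30L, n_concordant_down = 30L,
                            n_discordant = 60L,
                            effect_t = 3 * scale_t, effect_p = 3 * scale_p,
                            n_plasma_planted = 21L,
                            plasma_source_size = 1929L,
                            drug_fraction = 0.5, seed = 1L) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  stopifnot(scale_t > 0, scale_p > 0)
  n_planted <- n_concordant_up + n_concordant_down + n_discordant
  if (n_genes < 10L * n_planted) {
    stop("universe must hold at least 10x the planted gene count",
         call. = FALSE)
  }
  if (n_plasma_planted > n_discordant) {
    stop("cannot flag more plasma members than planted discordant genes",
         call. = FALSE)
  }
  universe <- sprintf("g%04d", seq_len(n_genes))
  # planted blocks occupy the head of the universe; disjoint by construction
  up <- universe[seq_len(n_concordant_up)]
  down <- universe[n_concordant_up + seq_len(n_concordant_down)]
  disc <- universe[n_concordant_up + n_concordant_down +
                     seq_len(n_discordant)]
  structure(list(
    n_genes = as.integer(n_genes), rho = rho,
    mean_t = mean_t, mean_p = mean_p,
    scale_t = scale_t, scale_p = scale_p,
    effect_t = effect_t, effect_p = effect_p,
    universe = universe,
    planted_concordant_up = up,
    planted_concordant_down = down,
    planted_discordant = disc,
    plasma_planted = disc[seq_len(n_plasma_planted)],
    plasma_source_size = as.integer(plasma_source_size),
    drug_fraction = drug_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# Expected (noise-free) per-gene LFC targets implied by the truth object.
truth_targets <- function(truth) {
  t_shift <- p_shift <- stats::setNames(numeric(truth$n_genes),
                                        truth$universe)
  t_shift[truth$planted_concordant_up] <- truth$effect_t
  p_shift[truth$planted_concordant_up] <- truth$effect_p
  t_shift[truth$planted_concordant_down] <- -truth$effect_t
  p_shift[truth$planted_concordant_down] <- -truth$effect_p
  t_shift[truth$planted_discordant] <- -truth$effect_t
  p_shift[truth$planted_discordant] <- truth$effect_p
  list(transcript = truth$mean_t + t_shift,
       protein = truth$mean_p + p_shift)
}

#' Simulate paired transcript/protein fold-change tables
#'
#' Background pairs are drawn from a bivariate normal with correlation
#' `rho`, means `(mean_t, mean_p)` and scales `(scale_t, scale_p)` (via a
#' Cholesky construction on two independent standard-normal draws);
#' planted genes then receive their additive shifts. Feature identifiers
#' are platform-style (`tx.<gene>`, `pr.<gene>`) with accompanying mapping
#' tables so the full ingest path can be exercised. Pure function of
#' (parameters, seed).
#'
#' @param truth a [synthetic_truth()] object.
#' @return list with `transcripts` and `proteins` (data frames
#'   `feature_id`, `lfc`), `mapping_transcript` / `mapping_protein`
#'   (feature -> gene), and the `truth` echo.
#' @export
simulate_paired_lfc <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(truth$seed, "lfc"))
  n <- truth$n_genes
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  lfc_t <- truth$mean_t + truth$scale_t * z1
  lfc_p <- truth$mean_p +
    truth$scale_p * (truth$rho * z1 + sqrt(1 - truth$rho^2) * z2)
  names(lfc_t) <- names(lfc_p) <- truth$universe
  tg <- truth_targets(truth)
  shift_t <- tg$transcript - truth$mean_t
  shift_p <- tg$protein - truth$mean_p
  lfc_t <- lfc_t + shift_t
  lfc_p <- lfc_p + shift_p
  list(
    transcripts = data.frame(feature_id = paste0("tx.", truth$universe),
                             lfc = unname(lfc_t), stringsAsFactors = FALSE),
    proteins = data.frame(feature_id = paste0("pr.", truth$universe),
                          lfc = unname(lfc_p), stringsAsFactors = FALSE),
    mapping_transcript = data.frame(
      feature_id = paste0("tx.", truth$universe),
      gene_id = truth$universe, stringsAsFactors = FALSE),
    mapping_protein = data.frame(
      feature_id = paste0("pr.", truth$universe),
      gene_id = truth$universe, stringsAsFactors = FALSE),
    truth = truth
  )
}

#' Simulate log-expression matrices realising the target fold changes
#'
#' Builds a transcript and a protein log2-expression matrix whose per-gene
#' group-mean difference equals the gene's target (noise-free) fold change,
#' plus i.i.d. Gaussian measurement noise, so that [compute_lfc()] recovers
#' the targets with per-gene standard error
#' `noise_sd * sqrt(1/n_a + 1/n_b)`. Group labels are `grade3` (n_a
#' samples) and `grade1` (n_b samples), matching the `a - b` contrast
#' convention.
#'
#' @param truth a [synthetic_truth()] object.
#' @param n_a,n_b samples per group (>= 2 each; defaults 6 and 8, the
#'   proteomic cohort sizes the defaults emulate).
#' @param noise_sd per-measurement Gaussian noise sd (default 0.5).
#' @param base_mean baseline log2 abundance added to every gene
#'   (default 8).
#' @return list with `transcript` and `protein`, each holding `values`
#'   (matrix), `groups` (named vector) and `targets` (named target-LFC
#'   vector).
#' @export
simulate_expression_matrices <- function(truth, n_a = 6L, n_b = 8L,
                                         noise_sd = 0.5, base_mean = 8) {
  stopifnot(inherits(truth, "synthetic_truth"), n_a >= 2L, n_b >= 2L,
            noise_sd >= 0)
  set.seed(derive_seed(truth$seed, "expression"))
  tg <- truth_targets(truth)
  samples <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  groups <- stats::setNames(rep(c("grade3", "grade1"), c(n_a, n_b)), samples)
  build <- function(targets) {
    n <- length(targets)
    mu <- outer(rep(base_mean, n), rep(0, n_a + n_b), `+`)
    mu[, seq_len(n_a)] <- mu[, seq_len(n_a)] + targets
    noise <- stats::rnorm(n * (n_a + n_b), sd = noise_sd)
    values <- mu + base::matrix(noise, nrow = n)
    dimnames(values) <- list(names(targets), samples)
    list(values = values, groups = groups, targets = targets)
  }
  list(transcript = build(tg$transcript), protein = build(tg$protein))
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Random sets of uniform random sizes plus one planted set lying inside
#' the planted concordant-up genes, which therefore carries positive shifts
#' at both omic levels and should attain a positive NES in both enrichment
#' analyses when the shifts dominate the noise.
#'
#' @param truth a [synthetic_truth()] object.
#' @param n_sets number of random background sets (default 25; 0 gives a
#'   collection holding only the planted set).
#' @param set_size_range inclusive size range of random sets
#'   (default c(10, 60)).
#' @param planted_size size of the planted set (capped at the number of
#'   planted concordant-up genes).
#' @return named list of gene sets; the planted set is named
#'   `"PLANTED_UP_SET"`; attribute `planted_set` records that name.
#' @export
simulate_gene_sets <- function(truth, n_sets = 25L,
                               set_size_range = c(10L, 60L),
                               planted_size = 30L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            set_size_range[2L] <= truth$n_genes)
  set.seed(derive_seed(truth$seed, "sets"))
  sets <- list()
  if (n_sets > 0L) {
    sizes <- sample(seq(set_size_range[1L], set_size_range[2L]),
                    n_sets, replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(truth$universe, sz))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
  }
  planted_size <- min(planted_size, length(truth$planted_concordant_up))
  sets[["PLANTED_UP_SET"]] <- truth$planted_concordant_up[
    seq_len(planted_size)]
  attr(sets, "planted_set") <- "PLANTED_UP_SET"
  attr(sets, "source") <- "synthetic"
  sets
}

#' Simulate plasma-proteome and drug-interaction reference tables
#'
#' The plasma reference holds the flagged planted discordant genes plus
#' out-of-universe decoy identifiers up to the nominal source size -- as in
#' a real plasma catalogue, most members are absent from the analysed gene
#' universe, so the overlap with the top discordant genes recovers exactly
#' the planted members. The drug table links a configured fraction of the
#' planted concordant-up genes to one or more approved pseudo-drugs, adds
#' approved interactions for a few background genes (stage-1-only hits)
#' and some non-approved rows exercising the approval filter.
#'
#' @param truth a [synthetic_truth()] object.
#' @return list with `plasma` (a [reference_set()]) and `drugs` (a
#'   drug-interaction data frame: `gene_id`, `drug_name`, `approved`).
#' @export
simulate_reference_sets <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(truth$seed, "reference"))
  n_decoy <- truth$plasma_source_size - length(truth$plasma_planted)
  plasma <- reference_set(
    "synthetic_plasma",
    c(truth$plasma_planted,
      if (n_decoy > 0L) sprintf("plasma_only_%04d", seq_len(n_decoy))),
    source_size = truth$plasma_source_size)

  up <- truth$planted_concordant_up
  n_drugged <- round(truth$drug_fraction * length(up))
  drugged <- if (n_drugged > 0L) sort(sample(up, n_drugged)) else character()
  background <- setdiff(truth$universe,
                        c(up, truth$planted_concordant_down,
                          truth$planted_discordant))
  extra <- sort(sample(background, min(15L, length(background))))
  rows <- list()
  drug_pool <- sprintf("drug_%03d", seq_len(200L))
  add_rows <- function(genes, approved) {
    lapply(genes, function(g) {
      data.frame(gene_id = g,
                 drug_name = sample(drug_pool, sample(1:3, 1L)),
                 approved = approved, stringsAsFactors = FALSE)
    })
  }
  rows <- c(add_rows(drugged, TRUE), add_rows(extra, TRUE),
            add_rows(sort(sample(background, 5L)), FALSE))
  drugs <- do.call(rbind, rows)
  drugs <- drugs[!duplicated(drugs[, c("gene_id", "drug_name")]), ,
                 drop = FALSE]
  rownames(drugs) <- NULL
  list(plasma = plasma, drugs = drugs)
}

#' Write a complete synthetic study to disk
#'
#' Materialises every input the pipeline consumes: fold-change tables,
#' mapping tables, expression matrices with group assignments, a GMT
#' gene-set collection, plasma and drug reference tables, and a
#' `truth.json` record of the generative parameters and planted labels.
#'
#' @param truth a [synthetic_truth()] object.
#' @param out_dir output directory (created if absent).
#' @param n_a,n_b,noise_sd passed to [simulate_expression_matrices()].
#' @param n_sets,set_size_range,planted_size passed to
#'   [simulate_gene_sets()].
#' @return named character vector of written file paths, invisibly.
#' @export
simulate_study <- function(truth, out_dir, n_a = 6L, n_b = 8L,
                           noise_sd = 0.5, n_sets = 25L,
                           set_size_range = c(10L, 60L),
                           planted_size = 30L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lfc <- simulate_paired_lfc(truth)
  expr <- simulate_expression_matrices(truth, n_a, n_b, noise_sd)
  sets <- simulate_gene_sets(truth, n_sets, set_size_range, planted_size)
  refs <- simulate_reference_sets(truth)
  p <- function(f) file.path(out_dir, f)

  write_tsv_stable(lfc$transcripts, p("transcripts.tsv"))
  write_tsv_stable(lfc$proteins, p("proteins.tsv"))
  write_tsv_stable(lfc$mapping_transcript, p("mapping_transcript.tsv"))
  write_tsv_stable(lfc$mapping_protein, p("mapping_protein.tsv"))
  for (lvl in c("transcript", "protein")) {
    m <- expr[[lvl]]$values
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_stable(df, p(sprintf("expr_%s.tsv", lvl)))
    write_tsv_stable(
      data.frame(sample = names(expr[[lvl]]$groups),
                 group = unname(expr[[lvl]]$groups),
                 stringsAsFactors = FALSE),
      p(sprintf("groups_%s.tsv", lvl)))
  }
  write_gmt(sets, p("sets.gmt"))
  write_tsv_stable(data.frame(gene_id = refs$plasma$members,
                              stringsAsFactors = FALSE), p("plasma.tsv"))
  write_tsv_stable(refs$drugs, p("dgidb.tsv"))
  jsonlite::write_json(
    list(parameters = unclass(truth)[c("n_genes", "rho", "mean_t", "mean_p",
                                       "scale_t", "scale_p", "effect_t",
                                       "effect_p", "plasma_source_size",
                                       "drug_fraction", "seed")],
         planted_concordant_up = truth$planted_concordant_up,
         planted_concordant_down = truth$planted_concordant_down,
         planted_discordant = truth$planted_discordant,
         plasma_planted = truth$plasma_planted,
         planted_set = attr(sets, "planted_set")),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- c(transcripts = p("transcripts.tsv"), proteins = p("proteins.tsv"),
             mapping_transcript = p("mapping_transcript.tsv"),
             mapping_protein = p("mapping_protein.tsv"),
             expr_transcript = p("expr_transcript.tsv"),
             expr_protein = p("expr_protein.tsv"),
             groups_transcript = p("groups_transcript.tsv"),
             groups_protein = p("groups_protein.tsv"),
             sets = p("sets.gmt"), plasma = p("plasma.tsv"),
             drugs = p("dgidb.tsv"), truth = p("truth.json"))
  invisible(files)
}
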