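#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default:
#' duplicate collapse `max_abs`, midrank ties, top-10 reporting lists,
#' top-100 discordant selection for the plasma overlap, per-level FDR
#' threshold 0.2, 1000 permutations, running-sum weight 1, minimum set
#' size 5. Any entry can be overridden via a YAML file
#' ([read_run_config()]) or by editing the list.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    transcripts = NULL, proteins = NULL,
    mapping_transcript = NULL, mapping_protein = NULL,
    fallback_transcript = NULL, fallback_protein = NULL,
    gene_sets = NULL, plasma = NULL, drugs = NULL,
    out_dir = NULL,
    collapse = "max_abs", ties = "midrank",
    top_k_report = 10L, top_k_plasma = 100L,
    fdr_threshold = 0.2, n_perm = 1000L, weight = 1,
    min_set_size = 5L, blocklist = NULL,
    plasma_source_size = NULL,
    seed = 1L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Starts from [default_config()] and overrides any key present in the
#' file. Relative input paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  base <- dirname(normalizePath(path))
  path_keys <- c("transcripts", "proteins", "mapping_transcript",
                 "mapping_protein", "fallback_transcript",
                 "fallback_protein", "gene_sets", "plasma", "drugs",
                 "out_dir")
  for (k in path_keys) {
    v <- cfg[[k]]
    if (!is.null(v) && !grepl("^(/|[A-Za-z]:)", v)) {
      cfg[[k]] <- file.path(base, v)
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$top_k_report >= 1L, cfg$top_k_plasma >= 1L,
            cfg$n_perm >= 1L, cfg$weight >= 0)
  for (k in c("transcripts", "proteins", "out_dir")) {
    if (is.null(cfg[[k]])) stop("config is missing required entry: ", k,
                                call. = FALSE)
  }
  cfg
}

#' Plot-ready scatter table with highlight classes
#'
#' One row per gene with `x = lfc_transcript`, `y = lfc_protein` and a
#' highlight class assigned from the supplied top-k selections. Classes are
#' mutually exclusive; when a gene appears in several selections the first
#' match in the fixed priority order `concordant_up`, `concordant_down`,
#' `discordant_hi`, `discordant_lo` wins, everything else is `background`.
#'
#' @param table output of [rank_table()].
#' @param highlights named list of data frames (or gene-id vectors) for the
#'   four classes; missing entries mean no highlights of that class.
#' @return data frame `gene_id`, `lfc_transcript`, `lfc_protein`,
#'   `highlight`.
#' @export
export_scatter_data <- function(table,
                                highlights = list(concordant_up = NULL,
                                                  concordant_down = NULL,
                                                  discordant_hi = NULL,
                                                  discordant_lo = NULL)) {
  if (nrow(table) == 0L) stop("empty ranked table", call. = FALSE)
  ids <- function(h) {
    if (is.null(h)) character() else if (is.data.frame(h)) h$gene_id else h
  }
  cls <- rep("background", nrow(table))
  for (nm in c("discordant_lo", "discordant_hi", "concordant_down",
               "concordant_up")) {
    cls[table$gene_id %in% ids(highlights[[nm]])] <- nm
  }
  out <- data.frame(gene_id = table$gene_id,
                    lfc_transcript = table$lfc_transcript,
                    lfc_protein = table$lfc_protein,
                    highlight = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

ingest_level <- function(cfg, level) {
  records <- read_lfc_table(cfg[[paste0(level, "s")]])
  n_dropped <- attr(records, "n_dropped")
  map_path <- cfg[[paste0("mapping_", level)]]
  n_unmapped <- 0L
  if (!is.null(map_path)) {
    mapping <- read_mapping_table(map_path)
    fb_path <- cfg[[paste0("fallback_", level)]]
    fallback <- if (!is.null(fb_path)) read_mapping_table(fb_path) else NULL
    records <- map_to_gene_ids(records, mapping, fallback)
    n_unmapped <- attr(records, "n_unmapped")
  } else {
    records$gene_id <- records$feature_id
  }
  collapsed <- collapse_duplicates(records, cfg$collapse)
  list(collapsed = collapsed, n_dropped = n_dropped,
       n_unmapped = n_unmapped)
}

#' Run the full integration pipeline
#'
#' Executes ingest -> rank -> annotate -> enrich -> report on the inputs
#' named in the configuration and persists every stage artifact under
#' `out_dir`: `ranked_table.tsv`, four top-k tables, `scatter_data.tsv`,
#' `plasma_overlap.tsv` and `drug_targets.tsv` (when references are
#' configured), `enrichment_transcript.tsv` / `enrichment_protein.tsv` /
#' `enrichment_dual.tsv` plus a bubble-plot-ready `enrichment_bubble.tsv`
#' (when a gene-set collection is configured), `manifest.json` (file list
#' with row counts) and `run_log.txt`. All randomness derives from
#' `config$seed`; a failed stage aborts with a stage-named error and a
#' `.partial` marker file next to whatever was already written.
#'
#' @param config configuration list ([default_config()] /
#'   [read_run_config()]) or a YAML path.
#' @param dry_run if `TRUE`, run every stage but write nothing.
#' @return invisibly, a list with `manifest`, `log`, `ranked`,
#'   `correlation`, `top`, `overlap`, `drug`, `enrichment`.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_config(utils::modifyList(default_config(), config))
  out_dir <- cfg$out_dir
  if (!dry_run) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  log_lines <- character()
  note <- function(...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(...)
  }
  emit <- function(df, name) {
    if (!dry_run) write_tsv_stable(df, file.path(out_dir, name))
    written[[name]] <<- nrow(df)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (!dry_run && dir.exists(out_dir)) {
        file.create(file.path(out_dir, ".partial"))
      }
      stop_stage(stage, conditionMessage(e))
    })
  }

  # -- ingest ---------------------------------------------------------------
  integrated <- run_stage("ingest", {
    t_in <- ingest_level(cfg, "transcript")
    p_in <- ingest_level(cfg, "protein")
    note("transcripts: %d genes after collapse (%d rows dropped, %d unmapped)",
         nrow(t_in$collapsed), t_in$n_dropped, t_in$n_unmapped)
    note("proteins: %d genes after collapse (%d rows dropped, %d unmapped)",
         nrow(p_in$collapsed), p_in$n_dropped, p_in$n_unmapped)
    shared <- intersect_levels(t_in$collapsed, p_in$collapsed)
    note("intersection: %d genes shared across levels", nrow(shared))
    shared
  })

  # -- rank -----------------------------------------------------------------
  rank_out <- run_stage("rank", {
    ranked <- rank_table(integrated, cfg$ties)
    corr <- lfc_correlation(ranked)
    note("Pearson r = %.4f (p = %.3g, n = %d)", corr$r, corr$p_value, corr$n)
    k <- min(cfg$top_k_report, nrow(ranked))
    top <- list(
      concordant_up = top_k(ranked, k, "concordant_up"),
      concordant_down = top_k(ranked, k, "concordant_down"),
      discordant_hi = top_k(ranked, k, "discordant_protein_up"),
      discordant_lo = top_k(ranked, k, "discordant_protein_down")
    )
    emit(ranked, "ranked_table.tsv")
    for (nm in names(top)) {
      emit(top[[nm]], sprintf("top_%s.tsv", nm))
    }
    emit(export_scatter_data(ranked, top), "scatter_data.tsv")
    list(ranked = ranked, corr = corr, top = top)
  })
  ranked <- rank_out$ranked

  # -- annotate -------------------------------------------------------------
  annot <- run_stage("annotate", {
    overlap <- NULL
    drug <- NULL
    if (!is.null(cfg$plasma)) {
      plasma <- read_reference_set(cfg$plasma, "plasma",
                                   cfg$plasma_source_size)
      k <- min(cfg$top_k_plasma, nrow(ranked))
      top_disc <- top_k(ranked, k, "discordant_protein_up")
      overlap <- plasma_overlap(top_disc, plasma)
      note("plasma overlap: %d of top-%d discordant genes in reference",
           overlap$hit_count, overlap$query_size)
      emit(overlap$hits, "plasma_overlap.tsv")
    }
    if (!is.null(cfg$drugs)) {
      interactions <- read_drug_table(cfg$drugs)
      drug <- drug_target_filter(ranked, interactions)
      note("drug targets: %d genes with approved interactions, %d concordantly up",
           drug$stage1_count, drug$stage2_count)
      emit(drug$targets, "drug_targets.tsv")
    }
    list(overlap = overlap, drug = drug)
  })

  # -- enrich ---------------------------------------------------------------
  enrich <- run_stage("enrich", {
    if (is.null(cfg$gene_sets)) return(NULL)
    sets <- read_gmt(cfg$gene_sets)
    if (length(sets) == 0L) {
      note("enrichment: empty collection, stage skipped")
      return(NULL)
    }
    scores_t <- stats::setNames(ranked$lfc_transcript, ranked$gene_id)
    scores_p <- stats::setNames(ranked$lfc_protein, ranked$gene_id)
    res_t <- run_preranked_gsea(
      scores_t, sets, n_perm = cfg$n_perm, weight = cfg$weight,
      seed = derive_seed(cfg$seed, "enrich_transcript"),
      min_size = cfg$min_set_size, blocklist = cfg$blocklist)
    res_p <- run_preranked_gsea(
      scores_p, sets, n_perm = cfg$n_perm, weight = cfg$weight,
      seed = derive_seed(cfg$seed, "enrich_protein"),
      min_size = cfg$min_set_size, blocklist = cfg$blocklist)
    dual <- dual_level_combine(res_t, res_p, cfg$fdr_threshold)
    note("enrichment: %d sets tested, %d pass dual FDR < %.2g (combined < %.2g)",
         nrow(dual), sum(dual$passes_dual_fdr), cfg$fdr_threshold,
         attr(dual, "combined_threshold"))
    emit(res_t, "enrichment_transcript.tsv")
    emit(res_p, "enrichment_protein.tsv")
    emit(dual, "enrichment_dual.tsv")
    bubble <- merge(dual, res_t[, c("set_name", "size_in_universe")],
                    by = "set_name", sort = TRUE)
    emit(bubble[, c("set_name", "size_in_universe", "nes_transcript",
                    "nes_protein", "combined_nes", "passes_dual_fdr")],
         "enrichment_bubble.tsv")
    list(transcript = res_t, protein = res_p, dual = dual)
  })

  # -- report ---------------------------------------------------------------
  manifest <- run_stage("report", {
    man <- list(files = lapply(names(written), function(nm) {
      list(file = nm, rows = written[[nm]])
    }), seed = cfg$seed)
    if (!dry_run) {
      jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      partial <- file.path(out_dir, ".partial")
      if (file.exists(partial)) file.remove(partial)
    }
    man
  })

  invisible(list(manifest = manifest, log = log_lines, ranked = ranked,
                 correlation = rank_out$corr, top = rank_out$top,
                 overlap = annot$overlap, drug = annot$drug,
                 enrichment = enrich))
}
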