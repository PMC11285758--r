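#' Default analysis thresholds
#'
#' The single block of tunable thresholds used across the pipeline: scanner
#' p-value `t`, window bounds `m`/`M`, the strict purity cut for
#' selection-overlap analyses (`> 0.7`), the strict PSS posterior cut
#' (`> 0.95`), the omega cap (2), bin counts (20 for amino-acid positional
#' profiles, 10 for the PSS/LCR co-distribution), the over/under abundance
#' thresholds (8% / 2%) and the significance level (0.05).
#'
#' @return Named list of thresholds.
#' @export
lcr_defaults <- function() {
  list(
    t = 0.001, m = 5, M = 500, min_purity = 0.7, posterior = 0.95,
    omega_cap = 2, bins_lcr = 20, bins_pss = 10, over = 0.08, under = 0.02,
    alpha = 0.05, min_species = 3
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML path")
  config$thresholds <- modifyList(lcr_defaults(),
                                  config$thresholds %||% list())
  if (is.null(config$simulate) && is.null(config$inputs)) {
    abort("config error at 'simulate'/'inputs': one of the two is required")
  }
  if (!is.null(config$simulate) && is.null(config$simulate$seed) &&
      is.null(config$seed)) {
    abort("config error at 'seed': a seed is required for simulation")
  }
  config
}

#' Run the full LCR analysis pipeline
#'
#' Executes every stage in dependency order — data (simulation or TSV
#' input), LCR scan, ORF and clade filters, alignment mapping and
#' orthologous grouping, positional and purity profiles, diversity
#' statistics, and selection integration — writing per-stage TSVs, a JSON
#' report and a run manifest with file hashes to `out_dir`. Stages are
#' deterministic given the config (simulation draws all randomness from the
#' config seed), so re-running with the same config reproduces identical
#' output hashes.
#'
#' A stage failure is recorded and all downstream stages are marked
#' `skipped`; the manifest's `status` field then reports `failed`.
#'
#' @param config Config list or path to a YAML file. Top-level fields:
#'   `simulate` (arguments to [simulation_config()]) or `inputs` (paths to
#'   `genes` / `alignments` / `pss` / `omega` TSVs), optional `thresholds`
#'   overriding [lcr_defaults()], optional `seed`.
#' @param out_dir Output directory (created if needed).
#'
#' @return The run manifest, invisibly. `manifest$status` is `"ok"` or
#'   `"failed"`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  th <- config$thresholds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("data", "scan", "orf_filter", "map", "profile", "diversity",
              "selection", "report")
  status <- setNames(rep("pending", length(stages)), stages)
  outputs <- list()
  env <- new.env()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste0("error: ", conditionMessage(res))
      failed <<- TRUE
    } else {
      status[[name]] <<- "ok"
      outputs[[name]] <<- res
    }
    invisible(NULL)
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(df, path)
    path
  }

  run_stage("data", function() {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      cfg <- do.call(simulation_config, args)
      sim <- simulate_dataset(cfg)
      env$genes <- sim$genes
      env$alignments <- sim$alignments
      env$pss_raw <- sim$pss
      env$omega_raw <- sim$omega
      writeLines(sim$tree, file.path(out_dir, "trees.nwk"))
      c(emit(sim$genes, "genes.tsv"), emit(sim$alignments, "alignments.tsv"),
        emit(sim$pss, "pss_raw.tsv"), emit(sim$omega, "omega_raw.tsv"),
        file.path(out_dir, "trees.nwk"))
    } else {
      inp <- config$inputs
      for (f in c("genes", "alignments", "pss", "omega")) {
        if (is.null(inp[[f]])) {
          abort(paste0("missing input file for stage data: '", f, "'"))
        }
        if (!file.exists(inp[[f]])) {
          abort(paste0("missing input file for stage data: ", inp[[f]]))
        }
      }
      env$genes <- readr::read_tsv(inp$genes, show_col_types = FALSE)
      env$alignments <- readr::read_tsv(inp$alignments,
                                        show_col_types = FALSE)
      env$pss_raw <- readr::read_tsv(inp$pss, show_col_types = FALSE)
      env$omega_raw <- readr::read_tsv(inp$omega, show_col_types = FALSE)
      character(0)
    }
  })

  run_stage("scan", function() {
    lcrs <- env$genes %>%
      dplyr::group_split(.data$clade_id) %>%
      purrr::map(~ scan_lcrs(.x, t = th$t, m = th$m, M = th$M) %>%
                   left_join(distinct(.x, .data$gene_id, .data$species_id,
                                      .data$clade_id),
                             by = c("gene_id", "species_id"))) %>%
      bind_rows()
    env$lcrs <- lcrs
    emit(add_one_based(lcrs), "lcrs.tsv")
  })

  run_stage("orf_filter", function() {
    orf <- check_orf(env$genes$cds)
    kept <- env$genes[orf$pass, , drop = FALSE]
    filtered <- filter_clade_genes(kept, min_species = th$min_species)
    rep <- clade_filter_report(filtered)
    env$genes_kept <- filtered
    env$lcrs_kept <- semi_join(env$lcrs, filtered,
                               by = c("gene_id", "species_id"))
    env$alignments_kept <- semi_join(env$alignments, filtered,
                                     by = c("gene_id", "species_id"))
    env$orf_report <- tibble(
      gene_id = env$genes$gene_id, species_id = env$genes$species_id,
      pass = orf$pass, reason = orf$reason
    )
    c(emit(env$orf_report, "orf_report.tsv"),
      emit(rep$removed %||% tibble(), "clade_filter_removed.tsv"))
  })

  run_stage("map", function() {
    aligned <- map_to_alignment(env$lcrs_kept, env$alignments_kept)
    grouped <- group_orthologous(aligned)
    env$aligned_lcrs <- grouped
    env$coverage <- alignment_coverage(env$alignments_kept)
    c(emit(grouped, "aligned_lcrs.tsv"),
      emit(env$coverage, "alignment_coverage.tsv"))
  })

  run_stage("profile", function() {
    genes_meta <- env$genes_kept %>%
      mutate(protein_length = nchar(.data$protein)) %>%
      distinct(.data$gene_id, .data$clade_id, .data$species_id,
               .data$protein_length)
    lcr_pos <- env$lcrs_kept %>%
      inner_join(genes_meta,
                 by = c("gene_id", "species_id", "clade_id")) %>%
      mutate(midpoint = normalized_midpoint(.data$start0, .data$end0,
                                            .data$protein_length))
    env$lcr_pos <- lcr_pos
    residue_profiles <- lcr_pos %>%
      filter(.data$purity > th$min_purity) %>%
      group_by(.data$primary_residue) %>%
      group_modify(~ call_abundance(
        bin_positions(.x$midpoint, th$bins_lcr),
        over_threshold = th$over, under_threshold = th$under
      )) %>%
      ungroup()
    env$residue_profiles <- residue_profiles
    gradient <- purity_gradient_profile(env$lcrs_kept, env$genes_kept)
    env$gradient <- gradient
    classes <- lcr_pos %>%
      group_by(.data$gene_id, .data$clade_id) %>%
      summarise(class = classify_gene_position(.data$midpoint),
                .groups = "drop")
    env$gene_classes <- classes
    c(emit(residue_profiles, "residue_position_profiles.tsv"),
      emit(gradient, "purity_gradient.tsv"),
      emit(classes, "gene_position_classes.tsv"))
  })

  run_stage("diversity", function() {
    by_species <- env$lcrs_kept %>%
      group_by(.data$clade_id) %>%
      group_modify(~ diversity_by_unit(.x, unit = "species_id")) %>%
      ungroup()
    topk <- env$lcrs_kept %>%
      group_by(.data$clade_id) %>%
      group_modify(~ top_k_proportions(.x$signature, k = 20)) %>%
      ungroup()
    env$diversity <- by_species
    env$topk <- topk
    accum <- env$lcrs_kept %>%
      group_by(.data$clade_id) %>%
      group_modify(function(d, key) {
        if (nrow(d) < 2) return(tibble(slope = NA_real_))
        a <- accumulation_curve(d$signature,
                                seed = (config$seed %||% 1) + 17)
        tibble(slope = a$slope, model = a$model, n_lcrs = a$n)
      }) %>%
      ungroup()
    env$accum <- accum
    c(emit(by_species, "diversity_by_species.tsv"),
      emit(topk, "top20_lcr_types.tsv"),
      emit(accum, "accumulation_slopes.tsv"))
  })

  run_stage("selection", function() {
    pss <- load_pss(env$pss_raw, threshold = th$posterior) %>%
      semi_join(distinct(env$genes_kept, .data$gene_id), by = "gene_id")
    n_col <- env$alignments_kept %>%
      distinct(.data$gene_id, .data$clade_id, .data$aligned_cds) %>%
      group_by(.data$gene_id, .data$clade_id) %>%
      summarise(n_col = as.integer(nchar(.data$aligned_cds[1]) / 3),
                .groups = "drop")
    pure <- env$aligned_lcrs %>% filter(.data$purity > th$min_purity)
    overlap <- three_level_overlap(pure, pss, n_col, alpha = th$alpha)
    lcr_genes <- unique(pure$gene_id)
    omega_cmp <- omega_group_compare(env$omega_raw, lcr_genes,
                                     cap = th$omega_cap)
    gene_cds <- env$genes_kept %>%
      group_by(.data$gene_id, .data$clade_id) %>%
      summarise(cds = .data$cds[1], .groups = "drop")
    gc_cmp <- gc_group_compare(gene_cds, lcr_genes)
    env$overlap <- overlap
    env$omega_cmp <- omega_cmp
    env$gc_cmp <- gc_cmp
    c(emit(overlap, "overlap_results.tsv"),
      emit(omega_cmp, "omega_comparison.tsv"),
      emit(gc_cmp, "gc_comparison.tsv"))
  })

  run_stage("report", function() {
    genes_per_clade <- env$genes_kept %>%
      distinct(.data$clade_id, .data$gene_id) %>%
      count(.data$clade_id, name = "n_genes")
    lcr_frac <- env$lcrs_kept %>%
      distinct(.data$clade_id, .data$gene_id) %>%
      count(.data$clade_id, name = "n_lcr_genes") %>%
      left_join(genes_per_clade, by = "clade_id") %>%
      mutate(prop_genes_with_lcr = .data$n_lcr_genes / .data$n_genes)
    report <- list(
      n_genes = nrow(distinct(env$genes_kept, .data$gene_id)),
      n_lcrs = nrow(env$lcrs_kept),
      prop_genes_with_lcr = lcr_frac,
      diversity = env$diversity,
      accumulation = env$accum,
      overlap_summary = env$overlap %>%
        group_by(.data$level, .data$direction, .data$significant) %>%
        summarise(n = n(), .groups = "drop"),
      omega_comparison = env$omega_cmp,
      gc_comparison = env$gc_cmp
    )
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  })

  all_files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    tool = "lcrscan",
    version = as.character(utils::packageVersion("lcrscan")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed %||% config$simulate$seed,
    config = config[setdiff(names(config), "out_dir")],
    stages = purrr::imap(as.list(status), function(st, nm) {
      list(status = st,
           outputs = as.list(tools::md5sum(outputs[[nm]] %||% character(0))))
    }),
    status = if (failed) "failed" else "ok"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (failed) {
    warn(paste0("pipeline failed at stage: ",
                names(status)[grepl("^error", status)][1]))
  }
  invisible(manifest)
}
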