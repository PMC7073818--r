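# End-to-end orchestration: simulate -> build-db -> map-peptides ->
# fit-kloss -> assemble -> correlate -> enrich -> call-switches, driven by
# one configuration (YAML/JSON file or list), with a JSON manifest recording
# per-stage parameters, outputs, hashes and row counts. Every
# filter-exclusion count is logged: those counts are the primary debugging
# surface of the pipeline.

#' Load a pipeline configuration
#'
#' @param config A named list, or the path of a YAML or JSON file.
#' @return The validated configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a file path")
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% stop_config("config needs out_dir")
  config$log_level <- config$log_level %||% "info"
  if (is.null(config$simulate)) {
    for (f in c("transcripts", "expression", "precursors")) {
      p <- config$inputs[[f]]
      if (is.null(p)) stop_config("config needs inputs$", f,
                                  " when no simulate block is given")
      if (!file.exists(p)) stop_config("input file not found: ", p)
    }
    if (is.null(config$condition_labels))
      stop_config("config needs condition_labels when no simulate block is given")
  }
  config
}

#' @noRd
pk_log <- function(config, stage, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' @noRd
log_exclusions <- function(config, stage, exclusions, what = "reason") {
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    pk_log(config, stage, "no records excluded")
    return(invisible())
  }
  tab <- table(exclusions[[what]])
  for (r in names(tab))
    pk_log(config, stage, sprintf("excluded %d record(s): %s", tab[[r]], r))
}

#' @noRd
manifest_entry <- function(stage, params, outputs, n_rows, elapsed) {
  list(stage = stage, params = params,
       outputs = lapply(outputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       n_rows = n_rows, elapsed_s = round(elapsed, 3), status = "ok")
}

#' @noRd
stage_done <- function(manifest, stage, out_dir) {
  prev <- Filter(function(e) identical(e$stage, stage), manifest)
  if (length(prev) == 0) return(FALSE)
  all(vapply(prev[[1]]$outputs, function(o)
    file.exists(o$path) && identical(unname(tools::md5sum(o$path)), o$md5),
    TRUE))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; each writes its TSV outputs under
#' `config$out_dir` and appends a manifest entry (parameters, output hashes,
#' row counts). A failing stage aborts with the stage named. With
#' `resume = TRUE`, stages whose manifest entry and output hashes are intact
#' are skipped.
#'
#' @param config A configuration list or YAML/JSON path (see
#'   [pipeline_config()]). Must contain `out_dir` and `seed`; either a
#'   `simulate` block ([sim_config()] fields) or `inputs` paths
#'   (`transcripts`, `expression`, `precursors`, optionally `annotations`)
#'   plus `condition_labels`. Optional per-module blocks: `db_filter`,
#'   `digest`, `turnover` (plus `turnover$method`), `assembly`, `switch`,
#'   `enrichment`.
#' @param resume Skip stages already completed with intact outputs.
#' @return Invisibly, a list with the `manifest` and key in-memory results
#'   (`omics`, `correlations`, `events`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  seed <- config$seed
  results <- list()

  run_stage <- function(stage, fun) {
    if (resume && stage_done(manifest, stage, config$out_dir)) {
      pk_log(config, stage, "skipped (resume: outputs intact)")
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    entry <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    entry$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest <<- c(Filter(function(e) !identical(e$stage, stage), manifest),
                   list(entry))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  out <- function(name) file.path(config$out_dir, name)

  ## 1. simulate -------------------------------------------------------------
  run_stage("simulate", function() {
    if (is.null(config$simulate)) {
      results$transcripts <<- read_transcripts(config$inputs$transcripts)
      results$expression <<- read_expression_matrix(config$inputs$expression)
      results$precursors <<- read_precursor_table(config$inputs$precursors)
      results$condition <<- unlist(config$condition_labels)
      pk_log(config, "simulate", "external inputs loaded, nothing simulated")
      return(manifest_entry("simulate", list(source = "external"),
                            character(0),
                            list(precursors = nrow(results$precursors)), 0))
    }
    scfg <- do.call(sim_config, c(config$simulate,
                                  list(seed = derive_seed(seed, 1L))))
    sim <- simulate_transcriptome(scfg)
    sim$truth <- plant_buffering(sim$truth, scfg)
    ps <- simulate_psilac(sim$truth, scfg)
    results$transcripts <<- sim$transcripts
    results$expression <<- sim$expression
    results$precursors <<- ps$precursors
    results$condition <<- sim$truth$condition
    results$truth <<- sim$truth
    files <- c(out("transcripts.tsv"), out("expression.tsv"),
               out("precursors.tsv"))
    write_transcripts(sim$transcripts, files[1], seed = scfg$seed)
    write_expression_matrix(sim$expression, files[2], seed = scfg$seed)
    write_precursor_table(ps$precursors, files[3], seed = scfg$seed)
    pk_log(config, "simulate", sprintf("%d genes, %d precursor rows",
                                       scfg$n_genes, nrow(ps$precursors)))
    manifest_entry("simulate", config$simulate %||% list(), files,
                   list(precursors = nrow(ps$precursors)), 0)
  })

  ## 2. build-db --------------------------------------------------------------
  run_stage("build_db", function() {
    dcfg <- do.call(db_filter_config, config$db_filter %||% list())
    db <- build_filtered_db(results$transcripts, results$expression, dcfg)
    results$db <<- db$db
    files <- c(out("db.fasta"), out("db_report.tsv"))
    write_fasta(db$db, files[1])
    write_pk_tsv(db$report, files[2], command = "build-db", seed = seed)
    pk_log(config, "build_db",
           sprintf("%d of %d transcripts included", nrow(db$db),
                   nrow(db$report)))
    log_exclusions(config, "build_db",
                   db$report[!db$report$included, , drop = FALSE])
    manifest_entry("build_db", unclass(dcfg), files,
                   list(included = nrow(db$db)), 0)
  })

  ## 3. map-peptides ----------------------------------------------------------
  run_stage("map_peptides", function() {
    gcfg <- do.call(digest_config, config$digest %||% list())
    pmap <- digest_db(results$db, gcfg)
    assignments <- classify_peptides(pmap, results$transcripts)
    groups <- assemble_as_groups(assignments, results$expression)
    results$assignments <<- assignments
    results$groups <<- groups
    files <- c(out("peptide_assignments.tsv"), out("as_groups.tsv"))
    write_pk_tsv(assignments, files[1], command = "map-peptides", seed = seed)
    write_pk_tsv(groups, files[2], command = "map-peptides", seed = seed)
    pk_log(config, "map_peptides",
           sprintf("%d peptides (%d multi-gene excluded), %d AS groups",
                   nrow(assignments),
                   sum(assignments$class == "multi_gene"), nrow(groups)))
    manifest_entry("map_peptides", unclass(gcfg), files,
                   list(peptides = nrow(assignments), groups = nrow(groups)), 0)
  })

  ## 4. fit-kloss ------------------------------------------------------------
  run_stage("fit_kloss", function() {
    tcfg <- do.call(turnover_config,
                    config$turnover[setdiff(names(config$turnover %||% list()),
                                            "method")] %||% list())
    method <- config$turnover$method %||% "RIA"
    fit <- fit_kloss(results$precursors, tcfg, method = method)
    log_exclusions(config, "fit_kloss", fit$exclusions)
    agg <- aggregate_kloss(fit$estimates, peptide_group_map(results$groups),
                           tcfg)
    log_exclusions(config, "fit_kloss", agg$exclusions)
    results$kloss <<- agg
    files <- c(out("precursor_kloss.tsv"), out("peptide_kloss.tsv"),
               out("group_kloss.tsv"))
    write_pk_tsv(fit$estimates, files[1], command = "fit-kloss", seed = seed)
    write_pk_tsv(agg$peptide, files[2], command = "fit-kloss", seed = seed)
    write_pk_tsv(agg$group, files[3], command = "fit-kloss", seed = seed)
    pk_log(config, "fit_kloss",
           sprintf("%s: %d precursor fits, %d full-profile peptides, %d groups",
                   method, nrow(fit$estimates), length(agg$full_peptides),
                   length(unique(agg$group$group_id))))
    manifest_entry("fit_kloss", list(method = method), files,
                   list(precursors = nrow(fit$estimates),
                        groups = length(unique(agg$group$group_id))), 0)
  })

  ## 5. assemble ---------------------------------------------------------------
  run_stage("assemble", function() {
    acfg <- do.call(assembly_config, config$assembly %||% list())
    pint <- peptide_intensity_table(results$precursors)
    prot <- assemble_protein_matrix(pint, peptide_group_map(results$groups),
                                    acfg)
    log_exclusions(config, "assemble", prot$exclusions)
    om <- join_omics(prot$matrix, results$kloss$group, results$expression,
                     results$groups)
    results$omics <<- om
    files <- c(out("protein_matrix.tsv"), out("omics_long.tsv"))
    write_pk_tsv(data.frame(group_id = rownames(prot$matrix), prot$matrix,
                            check.names = FALSE), files[1],
                 command = "assemble", seed = seed)
    write_pk_tsv(omics_long(om), files[2], command = "assemble", seed = seed)
    pk_log(config, "assemble",
           sprintf("%d groups joined, %d correlation-ready",
                   nrow(om$rows), nrow(correlation_ready(om)$rows)))
    manifest_entry("assemble", unclass(acfg), files,
                   list(groups = nrow(om$rows)), 0)
  })

  ## 6. correlate --------------------------------------------------------------
  run_stage("correlate", function() {
    per <- do.call(rbind, lapply(OMICS_PAIRS, function(p)
      per_group_correlation(results$omics, p)))
    absres <- lapply(OMICS_PAIRS, function(p) {
      r <- absolute_correlation(results$omics, p)
      data.frame(pair = p, kind = "absolute", rho = r$rho, p = r$p, n = r$n)
    })
    relres <- lapply(OMICS_PAIRS, function(p) {
      r <- relative_correlation(results$omics, results$condition, p)
      data.frame(pair = p, kind = "relative", rho = r$rho, p = r$p, n = r$n)
    })
    summary <- do.call(rbind, c(absres, relres))
    results$correlations <<- per
    files <- c(out("group_correlations.tsv"), out("correlation_summary.tsv"))
    write_pk_tsv(per, files[1], command = "correlate", seed = seed)
    write_pk_tsv(summary, files[2], command = "correlate", seed = seed)
    n12 <- sum(per$pair == "mRNA_kloss" & !is.na(per$rho))
    pk_log(config, "correlate",
           sprintf("%d mRNA-k_loss group correlations (critical |rho| %.3f at n=%d)",
                   n12, critical_rho(ncol(results$omics$log2_protein)),
                   ncol(results$omics$log2_protein)))
    manifest_entry("correlate", list(), files,
                   list(group_correlations = nrow(per)), 0)
  })

  ## 7. enrich -----------------------------------------------------------------
  run_stage("enrich", function() {
    ecfg <- config$enrichment %||% list()
    min_members <- ecfg$min_members %||% 10L
    anns <- if (!is.null(config$inputs$annotations)) {
      read_annotations(config$inputs$annotations)
    } else {
      # synthetic demo terms: random gene sets, seeded from the global seed
      set.seed(derive_seed(seed, 7L))
      keys <- results$omics$rows$group_id
      n_terms <- ecfg$n_demo_terms %||% 20L
      stats::setNames(lapply(seq_len(n_terms), function(i)
        sample(keys, min(length(keys),
                         max(min_members, stats::rpois(1, 2 * min_members))))),
        sprintf("DEMO_TERM_%02d", seq_len(n_terms)))
    }
    rho <- results$correlations
    rho <- rho[rho$pair == "mRNA_kloss", ]
    scores <- stats::setNames(rho$rho, rho$group_id)
    res <- enrich_1d(scores, anns, min_members = min_members)
    files <- out("enrichment_1d.tsv")
    write_pk_tsv(res, files, command = "enrich", seed = seed)
    pk_log(config, "enrich", sprintf("%d terms tested", nrow(res)))
    manifest_entry("enrich", list(min_members = min_members), files,
                   list(terms = nrow(res)), 0)
  })

  ## 8. call-switches ----------------------------------------------------------
  run_stage("call_switches", function() {
    scfg <- do.call(switch_config, config$switch %||% list())
    events <- call_switches(results$expression, results$transcripts,
                            results$condition, scfg)
    conds <- sort(unique(results$condition))
    cl <- results$condition[colnames(results$omics$log2_protein)]
    gene_fc <- function(mat) {
      fc <- rowMeans(mat[, cl == conds[1], drop = FALSE], na.rm = TRUE) -
        rowMeans(mat[, cl == conds[2], drop = FALSE], na.rm = TRUE)
      out <- tapply(fc, results$omics$rows$gene_id, mean, na.rm = TRUE)
      out[!is.na(out)]
    }
    cons <- switch_consequences(events,
                                protein_fc = gene_fc(results$omics$log2_protein),
                                kloss_fc = gene_fc(results$omics$log2_kloss))
    results$events <<- events
    files <- c(out("switch_events.tsv"), out("switch_consequences.tsv"))
    write_pk_tsv(events, files[1], command = "call-switches", seed = seed)
    write_pk_tsv(cons$tests, files[2], command = "call-switches", seed = seed)
    pk_log(config, "call_switches", sprintf("%d switch events", nrow(events)))
    manifest_entry("call_switches", unclass(scfg), files,
                   list(events = nrow(events)), 0)
  })

  invisible(list(manifest = manifest,
                 omics = results$omics,
                 correlations = results$correlations,
                 events = results$events,
                 truth = results$truth))
}
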