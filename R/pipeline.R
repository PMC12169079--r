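# End-to-end pipeline: simulate (or read) inputs, run repertoire, zonation,
# spatial statistics and clone calling, and write a report bundle with
# provenance.

#' Pipeline configuration
#'
#' Collects the stage parameters and either simulation parameter objects
#' (`simulate`) or input file paths (`paths`) for a full run. All
#' referenced files must exist at validation time.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global seed; stage seeds are derived from it.
#' @param band_width_um Interface band width for zonation.
#' @param hyper_threshold Hyperexpansion frequency threshold.
#' @param max_edit_distance CDR3 match distance cutoff.
#' @param clone_probes Clone probe feature names.
#' @param eligible_cell_type Cell type eligible for clone calling.
#' @param min_qv Transcript quality cutoff for aggregation.
#' @param fc_threshold,alpha Differential-expression thresholds.
#' @param n_perm Permutations for the zone enrichment test.
#' @param simulate Optional named list of simulation parameter objects:
#'   `repertoire` ([repertoire_sim_params()]), `tissue`
#'   ([tissue_sim_params()]), `cells` ([cell_sim_params()]), `transcripts`
#'   ([transcript_sim_params()]).
#' @param paths Optional named list of input files: `sample_a`, `sample_b`
#'   (clonotype CSVs), `hepatocyte`, `portal`, `sinusoid`, `duct` (mask
#'   TIFFs) with `pixel_size_um`, `cells`, `transcripts` (CSVs),
#'   `reference` (CDR3 reference CSV).
#' @param pixel_size_um Pixel size for masks read from `paths`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, band_width_um = 50,
                            hyper_threshold = 0.01, max_edit_distance = 1L,
                            clone_probes = c("clone1", "clone2", "clone3"),
                            eligible_cell_type = "CD8_T", min_qv = 20,
                            fc_threshold = 0.25, alpha = 0.05,
                            n_perm = 999L,
                            simulate = NULL, paths = NULL,
                            pixel_size_um = NULL) {
  if (is.null(simulate) == is.null(paths)) {
    stopf("provide exactly one of 'simulate' or 'paths'")
  }
  stopifnot(band_width_um > 0, hyper_threshold > 0, hyper_threshold < 1,
            max_edit_distance >= 0, min_qv >= 0, fc_threshold >= 0,
            alpha > 0, alpha < 1, n_perm >= 100)
  if (!is.null(paths)) {
    files <- unlist(paths[vapply(paths, is.character, logical(1))])
    missing <- files[!file.exists(files)]
    if (length(missing)) stopf("input file(s) not found: %s", paste(missing, collapse = ", "))
    if (is.null(pixel_size_um) || pixel_size_um <= 0) {
      stopf("pixel_size_um is required (and positive) when reading masks from paths")
    }
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed),
         band_width_um = band_width_um, hyper_threshold = hyper_threshold,
         max_edit_distance = as.integer(max_edit_distance),
         clone_probes = clone_probes,
         eligible_cell_type = eligible_cell_type, min_qv = min_qv,
         fc_threshold = fc_threshold, alpha = alpha,
         n_perm = as.integer(n_perm),
         simulate = simulate, paths = paths, pixel_size_um = pixel_size_um),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes repertoire analysis, zonation, spatial statistics and clone
#' calling on simulated or file-based inputs, writes a CSV/JSON report
#' bundle plus a provenance record into `config$outdir`, and returns the
#' report objects invisibly. Reruns with an identical configuration are
#' reproducible: all stage seeds derive from the global seed.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a named list with the stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- inputs -------------------------------------------------------------
  manifest <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    rep_pair <- stage("simulate", {
      stopifnot(!is.null(sim$repertoire), !is.null(sim$tissue),
                !is.null(sim$cells), !is.null(sim$transcripts))
      generate_repertoire_pair(sim$repertoire)
    })
    tissue <- stage("simulate", generate_tissue(sim$tissue))
    masks <- tissue$masks
    tab_a <- rep_pair$sample_a
    tab_b <- rep_pair$sample_b
    reference <- spike_reference()
    manifest <- c(rep_pair$manifest, tissue$manifest)
  } else {
    p <- config$paths
    tab_a <- stage("read", read_clonotype_table(p$sample_a))
    tab_b <- stage("read", read_clonotype_table(p$sample_b))
    masks <- stage("read", mask_bundle(
      read_mask(p$hepatocyte), read_mask(p$portal),
      read_mask(p$sinusoid), read_mask(p$duct),
      pixel_size_um = config$pixel_size_um
    ))
    reference <- if (!is.null(p$reference)) read_cdr3_reference(p$reference) else spike_reference()
  }

  # --- repertoire ---------------------------------------------------------
  report$repertoire <- stage("repertoire", {
    sum_a <- call_hyperexpanded(compute_frequencies(tab_a), config$hyper_threshold)
    sum_b <- call_hyperexpanded(compute_frequencies(tab_b), config$hyper_threshold)
    sharing <- compare_samples(sum_a, sum_b)
    hyper_b <- sum_b[sum_b$hyperexpanded, , drop = FALSE]
    matches <- match_cdr3(hyper_b, reference, config$max_edit_distance)
    write_clonotype_table(sum_a, file.path(config$outdir, "repertoire_summary_a.csv"))
    write_clonotype_table(sum_b, file.path(config$outdir, "repertoire_summary_b.csv"))
    jsonlite::write_json(
      list(n_shared = sharing$n_shared, n_unique_a = sharing$n_unique_a,
           n_unique_b = sharing$n_unique_b,
           persistence = sharing$persistence),
      file.path(config$outdir, "sharing.json"), auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(matches, file.path(config$outdir, "cdr3_matches.csv"), row.names = FALSE)
    list(summary_a = sum_a, summary_b = sum_b, sharing = sharing, matches = matches)
  })

  # --- zonation -----------------------------------------------------------
  zone_map <- stage("zonation", build_zone_map(masks, config$band_width_um))
  write_zone_map(zone_map, file.path(config$outdir, "zones.tif"),
                 file.path(config$outdir, "zones.json"))
  report$zone_map <- zone_map

  # --- cells and spatial statistics ---------------------------------------
  if (!is.null(config$simulate)) {
    gen <- stage("simulate", generate_cells(zone_map, config$simulate$cells))
    cells <- gen$cells
    manifest <- c(manifest, gen$manifest)
  } else {
    cells <- stage("read", read_cell_table(config$paths$cells))
  }
  cells <- stage("spatial_stats", assign_zones(cells, zone_map))
  selection <- if (!is.null(cells$true_clone)) !is.na(cells$true_clone) else
    rep(TRUE, nrow(cells))
  report$zone_stats <- stage("spatial_stats", {
    zs <- zone_statistics(cells, zone_map, subset = selection)
    utils::write.csv(zs, file.path(config$outdir, "zone_stats.csv"), row.names = FALSE)
    zs
  })
  if (any(selection) && !all(selection)) {
    report$enrichment <- stage("spatial_stats", {
      en <- zone_enrichment_test(cells, selection, n_perm = config$n_perm,
                                 seed = config$seed)
      utils::write.csv(en, file.path(config$outdir, "zone_enrichment.csv"), row.names = FALSE)
      en
    })
  }

  # --- clone calling -------------------------------------------------------
  if (!is.null(config$simulate)) {
    gtx <- stage("simulate", generate_transcripts(cells, config$simulate$transcripts))
    transcripts <- gtx$transcripts
    manifest <- c(manifest, gtx$manifest)
    write_cell_table(cells, file.path(config$outdir, "cells.csv"))
    write_transcript_table(transcripts, file.path(config$outdir, "transcripts.csv"))
  } else {
    transcripts <- stage("read", read_transcript_table(config$paths$transcripts))
  }
  report$clone_calls <- stage("clone_calling", {
    counts <- aggregate_transcripts(transcripts, cells, min_qv = config$min_qv)
    cfg <- clone_call_config(config$clone_probes,
                             eligible_cell_type = config$eligible_cell_type,
                             min_qv = config$min_qv)
    calls <- call_tcr_positive(cells, counts, cfg)
    bt <- bleedthrough_fraction(transcripts, cells, config$clone_probes,
                                eligible_cell_type = config$eligible_cell_type)
    write_cell_table(calls$cells, file.path(config$outdir, "cell_calls.csv"))
    jsonlite::write_json(
      list(summary = calls$summary,
           eligible_fraction = bt$eligible_fraction,
           outside_eligible_fraction = bt$outside_eligible_fraction,
           unassigned_fraction = bt$unassigned_fraction),
      file.path(config$outdir, "clone_calling.json"), auto_unbox = TRUE, digits = NA
    )
    tcr_pos <- calls$cells$tcr_status == "TCR+"
    eligible <- cells$cell_type == config$eligible_cell_type
    deg <- NULL
    if (sum(tcr_pos) >= 3L && sum(eligible & !tcr_pos) >= 3L) {
      deg <- differential_expression(counts, tcr_pos, eligible & !tcr_pos,
                                     fc_threshold = config$fc_threshold,
                                     alpha = config$alpha,
                                     exclude_from_norm = config$clone_probes)
      utils::write.csv(deg, file.path(config$outdir, "deg.csv"), row.names = FALSE)
    }
    list(counts = counts, calls = calls, bleedthrough = bt, deg = deg)
  })

  # --- provenance ----------------------------------------------------------
  cfg_path <- file.path(config$outdir, "config.json")
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       cfg_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  provenance <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("clonescape")),
    r_version = R.version.string,
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(provenance, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(manifest)) write_manifest(manifest, file.path(config$outdir, "manifest.json"))
  report$provenance <- provenance
  invisible(report)
}
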