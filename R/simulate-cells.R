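# Zone-dependent synthetic cell tables: homogeneous Poisson placement per
# zone and cell type, with clone-labelled CD8 T cells optionally enriched at
# the portal interface and Bernoulli marker-positivity flags.

#' Parameters for synthetic cell placement
#'
#' Cells are placed by a homogeneous Poisson process within each zone.
#' Every cell type uses its base density in every zone; CD8 T cells are
#' split into clone-labelled cells (per-clone fraction of the CD8 density)
#' and unlabelled cells, and the labelled-clone density is multiplied by
#' `pi_enrichment_factor` inside the portal-interface zone.
#'
#' @param base_density_per_mm2 Named numeric vector: cells per mm2 per cell
#'   type (must include `cd8_type` when clones are requested).
#' @param clone_labels Character vector of clone names (may be empty).
#' @param clone_freq_in_cd8 Numeric vector (same length as `clone_labels`):
#'   fraction of the CD8 density belonging to each clone.
#' @param pi_enrichment_factor Multiplier (>= 1) applied to labelled-clone
#'   density in the portal-interface zone.
#' @param marker_positive_prob Optional numeric matrix with markers as rows
#'   and columns `clone` and `other`: probability that a cell is positive
#'   for the marker, by clone-labelled status.
#' @param cd8_type Name of the CD8 T cell type (default `"CD8_T"`).
#' @param seed Integer seed.
#' @return A validated `cell_sim_params` list.
#' @export
cell_sim_params <- function(base_density_per_mm2,
                            clone_labels = character(),
                            clone_freq_in_cd8 = numeric(),
                            pi_enrichment_factor = 1,
                            marker_positive_prob = NULL,
                            cd8_type = "CD8_T",
                            seed = 1L) {
  if (is.null(names(base_density_per_mm2)) || any(!nzchar(names(base_density_per_mm2)))) {
    stopf("base_density_per_mm2 must be a named vector of cell types")
  }
  if (any(base_density_per_mm2 < 0)) stopf("densities must be non-negative")
  if (length(clone_labels) != length(clone_freq_in_cd8)) {
    stopf("clone_labels and clone_freq_in_cd8 must have equal length")
  }
  if (length(clone_labels)) {
    if (!cd8_type %in% names(base_density_per_mm2)) {
      stopf("base_density_per_mm2 lacks the CD8 type '%s'", cd8_type)
    }
    if (any(clone_freq_in_cd8 < 0) || sum(clone_freq_in_cd8) > 1) {
      stopf("clone_freq_in_cd8 must be non-negative and sum to at most 1")
    }
  }
  if (!is_scalar_num(pi_enrichment_factor) || pi_enrichment_factor < 1) {
    stopf("pi_enrichment_factor must be a real >= 1")
  }
  if (!is.null(marker_positive_prob)) {
    marker_positive_prob <- as.matrix(marker_positive_prob)
    if (is.null(rownames(marker_positive_prob)) ||
        !all(c("clone", "other") %in% colnames(marker_positive_prob))) {
      stopf("marker_positive_prob needs marker rownames and columns 'clone' and 'other'")
    }
    if (any(marker_positive_prob < 0 | marker_positive_prob > 1)) {
      stopf("marker probabilities must lie in [0,1]")
    }
  }
  structure(
    list(base_density_per_mm2 = base_density_per_mm2,
         clone_labels = as.character(clone_labels),
         clone_freq_in_cd8 = as.numeric(clone_freq_in_cd8),
         pi_enrichment_factor = pi_enrichment_factor,
         marker_positive_prob = marker_positive_prob,
         cd8_type = cd8_type, seed = as.integer(seed)),
    class = "cell_sim_params"
  )
}

# Uniform positions inside n pixels drawn (with replacement) from a zone.
sample_positions_in_zone <- function(labels, code, n, ps) {
  px <- which(labels == code)
  if (!length(px) || n == 0L) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  }
  idx <- px[sample.int(length(px), n, replace = TRUE)]
  nr <- nrow(labels)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  data.frame(
    x_um = (col - 1L) * ps + runif(n) * ps,
    y_um = (row - 1L) * ps + runif(n) * ps
  )
}

#' Generate a synthetic cell table over a zone map
#'
#' @param zone_map A [build_zone_map()] result.
#' @param params A [cell_sim_params()] object.
#' @return A list with `cells` (data frame: `cell_id`, `x_um`, `y_um`,
#'   `cell_type`, `true_zone`, `true_clone`, one logical `marker_*` column
#'   per marker) and `manifest` recording the requested densities, clone
#'   fractions, enrichment factor and seed.
#' @export
generate_cells <- function(zone_map, params) {
  stopifnot(inherits(zone_map, "zone_map"), inherits(params, "cell_sim_params"))
  withr::local_seed(child_seed(params$seed, "cells"))
  ps <- zone_map$pixel_size_um
  areas <- zone_map$areas_mm2
  if (all(areas == 0)) stopf("zone map has no tissue")

  groups <- list()
  for (ct in names(params$base_density_per_mm2)) {
    dens <- params$base_density_per_mm2[[ct]]
    if (ct == params$cd8_type && length(params$clone_labels)) {
      groups[[ct]] <- list(type = ct, clone = NA_character_,
                           density = dens * (1 - sum(params$clone_freq_in_cd8)))
      for (i in seq_along(params$clone_labels)) {
        groups[[paste0(ct, ".", params$clone_labels[i])]] <- list(
          type = ct, clone = params$clone_labels[i],
          density = dens * params$clone_freq_in_cd8[i]
        )
      }
    } else {
      groups[[ct]] <- list(type = ct, clone = NA_character_, density = dens)
    }
  }

  parts <- list()
  for (g in groups) {
    for (z in names(ZONE_LEVELS)) {
      dens <- g$density
      if (!is.na(g$clone) && z == "PORTAL_INTERFACE") {
        dens <- dens * params$pi_enrichment_factor
      }
      if (dens <= 0) next
      if (areas[[z]] == 0) {
        warnf("zone %s has zero area; requested density for %s skipped", z, g$type)
        next
      }
      n <- rpois(1L, dens * areas[[z]])
      if (n == 0L) next
      pos <- sample_positions_in_zone(zone_map$labels, ZONE_LEVELS[[z]], n, ps)
      parts[[length(parts) + 1L]] <- data.frame(
        x_um = pos$x_um, y_um = pos$y_um,
        cell_type = g$type, true_zone = z, true_clone = g$clone,
        stringsAsFactors = FALSE
      )
    }
  }
  cells <- if (length(parts)) do.call(rbind, parts) else
    data.frame(x_um = numeric(0), y_um = numeric(0), cell_type = character(0),
               true_zone = character(0), true_clone = character(0))
  if (nrow(cells)) {
    cells <- cells[order(cells$true_zone, cells$cell_type, cells$x_um, cells$y_um), , drop = FALSE]
    cells <- cbind(cell_id = sprintf("cell_%07d", seq_len(nrow(cells))), cells,
                   stringsAsFactors = FALSE)
    rownames(cells) <- NULL
  } else {
    cells <- cbind(cell_id = character(0), cells)
  }

  if (!is.null(params$marker_positive_prob) && nrow(cells)) {
    labelled <- !is.na(cells$true_clone)
    for (m in rownames(params$marker_positive_prob)) {
      p <- ifelse(labelled,
                  params$marker_positive_prob[m, "clone"],
                  params$marker_positive_prob[m, "other"])
      cells[[paste0("marker_", m)]] <- runif(nrow(cells)) < p
    }
  }

  manifest <- list(cells = list(
    base_density_per_mm2 = params$base_density_per_mm2,
    clone_labels = params$clone_labels,
    clone_freq_in_cd8 = params$clone_freq_in_cd8,
    pi_enrichment_factor = params$pi_enrichment_factor,
    marker_positive_prob = params$marker_positive_prob,
    cd8_type = params$cd8_type,
    n_cells = nrow(cells),
    seed = params$seed
  ))
  list(cells = cells, manifest = manifest)
}
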