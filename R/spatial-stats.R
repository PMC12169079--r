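# Cell-to-zone assignment and per-zone occupancy, density, marker and
# enrichment statistics.

#' Assign cells to zones by centroid
#'
#' Looks up the zone label of the pixel containing each cell centroid.
#' Cells outside the raster are flagged and excluded (with a warning);
#' cells on background pixels get `NA` zone and are excluded from zone
#' statistics but counted. A logical `in_duct` column records centroids on
#' bile-duct pixels (a convenience counter, not a separate zone).
#'
#' @param cells Data frame with `x_um` and `y_um` columns (micrometres, in
#'   the zone map's coordinate frame).
#' @param zone_map A [build_zone_map()] result.
#' @return `cells` with `zone` (zone name or `NA`) and `in_duct` columns;
#'   attributes `n_outside` and `n_background` report the exclusions.
#' @export
assign_zones <- function(cells, zone_map) {
  stopifnot(inherits(zone_map, "zone_map"))
  if (nrow(cells) == 0L) {
    cells$zone <- character(0)
    cells$in_duct <- logical(0)
    attr(cells, "n_outside") <- 0L
    attr(cells, "n_background") <- 0L
    return(cells)
  }
  ps <- zone_map$pixel_size_um
  nr <- nrow(zone_map$labels); nc <- ncol(zone_map$labels)
  col <- floor(cells$x_um / ps) + 1L
  row <- floor(cells$y_um / ps) + 1L
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  if (any(!inside)) {
    warnf("%d cell(s) outside the raster were excluded from zone assignment",
          sum(!inside))
  }
  code <- rep(NA_integer_, nrow(cells))
  code[inside] <- zone_map$labels[cbind(row[inside], col[inside])]
  zone <- rep(NA_character_, nrow(cells))
  on_tissue <- !is.na(code) & code > 0L
  zone[on_tissue] <- names(ZONE_LEVELS)[code[on_tissue]]
  cells$zone <- zone
  in_duct <- rep(FALSE, nrow(cells))
  in_duct[inside] <- zone_map$duct[cbind(row[inside], col[inside])]
  cells$in_duct <- in_duct
  attr(cells, "n_outside") <- sum(!inside)
  attr(cells, "n_background") <- sum(inside & code == 0L)
  cells
}

#' Per-zone occupancy, density and marker statistics
#'
#' For a selection of cells (all cells by default), reports per zone the
#' cell count, the fraction of the selection, the zone area, the density
#' (cells per mm2) and the marker-positive fraction for each requested
#' marker. Fractions are computed over selected cells with a zone label, so
#' they sum to 1.
#'
#' @param cells Zone-assigned cells (see [assign_zones()]).
#' @param zone_map The [build_zone_map()] result (source of zone areas).
#' @param subset Optional logical vector selecting the cells to summarise.
#' @param markers Character vector of marker names (matching `marker_*`
#'   columns).
#' @return Data frame with one row per zone and columns `zone`, `n_cells`,
#'   `fraction`, `area_mm2`, `density_per_mm2` and `frac_<marker>`;
#'   attributes `n_selected`, `n_background`, `overall_density_per_mm2`
#'   and `n_in_duct`.
#' @export
zone_statistics <- function(cells, zone_map, subset = NULL, markers = character()) {
  stopifnot(inherits(zone_map, "zone_map"))
  if (is.null(cells$zone)) stopf("cells have no zone column; run assign_zones() first")
  sel <- if (is.null(subset)) rep(TRUE, nrow(cells)) else subset
  if (length(sel) != nrow(cells)) stopf("subset length does not match cell table")
  sel[is.na(sel)] <- FALSE
  zoned <- sel & !is.na(cells$zone)
  n_sel <- sum(zoned)
  zones <- names(ZONE_LEVELS)
  zf <- factor(cells$zone[zoned], levels = zones)
  n <- as.vector(table(zf))
  areas <- unname(zone_map$areas_mm2[zones])
  dens <- rep(NA_real_, length(zones))
  ok_area <- areas > 0
  dens[ok_area] <- n[ok_area] / areas[ok_area]
  if (any(!ok_area & n > 0)) {
    warnf("zone(s) with zero area but assigned cells: %s",
          paste(zones[!ok_area & n > 0], collapse = ", "))
  }
  out <- data.frame(
    zone = zones,
    n_cells = n,
    fraction = if (n_sel > 0) n / n_sel else rep(NA_real_, length(zones)),
    area_mm2 = areas,
    density_per_mm2 = dens,
    stringsAsFactors = FALSE
  )
  for (m in markers) {
    colname <- paste0("marker_", m)
    if (is.null(cells[[colname]])) stopf("marker column '%s' not found", colname)
    pos <- tapply(cells[[colname]][zoned], zf, function(v) mean(v))
    out[[paste0("frac_", m)]] <- as.vector(pos)
  }
  attr(out, "n_selected") <- n_sel
  attr(out, "n_background") <- sum(sel & is.na(cells$zone))
  attr(out, "overall_density_per_mm2") <-
    if (zone_map$total_tissue_mm2 > 0) n_sel / zone_map$total_tissue_mm2 else NA_real_
  attr(out, "n_in_duct") <- if (!is.null(cells$in_duct)) sum(zoned & cells$in_duct) else NA_integer_
  out
}

#' Fisher exact comparison of marker positivity between two groups
#'
#' Builds the 2x2 table of marker positivity by group and applies the
#' two-sided Fisher exact test. The reported odds ratio is the sample
#' (cross-product) odds ratio; 0.5 is added to every cell only when some
#' cell is zero, and that continuity correction is flagged.
#'
#' @param x Either a 2x2 matrix/table (rows = groups, columns =
#'   positive/negative) or a cell data frame for group A.
#' @param y Cell data frame for group B (when `x` is a data frame).
#' @param marker Marker name (matching a `marker_<name>` column) when cell
#'   data frames are supplied.
#' @return A `proportion_test` list: `table`, `prop_a`, `prop_b`,
#'   `odds_ratio`, `p_value`, `continuity`.
#' @export
proportion_test <- function(x, y = NULL, marker = NULL) {
  if (is.matrix(x) || is.table(x)) {
    tab <- as.matrix(x)
    if (!all(dim(tab) == c(2L, 2L))) stopf("contingency table must be 2x2")
  } else {
    if (is.null(y) || is.null(marker)) {
      stopf("supply either a 2x2 table or two cell groups and a marker name")
    }
    colname <- paste0("marker_", marker)
    if (is.null(x[[colname]]) || is.null(y[[colname]])) {
      stopf("marker column '%s' absent from the cell records", colname)
    }
    if (nrow(x) == 0L || nrow(y) == 0L) stopf("both groups must be non-empty")
    tab <- rbind(
      a = c(positive = sum(x[[colname]]), negative = sum(!x[[colname]])),
      b = c(positive = sum(y[[colname]]), negative = sum(!y[[colname]]))
    )
  }
  storage.mode(tab) <- "double"
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  continuity <- any(tab == 0)
  t2 <- if (continuity) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(
    list(table = tab,
         prop_a = tab[1, 1] / sum(tab[1, ]),
         prop_b = tab[2, 1] / sum(tab[2, ]),
         odds_ratio = or,
         p_value = p,
         continuity = continuity),
    class = "proportion_test"
  )
}

#' @method print proportion_test
#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("proportion test: %.1f%% vs %.1f%% (OR %.3g, Fisher p = %.3g%s)\n",
              100 * x$prop_a, 100 * x$prop_b, x$odds_ratio, x$p_value,
              if (x$continuity) ", continuity-corrected OR" else ""))
  invisible(x)
}

#' Permutation test for zonal enrichment of a cell selection
#'
#' Tests, per zone, whether a selection of cells (e.g. clone-positive CD8 T
#' cells) occupies the zone more than expected for a random draw of the
#' same size from the reference population (all supplied cells with a zone
#' label), by permutation: the statistic is the observed selected-cell
#' fraction in the zone minus the reference fraction, and the p-value is
#' the upper-tail permutation probability with add-one correction.
#'
#' @param cells Zone-assigned reference population.
#' @param selection Logical vector (length `nrow(cells)`) marking the
#'   selected subset.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return Data frame per zone: `zone`, `n_ref`, `n_sel`, `frac_ref`,
#'   `frac_sel`, `statistic`, `p_value`; attributes `n_perm` and `seed`.
#' @export
zone_enrichment_test <- function(cells, selection, n_perm = 999L, seed = 1L) {
  if (is.null(cells$zone)) stopf("cells have no zone column; run assign_zones() first")
  if (length(selection) != nrow(cells)) stopf("selection length does not match cell table")
  if (!is_count(n_perm) || n_perm < 100) stopf("n_perm must be an integer >= 100")
  selection[is.na(selection)] <- FALSE
  zoned <- !is.na(cells$zone)
  zf <- factor(cells$zone[zoned], levels = names(ZONE_LEVELS))
  sel <- selection[zoned]
  n_ref <- length(zf)
  n_sel <- sum(sel)
  if (n_sel == 0L || n_ref == 0L) stopf("selection and reference must be non-empty")
  zones <- names(ZONE_LEVELS)
  ref_counts <- as.vector(table(zf))
  obs_counts <- as.vector(table(zf[sel]))
  frac_ref <- ref_counts / n_ref
  frac_sel <- obs_counts / n_sel
  statistic <- frac_sel - frac_ref

  withr::local_seed(child_seed(seed, "enrichment"))
  zi <- as.integer(zf)
  exceed <- integer(length(zones))
  for (b in seq_len(n_perm)) {
    perm <- zi[sample.int(n_ref, n_sel)]
    perm_stat <- tabulate(perm, nbins = length(zones)) / n_sel - frac_ref
    exceed <- exceed + (perm_stat >= statistic)
  }
  out <- data.frame(
    zone = zones, n_ref = ref_counts, n_sel = obs_counts,
    frac_ref = frac_ref, frac_sel = frac_sel,
    statistic = statistic,
    p_value = (1 + exceed) / (n_perm + 1),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  out
}
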