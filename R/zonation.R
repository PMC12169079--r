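# Five-zone liver decomposition from binary tissue masks via exact
# Euclidean distance transforms.

#' Zone codes and names
#'
#' Integer label codes used in zone rasters: 0 background, 1 portal tract,
#' 2 portal interface, 3 lobular interface, 4 extrasinusoidal lobule,
#' 5 intrasinusoidal lobule.
#' @export
ZONE_LEVELS <- c(
  PORTAL = 1L, PORTAL_INTERFACE = 2L, LOBULAR_INTERFACE = 3L,
  LOBULE_EXTRASINUSOIDAL = 4L, LOBULE_INTRASINUSOIDAL = 5L
)

as_binary_mask <- function(m, name) {
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1) | m %in% c(0, 255))) {
    stopf("%s mask is not binary (values other than 0/1 or 0/255 found)", name)
  }
  m > 0
}

#' Bundle binary tissue masks
#'
#' Collects the four classifier-derived binary masks (hepatocyte
#' parenchyma, portal tracts, sinusoid lumina, bile ducts) with their pixel
#' size. Rasters use the image convention: origin top-left, x rightward
#' (columns), y downward (rows), pixel centres at half-integer micrometres.
#'
#' @param hepatocyte,portal,sinusoid,duct Binary matrices of identical
#'   dimensions (logical, 0/1, or 0/255).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return A `mask_bundle` object.
#' @export
mask_bundle <- function(hepatocyte, portal, sinusoid, duct, pixel_size_um) {
  stopifnot(is_scalar_num(pixel_size_um), pixel_size_um > 0)
  masks <- list(hepatocyte = hepatocyte, portal = portal,
                sinusoid = sinusoid, duct = duct)
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stopf("mask dimensions differ")
  masks <- Map(as_binary_mask, masks, names(masks))
  structure(c(masks, list(pixel_size_um = pixel_size_um)), class = "mask_bundle")
}

# Metric Euclidean distance (micrometres) from every pixel to the nearest
# pixel of `target` (a logical matrix). Inf when target is empty.
distance_to <- function(target, pixel_size_um) {
  if (!any(target)) {
    return(matrix(Inf, nrow(target), ncol(target)))
  }
  if (all(target)) {
    return(matrix(0, nrow(target), ncol(target)))
  }
  # distmap(): distance of each foreground pixel to the nearest background
  # pixel; with the target as background this is distance-to-target.
  d <- EBImage::distmap(matrix(as.numeric(!target), nrow(target)), metric = "euclidean")
  as.matrix(d) * pixel_size_um
}

#' Build the five-zone liver decomposition
#'
#' Partitions tissue into portal tract, portal interface (PI), lobular
#' interface (LI), extrasinusoidal and intrasinusoidal lobule. The limiting
#' plate is the boundary between the portal region and the lobule; the PI is
#' the portal-side band within `band_width_um` of the lobule, the LI the
#' lobule-side band within `band_width_um` of the portal region, and the
#' remaining (reduced) lobule is split by the sinusoid mask. Distances are
#' exact Euclidean distances on the metric grid, and bands are inclusive
#' (`<= band_width_um`). Bile-duct pixels are treated as part of the portal
#' region; non-hepatocyte, non-portal, non-sinusoid tissue follows the
#' lobule rules.
#'
#' @param masks A [mask_bundle()].
#' @param band_width_um Interface band width in micrometres (default 50,
#'   must be at least the pixel size).
#' @return A `zone_map` object: integer `labels` raster (see
#'   [ZONE_LEVELS]), `pixel_size_um`, `band_width_um`, per-zone
#'   `areas_mm2`, `total_tissue_mm2` and the `duct` mask (kept for the
#'   duct-infiltration counter).
#' @export
build_zone_map <- function(masks, band_width_um = 50) {
  stopifnot(inherits(masks, "mask_bundle"))
  ps <- masks$pixel_size_um
  if (!is_scalar_num(band_width_um) || band_width_um < ps) {
    stopf("band_width_um must be a number >= pixel_size_um (%g)", ps)
  }
  portal_region <- masks$portal | masks$duct
  tissue <- masks$hepatocyte | portal_region | masks$sinusoid
  lobule <- tissue & !portal_region

  labels <- matrix(0L, nrow(tissue), ncol(tissue))
  if (any(portal_region)) {
    d_lob <- distance_to(lobule, ps)
    pi_band <- portal_region & d_lob <= band_width_um
    labels[portal_region] <- ZONE_LEVELS[["PORTAL"]]
    labels[pi_band] <- ZONE_LEVELS[["PORTAL_INTERFACE"]]
  }
  if (any(lobule)) {
    d_por <- distance_to(portal_region, ps)
    li_band <- lobule & d_por <= band_width_um
    rest <- lobule & !li_band
    labels[li_band] <- ZONE_LEVELS[["LOBULAR_INTERFACE"]]
    labels[rest & masks$sinusoid] <- ZONE_LEVELS[["LOBULE_INTRASINUSOIDAL"]]
    labels[rest & !masks$sinusoid] <- ZONE_LEVELS[["LOBULE_EXTRASINUSOIDAL"]]
  }

  px_area_mm2 <- ps^2 * 1e-6
  counts <- tabulate(labels[labels > 0L], nbins = 5L)
  areas <- stats::setNames(counts * px_area_mm2, names(ZONE_LEVELS))
  structure(
    list(labels = labels, pixel_size_um = ps, band_width_um = band_width_um,
         areas_mm2 = areas, total_tissue_mm2 = sum(areas),
         duct = masks$duct),
    class = "zone_map"
  )
}

#' Per-zone areas
#'
#' @param zone_map A [build_zone_map()] result.
#' @return Data frame with columns `zone`, `code`, `area_mm2`; the total
#'   tissue area is attached as attribute `total_tissue_mm2`.
#' @export
zone_areas <- function(zone_map) {
  stopifnot(inherits(zone_map, "zone_map"))
  out <- data.frame(
    zone = names(ZONE_LEVELS),
    code = unname(ZONE_LEVELS),
    area_mm2 = unname(zone_map$areas_mm2[names(ZONE_LEVELS)]),
    stringsAsFactors = FALSE
  )
  attr(out, "total_tissue_mm2") <- zone_map$total_tissue_mm2
  out
}

#' @method print zone_map
#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("zone_map: %d x %d px at %g um/px, band %g um\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um, x$band_width_um))
  cat(sprintf("  total tissue %.3f mm2\n", x$total_tissue_mm2))
  for (z in names(ZONE_LEVELS)) {
    cat(sprintf("  %-24s %.3f mm2\n", z, x$areas_mm2[[z]]))
  }
  invisible(x)
}

#' @method plot zone_map
#' @export
plot.zone_map <- function(x, ...) {
  cols <- c("white", "#8c510a", "#d8b365", "#c7eae5", "#5ab4ac", "#01665e")
  graphics::image(t(x$labels)[, nrow(x$labels):1, drop = FALSE],
                  col = cols, zlim = c(0, 5), axes = FALSE, asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}
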