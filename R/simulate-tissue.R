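# Synthetic lobular tissue geometry: portal tract disks with central bile
# ducts, sinusoid polylines inside the lobule, hepatocyte parenchyma as the
# remainder. A stand-in for classifier-derived masks of a liver section.

#' Parameters for a synthetic tissue geometry
#'
#' @param width_um,height_um Section extent in micrometres.
#' @param pixel_size_um Raster resolution (micrometres per pixel).
#' @param n_portal_tracts Number of circular portal tracts to place.
#' @param portal_radius_um Mean portal tract radius.
#' @param portal_radius_jitter Relative radius jitter (each tract's radius
#'   is uniform in `portal_radius_um * (1 +/- jitter)`).
#' @param sinusoid_fraction Target fraction of lobule pixels covered by
#'   sinusoid lumina.
#' @param duct_radius_um Bile duct radius (one duct per portal tract,
#'   centred in the tract).
#' @param seed Integer seed.
#' @return A validated `tissue_sim_params` list.
#' @export
tissue_sim_params <- function(width_um = 3000, height_um = 3000,
                              pixel_size_um = 2, n_portal_tracts = 6L,
                              portal_radius_um = 120,
                              portal_radius_jitter = 0.2,
                              sinusoid_fraction = 0.10,
                              duct_radius_um = 15, seed = 1L) {
  stopifnot(width_um > 0, height_um > 0, pixel_size_um > 0,
            n_portal_tracts >= 0, portal_radius_um > 0,
            portal_radius_jitter >= 0, portal_radius_jitter < 1,
            duct_radius_um >= 0, duct_radius_um < portal_radius_um)
  if (!is_fraction(sinusoid_fraction)) stopf("sinusoid_fraction must lie in [0,1]")
  if (n_portal_tracts > 0 && min(width_um, height_um) < 4 * 2 * portal_radius_um) {
    stopf("raster dimensions must be at least 4x the portal diameter")
  }
  structure(
    list(width_um = width_um, height_um = height_um,
         pixel_size_um = pixel_size_um,
         n_portal_tracts = as.integer(n_portal_tracts),
         portal_radius_um = portal_radius_um,
         portal_radius_jitter = portal_radius_jitter,
         sinusoid_fraction = sinusoid_fraction,
         duct_radius_um = duct_radius_um, seed = as.integer(seed)),
    class = "tissue_sim_params"
  )
}

# Paint a disk of radius r_um centred at (cx, cy) in micrometre coordinates
# into logical matrix m (rows = y, cols = x, pixel centres at half-integers).
paint_disk <- function(m, cx, cy, r_um, ps) {
  nr <- nrow(m); nc <- ncol(m)
  c0 <- max(1L, floor((cx - r_um) / ps)); c1 <- min(nc, ceiling((cx + r_um) / ps) + 1L)
  r0 <- max(1L, floor((cy - r_um) / ps)); r1 <- min(nr, ceiling((cy + r_um) / ps) + 1L)
  if (c0 > c1 || r0 > r1) return(m)
  cols <- c0:c1; rows <- r0:r1
  px <- (cols - 0.5) * ps; py <- (rows - 0.5) * ps
  inside <- outer((py - cy)^2, (px - cx)^2, "+") <= r_um^2
  m[rows, cols] <- m[rows, cols] | inside
  m
}

#' Generate synthetic tissue masks
#'
#' Places non-overlapping circular portal tracts (each with a central bile
#' duct), draws sinusoids as dilated random-walk polylines inside the
#' lobule until the target area fraction is reached, and assigns the
#' remaining lobule to hepatocyte parenchyma.
#'
#' @param params A [tissue_sim_params()] object.
#' @return A list with `masks` (a [mask_bundle()]) and `manifest` recording
#'   tract centres/radii, the realised sinusoid fraction and the seed.
#' @export
generate_tissue <- function(params) {
  stopifnot(inherits(params, "tissue_sim_params"))
  withr::local_seed(child_seed(params$seed, "tissue"))
  ps <- params$pixel_size_um
  nc <- max(1L, round(params$width_um / ps))
  nr <- max(1L, round(params$height_um / ps))
  width <- nc * ps; height <- nr * ps

  portal <- matrix(FALSE, nr, nc)
  duct <- matrix(FALSE, nr, nc)
  centres <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  if (params$n_portal_tracts > 0L) {
    jit <- params$portal_radius_jitter
    max_try <- 200L * params$n_portal_tracts
    tries <- 0L
    while (length(radii) < params$n_portal_tracts) {
      tries <- tries + 1L
      if (tries > max_try) {
        stopf("could not place %d non-overlapping portal tracts after %d tries",
              params$n_portal_tracts, max_try)
      }
      r <- params$portal_radius_um * runif(1, 1 - jit, 1 + jit)
      cx <- runif(1, r, width - r)
      cy <- runif(1, r, height - r)
      if (nrow(centres)) {
        d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
        if (any(d < radii + r + 2 * ps)) next
      }
      centres <- rbind(centres, c(cx, cy))
      radii <- c(radii, r)
      portal <- paint_disk(portal, cx, cy, r, ps)
      if (params$duct_radius_um > 0) {
        duct <- paint_disk(duct, cx, cy, params$duct_radius_um, ps)
      }
    }
  }

  lobule <- !portal
  n_lobule <- sum(lobule)
  sinusoid <- matrix(FALSE, nr, nc)
  # Sinusoids: random-walk polylines dilated to ~8 um width (disk stamps of
  # radius 4 um along the path), clipped to the lobule.
  if (params$sinusoid_fraction > 0 && n_lobule > 0) {
    target <- params$sinusoid_fraction * n_lobule
    half_w <- 4
    step <- 6
    offs <- which(outer(((-ceiling(half_w / ps)):(ceiling(half_w / ps)) * ps)^2,
                        ((-ceiling(half_w / ps)):(ceiling(half_w / ps)) * ps)^2,
                        "+") <= half_w^2, arr.ind = TRUE)
    k <- ceiling(half_w / ps) + 1L
    d_off <- cbind(offs[, 1] - k, offs[, 2] - k)
    walks <- 0L
    while (sum(sinusoid) < target && walks < 10000L) {
      walks <- walks + 1L
      x <- runif(1, 0, width); y <- runif(1, 0, height)
      theta <- runif(1, 0, 2 * pi)
      n_steps <- 120L
      xs <- numeric(n_steps); ys <- numeric(n_steps)
      for (i in seq_len(n_steps)) {
        theta <- theta + rnorm(1, 0, 0.35)
        x <- min(max(x + step * cos(theta), 0), width)
        y <- min(max(y + step * sin(theta), 0), height)
        xs[i] <- x; ys[i] <- y
      }
      rr <- pmin(pmax(floor(ys / ps) + 1L, 1L), nr)
      cc <- pmin(pmax(floor(xs / ps) + 1L, 1L), nc)
      pr <- rep(rr, each = nrow(d_off)) + rep(d_off[, 1], n_steps)
      pc <- rep(cc, each = nrow(d_off)) + rep(d_off[, 2], n_steps)
      ok <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
      idx <- cbind(pr[ok], pc[ok])
      keep <- lobule[idx]
      sinusoid[idx[keep, , drop = FALSE]] <- TRUE
    }
  }
  hepatocyte <- lobule & !sinusoid

  masks <- mask_bundle(hepatocyte, portal, sinusoid, duct, pixel_size_um = ps)
  manifest <- list(tissue = list(
    portal_centres_um = centres, portal_radii_um = radii,
    sinusoid_fraction_realised = if (n_lobule > 0) sum(sinusoid) / n_lobule else 0,
    width_um = width, height_um = height, pixel_size_um = ps,
    seed = params$seed
  ))
  list(masks = masks, manifest = manifest)
}
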