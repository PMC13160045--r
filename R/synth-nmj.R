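#' Parameters for synthetic NMJ volumes
#'
#' Describes a synthetic Airyscan-class volume of one *Drosophila* NMJ
#' bouton: a disc-footprint terminal spanning the interior z-slices, with
#' the periactive-zone pattern painted on one designated surface slice of
#' the upper half. The footprint is tiled into `n_units` periactive-zone
#' units (Voronoi cells of well-separated seed points); each mesh channel
#' carries a mesh band of width `mesh_width_nm` inward from every unit
#' boundary whose mean intensity is exactly `mesh_enrichment` times the core
#' intensity before noise (a two-level profile cresting at the unit
#' boundary, so the inter-unit ridge is unambiguous). Brp puncta are placed
#' at the centroids of a fraction `brp_fraction` of units, and a Pak spot is
#' apposed to every unit when `pak_apposition` is set. Noise follows
#' `value = Poisson(poisson_scale * signal) + Normal(0, read_noise_sd)`;
#' both 0 = noise-free.
#'
#' @param size Volume dimensions `c(y, x, z)` in pixels.
#' @param lateral_nm,axial_nm Pixel calibration.
#' @param bouton_radius_px Footprint disc radius.
#' @param n_units Number of periactive-zone units `K >= 1`.
#' @param mesh_width_nm Width of the enriched band.
#' @param mesh_enrichment Band/core mean ratio `R > 0`; a scalar or a named
#'   vector over `mesh_channels`.
#' @param mesh_channels Channels carrying the mesh pattern.
#' @param base_intensity Core intensity of mesh channels on the surface
#'   slice.
#' @param core_texture_amp,core_texture_scale_px Amplitude (relative sd) and
#'   correlation length of the smooth large-scale intensity texture
#'   multiplying the unit cores (stains are never flat); the texture is
#'   renormalized per unit so every core mean equals `base_intensity`
#'   exactly.
#' @param interior_intensity Intensity of non-surface occupied slices.
#' @param brp_fraction Fraction `p` of units receiving a Brp punctum; the
#'   positive count is `round(p * K)`.
#' @param brp_amp,brp_sigma_nm Brp punctum amplitude and sd.
#' @param pak_apposition Paint a Pak spot under every unit?
#' @param pak_amp,pak_sigma_nm Pak spot amplitude and sd.
#' @param background Constant background offset in every channel.
#' @param psf_fwhm_nm Optional isotropic lateral PSF blur (0 = crisp).
#' @param poisson_scale,read_noise_sd Noise model (0 = off).
#' @param seed RNG seed.
#' @return A validated `synth_nmj_params` object.
#' @export
synth_nmj_params <- function(size = c(160L, 160L, 8L),
                             lateral_nm = 50, axial_nm = 200,
                             bouton_radius_px = 55,
                             n_units = 20L,
                             mesh_width_nm = 175,
                             mesh_enrichment = 2,
                             mesh_channels = c("nwk", "dyn", "endoA",
                                               "dap160", "fasII"),
                             base_intensity = 100,
                             core_texture_amp = 0.25,
                             core_texture_scale_px = 40,
                             interior_intensity = 30,
                             brp_fraction = 0.6,
                             brp_amp = 400, brp_sigma_nm = 70,
                             pak_apposition = TRUE,
                             pak_amp = 100, pak_sigma_nm = 150,
                             background = 2,
                             psf_fwhm_nm = 0,
                             poisson_scale = 1, read_noise_sd = 2,
                             seed = 1L) {
  p <- list(size = as.integer(size), lateral_nm = lateral_nm,
            axial_nm = axial_nm, bouton_radius_px = bouton_radius_px,
            n_units = as.integer(n_units), mesh_width_nm = mesh_width_nm,
            mesh_enrichment = mesh_enrichment, mesh_channels = mesh_channels,
            base_intensity = base_intensity,
            core_texture_amp = core_texture_amp,
            core_texture_scale_px = core_texture_scale_px,
            interior_intensity = interior_intensity,
            brp_fraction = brp_fraction, brp_amp = brp_amp,
            brp_sigma_nm = brp_sigma_nm, pak_apposition = pak_apposition,
            pak_amp = pak_amp, pak_sigma_nm = pak_sigma_nm,
            background = background, psf_fwhm_nm = psf_fwhm_nm,
            poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
            seed = as.integer(seed))
  stopifnot(length(p$size) == 3L, all(p$size >= c(16L, 16L, 4L)),
            p$n_units >= 1L, all(p$mesh_enrichment > 0),
            p$brp_fraction >= 0, p$brp_fraction <= 1,
            p$bouton_radius_px < min(p$size[1:2]) / 2,
            p$poisson_scale >= 0, p$read_noise_sd >= 0)
  check_roles(p$mesh_channels)
  structure(p, class = "synth_nmj_params")
}

# Poisson-disc style seed placement inside a logical footprint.
place_unit_seeds <- function(footprint, k) {
  coords <- which(footprint, arr.ind = TRUE)  # (row=y+1, col=x+1)
  area <- nrow(coords)
  dmin <- 0.7 * sqrt(area / k)
  picked <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(picked) < k && tries < 400L * k) {
    tries <- tries + 1L
    cand <- coords[sample.int(area, 1L), ]
    if (nrow(picked) == 0 ||
        min((picked[, 1] - cand[1])^2 + (picked[, 2] - cand[2])^2) >=
          dmin^2) {
      picked <- rbind(picked, cand)
    }
  }
  if (nrow(picked) < k) {
    stop(k, " units unplaceable in the bouton footprint (placed ",
         nrow(picked), ")")
  }
  picked  # (y+1, x+1) matrix rows in placement order
}

# Per-unit inward band: unit pixels within `band_px` (Euclidean, pixel
# centers) of the unit's exterior (pixels of a different label or
# background). The innermost boundary ring sits at distance 1.
unit_band <- function(labels, id, band_px) {
  inunit <- labels == id
  d <- distance_map(inunit)
  list(band = inunit & d <= band_px, dist = d)
}

#' Generate a synthetic NMJ volume with ground truth
#'
#' Renders the scene described by [synth_nmj_params()]. Channels are `brp`,
#' `pak` and the configured mesh channels. The ground truth carries the true
#' unit label image of the footprint, per-unit records (centroid, area,
#' exact mesh/core mean ratio, Brp and Pak status, Brp punctum center), the
#' noise-free channel stacks (for oracle comparisons), the surface slice
#' index and all generator parameters.
#'
#' @param p A [synth_nmj_params()] object.
#' @return A list with elements `volume` (an [image_volume()]) and `truth`.
#' @export
generate_nmj_volume <- function(p) {
  stopifnot(inherits(p, "synth_nmj_params"))
  with_seed(p$seed, {
    ny <- p$size[1]; nx <- p$size[2]; nz <- p$size[3]
    cal <- pixel_calibration(p$lateral_nm, p$axial_nm)
    cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
    gy <- matrix(0:(ny - 1), ny, nx)
    gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
    footprint <- (gy - cy)^2 + (gx - cx)^2 <= p$bouton_radius_px^2
    occupied <- 2:(nz - 1)
    upper <- 1:ceiling(nz / 2)
    surface <- max(intersect(occupied, upper))
    k <- p$n_units
    seeds <- place_unit_seeds(footprint, k)
    # Voronoi tiling of the footprint (ties -> lower seed id)
    fcoord <- which(footprint, arr.ind = TRUE)
    d2 <- outer(fcoord[, 1], seeds[, 1], "-")^2 +
      outer(fcoord[, 2], seeds[, 2], "-")^2
    assign_id <- max.col(-d2, ties.method = "first")
    labels <- matrix(0L, ny, nx)
    labels[fcoord] <- assign_id
    band_px <- nm_to_px(p$mesh_width_nm, cal)
    rvec <- p$mesh_enrichment
    if (is.null(names(rvec))) {
      rvec <- stats::setNames(rep(rvec, length.out = length(p$mesh_channels)),
                              p$mesh_channels)
    }
    base <- p$base_intensity
    core_level <- base + p$background  # the core mean seen by the analysis
    # Mesh band of unit u: a two-level profile over the band pixels
    # (distance to the unit's exterior <= band_px): a uniform crest on the
    # outermost ring (distance < 2) and a uniform lower level on the inner
    # band, balanced so the band mean is exactly base + (R-1)*core_level,
    # i.e. (band + background) = R * (core + background). The crest heights
    # decrease strictly with the raster order in which the seed minima will
    # be discovered (anchored by a deterministic dip in each core), so the
    # deterministic (intensity, label, raster) tie-break of seeded region
    # growing awards every contested watershed ring to its true owner and
    # the Voronoi partition is recoverable from the noise-free scene.
    units <- vector("list", k)
    band_all <- matrix(FALSE, ny, nx)
    ramp <- matrix(0, ny, nx)  # normalized band profile, 0 elsewhere
    bands <- vector("list", k)
    anchor <- matrix(NA_real_, k, 2)  # (row, col) of each unit's core dip
    anchor_key <- integer(k)
    for (id in seq_len(k)) {
      ub <- unit_band(labels, id, band_px)
      bands[[id]] <- ub
      band_all <- band_all | ub$band
      ucoord <- which(labels == id, arr.ind = TRUE)
      ctr <- colMeans(ucoord)
      core_coord <- which(labels == id & !ub$band, arr.ind = TRUE)
      if (!nrow(core_coord)) core_coord <- ucoord
      near <- which.min((core_coord[, 1] - ctr[1])^2 +
                          (core_coord[, 2] - ctr[2])^2)
      anchor[id, ] <- core_coord[near, ]
      anchor_key[id] <- (anchor[id, 2] - 1) * ny + anchor[id, 1]
      units[[id]] <- list(id = id,
                          seed_px = c(x = seeds[id, 2] - 1,
                                      y = seeds[id, 1] - 1),
                          centroid_px = c(x = mean(ucoord[, 2]) - 1,
                                          y = mean(ucoord[, 1]) - 1),
                          area_px = nrow(ucoord))
    }
    crest_rank <- rank(anchor_key, ties.method = "first")
    for (id in seq_len(k)) {
      ub <- bands[[id]]
      bandc <- which(ub$band)
      if (length(bandc)) {
        ring <- ub$dist[bandc] < 2
        kap <- 2.2 + 0.4 * (k - crest_rank[id]) / max(k, 1L)
        n_ring <- sum(ring)
        n_inner <- length(bandc) - n_ring
        if (n_inner == 0L) kap <- 1
        kap <- min(kap, 0.95 * length(bandc) / max(n_ring, 1L))
        vals <- numeric(length(bandc))
        vals[ring] <- kap
        if (n_inner > 0L) {
          vals[!ring] <- (length(bandc) - n_ring * kap) / n_inner
        }
        ramp[bandc] <- vals  # per-unit band mean exactly 1
      }
    }
    # Smooth multiplicative texture over the cores plus a deterministic
    # anchor dip at each unit's core pixel nearest its centroid (stains are
    # never flat, and the dip pins one deep, raster-predictable intensity
    # minimum per unit); renormalized so every core mean is exactly 1.
    core_all <- footprint & !band_all
    tex <- matrix(1, ny, nx)
    raw_tex <- matrix(1, ny, nx)
    if (p$core_texture_amp > 0) {
      z <- gauss_blur2d(matrix(rnorm(ny * nx), ny, nx),
                        p$core_texture_scale_px / 2)
      z <- (z - mean(z)) / sd(z)
      raw_tex <- pmax(1 + p$core_texture_amp * z, 0.2)
    }
    for (id in seq_len(k)) {
      dip <- exp(-((gy - (anchor[id, 1] - 1))^2 +
                     (gx - (anchor[id, 2] - 1))^2) / (2 * 2.5^2))
      tx <- raw_tex * (1 - 0.55 * dip)
      cidx <- which(labels == id & core_all)
      if (length(cidx)) tex[cidx] <- tx[cidx] / mean(tx[cidx])
    }
    mesh_patterns <- list()
    for (rv in unique(rvec)) {
      pat <- matrix(0, ny, nx)
      pat[core_all] <- base * tex[core_all]
      pat[band_all] <- base + (rv - 1) * core_level * ramp[band_all]
      mesh_patterns[[as.character(rv)]] <- pat
    }
    # Brp-positive units and puncta at unit centroids
    n_pos <- round(p$brp_fraction * k)
    pos_ids <- if (n_pos > 0) sort(sample.int(k, n_pos)) else integer(0)
    brp_surface <- matrix(0, ny, nx)
    for (id in seq_len(k)) {
      u <- units[[id]]
      u$brp_positive <- id %in% pos_ids
      u$pak_apposed <- isTRUE(p$pak_apposition)
      u$mesh_core_ratio <- rvec
      if (u$brp_positive) {
        d2c <- (gy - (u$centroid_px["y"]))^2 + (gx - (u$centroid_px["x"]))^2
        brp_surface <- brp_surface +
          p$brp_amp * exp(-d2c * p$lateral_nm^2 / (2 * p$brp_sigma_nm^2))
        u$brp_center_px <- u$centroid_px
      }
      units[[id]] <- u
    }
    pak_surface <- matrix(0, ny, nx)
    if (isTRUE(p$pak_apposition)) {
      for (id in seq_len(k)) {
        ctr <- units[[id]]$centroid_px
        d2c <- (gy - ctr["y"])^2 + (gx - ctr["x"])^2
        pak_surface <- pak_surface +
          p$pak_amp * exp(-d2c * p$lateral_nm^2 / (2 * p$pak_sigma_nm^2))
      }
    }
    # assemble volumes
    roles <- c(p$mesh_channels, "brp", "pak")
    sigma_px <- p$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / p$lateral_nm
    clean <- list()
    for (role in roles) {
      vol <- array(0, dim = c(ny, nx, nz))
      for (z in occupied) {
        sl <- matrix(0, ny, nx)
        if (z == surface) {
          sl <- switch(role,
            brp = brp_surface,
            pak = pak_surface,
            mesh_patterns[[as.character(rvec[[role]])]])
        } else if (!(role %in% c("brp", "pak"))) {
          sl[footprint] <- p$interior_intensity
        }
        if (sigma_px > 0) sl <- gauss_blur2d(sl, sigma_px)
        vol[, , z] <- sl
      }
      clean[[role]] <- vol + p$background
    }
    chs <- lapply(clean, function(vol) {
      out <- vol
      for (z in seq_len(nz)) {
        out[, , z] <- apply_noise(vol[, , z], p$poisson_scale,
                                  p$read_noise_sd)
      }
      quantize_storage(out)  # emit at 16-bit camera depth
    })
    volume <- image_volume(chs, cal, id = "synth_nmj")
    truth <- structure(list(kind = "nmj", params = unclass(p), seed = p$seed,
                            labels = labels, footprint = footprint,
                            band = band_all, surface_slice = surface,
                            band_px = band_px, units = units,
                            clean = clean),
                       class = "ground_truth")
    list(volume = volume, truth = truth)
  })
}
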