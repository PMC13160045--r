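#' Parameters for synthetic STED fields
#'
#' Describes a synthetic two-color-STED scene of cultured-neuron synapses on
#' a square grid of non-overlapping cells, mixing side-view synapses (an
#' elongated active-zone marker bar with an adjacent vesicle cloud and a
#' protein band at a known signed offset) and en-face synapses (a marker
#' disk ringed by protein clusters at known radii). Geometry is specified in
#' nm; bar/band/cloud widths are FWHM. The defaults emulate the acquisition
#' conditions of the STED workflow: 22.7 nm pixels, a 60 nm PSF, a marker
#' bar of 300 x 80 nm, a vesicle cloud of 400 nm adjacent on the
#' presynaptic side, protein bands offset by +/- 90.8 nm (4 px) and en-face
#' clusters at 250 nm from the active-zone center. Photon noise follows
#' `value = Poisson(poisson_scale * signal) + Normal(0, read_noise_sd)`;
#' setting both noise parameters to 0 yields the noise-free variant.
#'
#' @param n_sideview,n_enface Number of synapses of each kind.
#' @param cell_px Side length of one synapse cell in pixels.
#' @param lateral_nm Pixel pitch (nm/px).
#' @param marker_length_nm,marker_width_nm,marker_amp Marker bar geometry
#'   (FWHM) and amplitude.
#' @param delta_nm Signed protein-band offset(s), recycled over side-view
#'   synapses; positive = toward the presynaptic (vesicle-cloud) side.
#' @param protein_sigma_nm,protein_amp Protein band sd and amplitude.
#' @param cloud_diam_nm,cloud_amp Vesicle cloud FWHM (>= 250 by default)
#'   and amplitude.
#' @param clusters_per_synapse,cluster_radius_nm,cluster_sigma_nm,cluster_amp
#'   En-face cluster count, ring radius, spot sd and amplitude.
#' @param enface_marker_sigma_nm,enface_marker_amp,enface_vesicle_sigma_nm
#'   En-face marker / vesicle disk geometry.
#' @param psf_fwhm_nm Isotropic gaussian PSF FWHM (0 disables blurring).
#' @param background Constant background offset added to every channel.
#' @param poisson_scale,read_noise_sd Noise model parameters (0 = off).
#' @param seed RNG seed; identical params + seed give bitwise-identical
#'   scenes.
#' @return A validated `synth_sted_params` object.
#' @export
synth_sted_params <- function(n_sideview = 4L, n_enface = 4L,
                              cell_px = 64L, lateral_nm = 22.7,
                              marker_length_nm = 300, marker_width_nm = 80,
                              marker_amp = 150,
                              delta_nm = 90.8,
                              protein_sigma_nm = 45, protein_amp = 100,
                              cloud_diam_nm = 400, cloud_amp = 100,
                              clusters_per_synapse = 4L,
                              cluster_radius_nm = 250,
                              cluster_sigma_nm = 40, cluster_amp = 120,
                              enface_marker_sigma_nm = 60,
                              enface_marker_amp = 150,
                              enface_vesicle_sigma_nm = 200,
                              psf_fwhm_nm = 60,
                              background = 5,
                              poisson_scale = 1, read_noise_sd = 2,
                              seed = 1L) {
  p <- list(n_sideview = as.integer(n_sideview),
            n_enface = as.integer(n_enface),
            cell_px = as.integer(cell_px), lateral_nm = lateral_nm,
            marker_length_nm = marker_length_nm,
            marker_width_nm = marker_width_nm, marker_amp = marker_amp,
            delta_nm = delta_nm, protein_sigma_nm = protein_sigma_nm,
            protein_amp = protein_amp, cloud_diam_nm = cloud_diam_nm,
            cloud_amp = cloud_amp,
            clusters_per_synapse = as.integer(clusters_per_synapse),
            cluster_radius_nm = cluster_radius_nm,
            cluster_sigma_nm = cluster_sigma_nm, cluster_amp = cluster_amp,
            enface_marker_sigma_nm = enface_marker_sigma_nm,
            enface_marker_amp = enface_marker_amp,
            enface_vesicle_sigma_nm = enface_vesicle_sigma_nm,
            psf_fwhm_nm = psf_fwhm_nm, background = background,
            poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
            seed = as.integer(seed))
  stopifnot(p$n_sideview >= 0, p$n_enface >= 0,
            p$n_sideview + p$n_enface >= 1,
            p$cell_px >= 16, p$lateral_nm > 0, p$psf_fwhm_nm >= 0,
            all(c(p$marker_amp, p$protein_amp, p$cloud_amp,
                  p$cluster_amp, p$enface_marker_amp) >= 0),
            p$poisson_scale >= 0, p$read_noise_sd >= 0,
            p$background >= 0)
  half_nm <- p$cell_px * p$lateral_nm / 2
  reach <- max(abs(p$delta_nm) + 3 * p$protein_sigma_nm,
               p$cloud_diam_nm / 2 + 0.8 * p$cloud_diam_nm,
               p$cluster_radius_nm + 4 * p$cluster_sigma_nm)
  if (reach > half_nm) {
    stop("synapse geometry (reach ", round(reach), " nm) would overlap the ",
         "cell border (half-size ", round(half_nm), " nm)")
  }
  structure(p, class = "synth_sted_params")
}

# Additive Poisson + gaussian read-noise model; both parameters 0 = identity.
apply_noise <- function(x, poisson_scale, read_noise_sd) {
  out <- x
  if (poisson_scale > 0) {
    out <- matrix(rpois(length(x), poisson_scale * as.vector(x)), nrow(x))
  }
  if (read_noise_sd > 0) {
    out <- out + matrix(rnorm(length(x), 0, read_noise_sd), nrow(x))
  }
  pmax(out, 0)
}

#' Generate a synthetic STED field with ground truth
#'
#' Renders the scene described by a [synth_sted_params()] object and returns
#' the calibrated [image_field()] (channels `az_marker`, `vesicle_marker`,
#' `protein_of_interest`) together with a ground-truth record listing every
#' placed object: per-synapse centers (0-based pixel coordinates), profile
#' axis angle, signed protein offset, the presynaptic sign convention
#' (the vesicle cloud always lies on the positive-offset side of the
#' profile axis), en-face cluster centers/radii/amplitudes, and the full
#' parameter set and seed.
#'
#' @param p A [synth_sted_params()] object.
#' @return A list with elements `field` (an `image_field`) and `truth`.
#' @export
generate_sted_field <- function(p) {
  stopifnot(inherits(p, "synth_sted_params"))
  with_seed(p$seed, {
    n_tot <- p$n_sideview + p$n_enface
    ncols <- ceiling(sqrt(n_tot))
    nrows <- ceiling(n_tot / ncols)
    cell <- p$cell_px
    nx <- ncols * cell
    ny <- nrows * cell
    nm <- p$lateral_nm
    chs <- list(az_marker = matrix(0, ny, nx),
                vesicle_marker = matrix(0, ny, nx),
                protein_of_interest = matrix(0, ny, nx))
    deltas <- rep(p$delta_nm, length.out = max(p$n_sideview, 1L))
    synapses <- vector("list", n_tot)
    fw2sd <- 1 / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    for (i in seq_len(n_tot)) {
      row <- (i - 1L) %/% ncols
      col <- (i - 1L) %% ncols
      # 0-based pixel coordinates of the cell-center pixel grid
      cx <- col * cell + (cell - 1) / 2
      cy <- row * cell + (cell - 1) / 2
      xs <- (col * cell):(col * cell + cell - 1L)
      ys <- (row * cell):(row * cell + cell - 1L)
      dxn <- (xs - cx) * nm  # nm offsets of pixel centers
      dyn_ <- (ys - cy) * nm
      gx <- matrix(dxn, length(ys), length(xs), byrow = TRUE)
      gy <- matrix(dyn_, length(ys), length(xs))
      if (i <= p$n_sideview) {
        ang <- runif(1, 0, pi)            # profile-axis direction
        delta <- deltas[i]
        u <- cos(ang) * gx + sin(ang) * gy   # along profile axis (+ = presyn)
        w <- -sin(ang) * gx + cos(ang) * gy  # along the marker bar
        s_l <- p$marker_length_nm * fw2sd
        s_w <- p$marker_width_nm * fw2sd
        s_c <- p$cloud_diam_nm * fw2sd
        u0 <- p$cloud_diam_nm / 2
        marker <- p$marker_amp * exp(-u^2 / (2 * s_w^2) - w^2 / (2 * s_l^2))
        protein <- p$protein_amp *
          exp(-(u - delta)^2 / (2 * p$protein_sigma_nm^2) -
                w^2 / (2 * s_l^2))
        cloud <- p$cloud_amp * exp(-((u - u0)^2 + w^2) / (2 * s_c^2))
        chs$az_marker[ys + 1L, xs + 1L] <-
          chs$az_marker[ys + 1L, xs + 1L] + marker
        chs$protein_of_interest[ys + 1L, xs + 1L] <-
          chs$protein_of_interest[ys + 1L, xs + 1L] + protein
        chs$vesicle_marker[ys + 1L, xs + 1L] <-
          chs$vesicle_marker[ys + 1L, xs + 1L] + cloud
        synapses[[i]] <- list(type = "sideview", center_px = c(x = cx, y = cy),
                              angle = ang, delta_nm = delta,
                              presynaptic_sign = 1L)
      } else {
        k <- p$clusters_per_synapse
        rot <- runif(1, 0, 2 * pi)
        angs <- rot + 2 * pi * (seq_len(k) - 1) / max(k, 1L) +
          runif(k, -0.2, 0.2)
        radii <- rep(p$cluster_radius_nm, length.out = k)
        cxs <- cx + radii * cos(angs) / nm
        cys <- cy + radii * sin(angs) / nm
        r2 <- gx^2 + gy^2
        marker <- p$enface_marker_amp *
          exp(-r2 / (2 * p$enface_marker_sigma_nm^2))
        vesicle <- p$cloud_amp * exp(-r2 / (2 * p$enface_vesicle_sigma_nm^2))
        protein <- matrix(0, cell, cell)
        for (j in seq_len(k)) {
          d2 <- (gx - (cxs[j] - cx) * nm)^2 + (gy - (cys[j] - cy) * nm)^2
          protein <- protein +
            p$cluster_amp * exp(-d2 / (2 * p$cluster_sigma_nm^2))
        }
        chs$az_marker[ys + 1L, xs + 1L] <-
          chs$az_marker[ys + 1L, xs + 1L] + marker
        chs$vesicle_marker[ys + 1L, xs + 1L] <-
          chs$vesicle_marker[ys + 1L, xs + 1L] + vesicle
        chs$protein_of_interest[ys + 1L, xs + 1L] <-
          chs$protein_of_interest[ys + 1L, xs + 1L] + protein
        synapses[[i]] <- list(type = "enface", center_px = c(x = cx, y = cy),
                              cluster_centers_px =
                                cbind(x = cxs, y = cys),
                              cluster_radii_nm = radii,
                              cluster_amp = rep(p$cluster_amp, k))
      }
    }
    sigma_px <- p$psf_fwhm_nm * fw2sd / nm
    for (role in names(chs)) {
      ch <- gauss_blur2d(chs[[role]], sigma_px) + p$background
      ch <- apply_noise(ch, p$poisson_scale, p$read_noise_sd)
      chs[[role]] <- quantize_storage(ch)  # emit at 16-bit camera depth
    }
    field <- image_field(chs, pixel_calibration(nm), id = "synth_sted")
    truth <- structure(list(kind = "sted", params = unclass(p),
                            seed = p$seed, synapses = synapses),
                       class = "ground_truth")
    list(field = field, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth (", x$kind, "): ", length(x$synapses %||% x$units),
      " object records, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize ground truth to JSON
#'
#' Raster-sized fields (true label images, footprints, noise-free channel
#' stacks) are omitted from the JSON record; they are reproducible from the
#' serialized parameters and seed.
#'
#' @param truth A `ground_truth` record.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$labels <- NULL
  x$footprint <- NULL
  x$band <- NULL
  x$clean <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}
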