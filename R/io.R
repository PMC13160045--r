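#' Save and load calibrated images as TIFF with a JSON sidecar
#'
#' Images are written as multi-page 16-bit TIFF (one page per channel, and
#' per slice for volumes, channel-major), with intensities mapped onto the
#' 16-bit sample grid by a per-channel power-of-two scale. Channel roles,
#' scales, calibration and stack depth go to a `<path>.json` sidecar. The
#' synthetic generators emit images already on this storage grid, so for
#' their scenes a write-then-reload round trip reproduces the pixel data
#' bit-for-bit; for arbitrary data, saving quantizes to 16-bit depth and
#' save-load-save is byte-identical.
#'
#' @param img An `image_field` or `image_volume`.
#' @param path Output TIFF path.
#' @return `save_field()` invisibly returns `path`; `load_field()` returns
#'   an `image_field` or `image_volume`.
#' @export
save_field <- function(img, path) {
  stopifnot(inherits(img, "image_field") || inherits(img, "image_volume"))
  is_vol <- inherits(img, "image_volume")
  pages <- list()
  scales <- numeric(0)
  for (role in names(img$channels)) {
    ch <- img$channels[[role]]
    scale <- storage_scale(ch)
    scales[role] <- scale
    if (is_vol) {
      for (z in seq_len(dim(ch)[3])) pages <- c(pages, list(ch[, , z] / scale))
    } else {
      pages <- c(pages, list(ch / scale))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    type = if (is_vol) "volume" else "field",
    id = img$id,
    roles = names(img$channels),
    scales = as.list(scales),
    nz = if (is_vol) dim(img$channels[[1]])[3] else 1L,
    calibration = list(lateral_nm = img$calibration$lateral_nm,
                       axial_nm = img$calibration$axial_nm)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_field
#' @param channel_map Character vector of channel roles in page order;
#'   required when no sidecar is present, must match the channel count.
#' @param calibration A [pixel_calibration()]; required when no sidecar is
#'   present. When both a sidecar and an argument are given, the argument
#'   wins and a warning is logged on mismatch.
#' @param volume Logical; declare the file volumetric (pages are z-slices of
#'   each channel). Taken from the sidecar when present.
#' @param nz Number of z-slices per channel for volumetric files without a
#'   sidecar.
#' @export
load_field <- function(path, channel_map = NULL, calibration = NULL,
                       volume = NULL, nz = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  divisor <- 2^info$bits.per.sample[1] - 1
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse any extra samples
    p / divisor  # back to the unit scale of the integer sample grid
  })
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (!is.null(meta)) {
    if (is.null(volume)) volume <- identical(meta$type, "volume")
    if (is.null(nz)) nz <- as.integer(meta$nz)
    if (is.null(channel_map)) channel_map <- unlist(meta$roles)
    axial <- meta$calibration$axial_nm
    if (!length(axial)) axial <- NULL
    cal_meta <- pixel_calibration(meta$calibration$lateral_nm,
                                  unlist(axial))
    if (is.null(calibration)) {
      calibration <- cal_meta
    } else if (!isTRUE(all.equal(calibration$lateral_nm,
                                 cal_meta$lateral_nm))) {
      warning("calibration argument (", calibration$lateral_nm,
              " nm/px) differs from file metadata (", cal_meta$lateral_nm,
              " nm/px); using the argument")
    }
    scales <- unlist(meta$scales)
  } else {
    if (is.null(channel_map) || is.null(calibration)) {
      stop("no sidecar: channel_map and calibration must be supplied")
    }
    if (is.null(volume)) volume <- FALSE
    if (is.null(nz)) nz <- 1L
    scales <- rep(1, length(channel_map))
    names(scales) <- channel_map
  }
  n_ch <- length(channel_map)
  expected <- if (volume) n_ch * nz else n_ch
  if (length(pages) != expected) {
    stop("channel-count mismatch: file has ", length(pages),
         " page(s) but channel map implies ", expected)
  }
  channels <- list()
  for (i in seq_len(n_ch)) {
    role <- channel_map[i]
    scale <- scales[[role]]
    if (volume) {
      idx <- (i - 1L) * nz + seq_len(nz)
      slices <- lapply(pages[idx], function(p) p * scale)
      channels[[role]] <- array(unlist(slices),
                                dim = c(dim(slices[[1]]), nz))
    } else {
      channels[[role]] <- pages[[i]] * scale
    }
  }
  id <- if (!is.null(meta)) meta$id else
    sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  if (volume) {
    image_volume(channels, calibration, id = id)
  } else {
    image_field(channels, calibration, id = id)
  }
}

#' Write a result table with run metadata
#'
#' Writes a UTF-8 CSV (header row, one record per entity) and a JSON
#' metadata sidecar recording the configuration hash, seed and package
#' version, so every table is traceable to the run that produced it.
#'
#' @param df A data frame; an `image_id` column identifies the source image
#'   of every row.
#' @param path Output CSV path.
#' @param cfg The [experiment_config()] of the run.
#' @return Invisibly, the path.
#' @export
write_result_table <- function(df, path, cfg = NULL) {
  stopifnot(is.data.frame(df))
  if (!"image_id" %in% names(df)) {
    stop("result tables must carry an 'image_id' column")
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(
    config_hash = if (!is.null(cfg)) config_hash(cfg) else NA,
    seed = if (!is.null(cfg)) cfg$rng_seed else NA,
    software = as.character(utils::packageVersion("perizone")),
    n_rows = nrow(df),
    columns = names(df)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  write_config(cfg, tf)
  unname(tools::md5sum(tf))
}
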