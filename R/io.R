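# TIFF + JSON-sidecar IO. TIFF stores normalized [0, 1] float32 pages;
# the affine de-normalization (offset, scale) and physical metadata live
# in the sidecar, so round trips are exact to float32 precision.

sidecar_path <- function(path) paste0(path, ".json")

write_scaled_tiff <- function(arr_list, path, meta) {
  lo <- min(vapply(arr_list, min, 0))
  hi <- max(vapply(arr_list, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(arr_list, function(m) (m - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta$offset <- lo
  meta$scale <- scale
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_sidecar <- function(path, required) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar ", sc, "; required keys: ",
         paste(required, collapse = ", "))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    stop("sidecar ", sc, " lacks required keys: ",
         paste(missing, collapse = ", "))
  meta
}

read_scaled_tiff <- function(path, required) {
  meta <- read_sidecar(path, c(required, "offset", "scale"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) m * meta$scale + meta$offset)
  list(pages = pages, meta = meta)
}

#' Read and write tomograms, hologram sets and phase maps
#'
#' Tomograms are stored as multi-page 32-bit float TIFF (pages are
#' z-slices) with voxel size, medium RI and origin in a JSON sidecar
#' (`<path>.json`); hologram sets add per-frame illumination directions,
#' wavelength and carrier; phase maps store radians. A missing or
#' incomplete sidecar is an error naming the required keys.
#'
#' @param tom,hs,pm object to write.
#' @param path TIFF file path.
#' @return the path (writers) or the reconstructed object (readers).
#' @export
write_tomogram <- function(tom, path) {
  stopifnot(inherits(tom, "ri_tomogram"))
  nz <- dim(tom$values)[3]
  pages <- lapply(seq_len(nz), function(k) tom$values[, , k])
  write_scaled_tiff(pages, path, list(
    kind = "ri_tomogram", voxel_size_um = tom$voxel_size,
    medium_ri = tom$medium_ri, origin_um = tom$origin))
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  r <- read_scaled_tiff(path, c("voxel_size_um", "medium_ri"))
  vals <- array(unlist(r$pages),
                dim = c(dim(r$pages[[1]]), length(r$pages)))
  origin <- r$meta$origin_um
  if (is.null(origin)) origin <- c(0, 0, 0)
  ri_tomogram(vals, r$meta$voxel_size_um, r$meta$medium_ri,
              origin = origin, tol = 0.05)
}

#' @rdname write_tomogram
#' @export
write_hologram_set <- function(hs, path) {
  stopifnot(inherits(hs, "hologram_set"))
  write_scaled_tiff(hs$frames, path, list(
    kind = "hologram_set", pixel_size_um = hs$pixel_size,
    wavelength_um = hs$wavelength, medium_ri = hs$medium_ri,
    carrier_frequency_cyc_um = hs$carrier_frequency,
    illum_dirs = hs$illum_dirs))
}

#' @rdname write_tomogram
#' @export
read_hologram_set <- function(path) {
  r <- read_scaled_tiff(path, c("pixel_size_um", "wavelength_um",
                                "medium_ri", "illum_dirs"))
  dirs <- matrix(unlist(r$meta$illum_dirs), ncol = 3)
  colnames(dirs) <- c("sx", "sy", "sz")
  fc <- r$meta$carrier_frequency_cyc_um
  frames <- lapply(seq_along(r$pages), function(k) {
    fr <- pmax(r$pages[[k]], 0)
    structure(fr, illum_dir = dirs[k, ],
              pixel_size = r$meta$pixel_size_um,
              carrier_frequency = fc)
  })
  hologram_set(frames, dirs, r$meta$pixel_size_um, r$meta$wavelength_um,
               r$meta$medium_ri, fc)
}

#' @rdname write_tomogram
#' @export
write_phase_map <- function(pm, path) {
  stopifnot(inherits(pm, "phase_map"))
  write_scaled_tiff(list(pm$phase), path, list(
    kind = "phase_map", pixel_size_um = pm$pixel_size,
    wavelength_um = pm$wavelength, source = pm$source))
}

#' @rdname write_tomogram
#' @export
read_phase_map <- function(path) {
  r <- read_scaled_tiff(path, c("pixel_size_um"))
  wl <- r$meta$wavelength_um
  phase_map(r$pages[[1]], r$meta$pixel_size_um,
            source = if (is.null(r$meta$source)) "measured" else r$meta$source,
            wavelength = if (is.null(wl)) NA_real_ else wl)
}

#' Write and read measurement records as CSV
#'
#' Columns carry unit suffixes (`volume_um3`, `concentration_fg_um3`, ...)
#' so the file is self-describing.
#'
#' @param records data.frame of measurements.
#' @param path CSV path.
#' @export
write_measurements <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("morphometric_record", class(out))
  out
}

#' Serialize a design or population specification as YAML
#' @param x a `sperm_design` or `breed_population_spec`.
#' @param path YAML path.
#' @export
write_design_yaml <- function(x, path) {
  if (inherits(x, "sperm_design")) {
    yaml::write_yaml(list(kind = "sperm_design", fields = unclass(x)), path)
  } else if (inherits(x, "breed_population_spec")) {
    groups <- lapply(x$groups, function(g) list(
      mean = unclass(if (inherits(g$mean, "sperm_design")) g$mean
                     else as.list(g$mean)),
      sd = as.list(g$sd)))
    yaml::write_yaml(list(kind = "breed_population_spec", groups = groups,
                          n_per_group = x$n_per_group, seed = x$seed), path)
  } else stop("unsupported object")
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$kind, "sperm_design")) {
    do.call(sperm_design, y$fields)
  } else if (identical(y$kind, "breed_population_spec")) {
    groups <- lapply(y$groups, function(g) list(
      mean = do.call(sperm_design, g$mean), sd = unlist(g$sd)))
    breed_population_spec(groups, y$n_per_group, y$seed)
  } else stop("unknown YAML kind: ", y$kind)
}
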