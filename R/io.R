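# Multi-page 32-bit-float TIFF persistence with a JSON sidecar carrying the
# numeric metadata (spacing, angles, energy tags). The sidecar lives at
# "<path>.json".

.sidecar_path <- function(path) paste0(path, ".json")

# TIFF storage holds [0,1]; data are affinely mapped there and the original
# range travels in the sidecar
.write_pages <- function(arr3d, path) {
  lo <- min(arr3d); hi <- max(arr3d)
  scaled <- if (hi > lo) (arr3d - lo) / (hi - lo) else arr3d * 0
  pages <- lapply(seq_len(dim(scaled)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  c(lo = lo, hi = hi)
}

.read_pages <- function(path, rng) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages)
  arr * (rng[2] - rng[1]) + rng[1]
}

#' Write / read a reconstructed volume as multi-page TIFF
#'
#' Slices (third axis) become TIFF pages; grid spacing and shape go to a
#' JSON sidecar next to the file.
#'
#' @param volume a [recon_volume()].
#' @param path output `.tif` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   the [recon_volume()] (without geometry).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  rng <- .write_pages(volume$values, path)
  jsonlite::write_json(
    list(kind = "recon_volume", shape = volume$grid$shape,
         spacing = volume$grid$spacing, range = unname(rng)),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "recon_volume"))
  vals <- .read_pages(path, meta$range)
  recon_volume(vals, recon_grid(meta$shape, meta$spacing))
}

#' Write / read a projection stack as multi-page TIFF
#'
#' Frames become TIFF pages; geometry and energy metadata go to a JSON
#' sidecar.
#'
#' @param stack a [projection_stack()].
#' @param path output `.tif` path.
#' @return `write_stack` returns `path` invisibly; `read_stack` the
#'   [projection_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "projection_stack"))
  rng <- .write_pages(stack$frames, path)
  g <- stack$geometry
  jsonlite::write_json(
    list(kind = "projection_stack", energy_tag = stack$energy_tag,
         energy_kev = stack$energy_kev, range = unname(rng),
         geometry = list(sid = g$sid, sdd = g$sdd, swing_deg = g$swing_deg,
                         n_views = g$n_views,
                         detector_shape = g$detector_shape, pitch = g$pitch,
                         sweep_axis = g$sweep_axis)),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "projection_stack"))
  gm <- meta$geometry
  geom <- acquisition_geometry("desk", sid = gm$sid, sdd = gm$sdd,
                               swing_deg = gm$swing_deg,
                               n_views = gm$n_views,
                               detector_shape = gm$detector_shape,
                               pitch = gm$pitch, sweep_axis = gm$sweep_axis)
  frames <- .read_pages(path, meta$range)
  ekev <- if (is.null(meta$energy_kev) || is.na(meta$energy_kev))
    NA_real_ else meta$energy_kev
  projection_stack(frames, geom, meta$energy_tag, ekev)
}
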