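## File formats. Volumes: NIfTI (via RNifti) or raw little-endian float32
## with a JSON sidecar; sinograms: raw little-endian float32 + JSON sidecar
## (datasets: values in column-major [angle, radial, plane, tof] order).
## Format headers are versioned; readers reject unknown major versions.

.format_version <- "1.0"

check_format_version <- function(meta, what) {
  v <- meta$format_version
  if (is.null(v)) stop(what, ": missing format_version")
  if (strsplit(v, ".", fixed = TRUE)[[1]][1] !=
      strsplit(.format_version, ".", fixed = TRUE)[[1]][1])
    stop(what, ": unsupported format major version ", v)
}

#' Write / read a scanner parameter file (JSON)
#'
#' The scanner file holds the geometry (explicit crystal coordinates in mm,
#' crystals per ring, ring count) and the energy/timing specifications.
#' Units are documented in the file itself. Reading validates the schema
#' and the geometric invariants (crystal count, common axial coordinate per
#' ring, energy window around 511 keV).
#'
#' @param scanner A scanner model.
#' @param path Output/input file path.
#' @return `write_scanner_json` the path invisibly; `read_scanner_json` a
#'   scanner model.
#' @export
write_scanner_json <- function(scanner, path) {
  obj <- list(
    format_version = .format_version,
    units = list(position = "mm", energy = "keV", time = "ps"),
    geometry = list(crystal_positions = unname(scanner$crystal_xyz),
                    crystals_per_ring = scanner$crystals_per_ring,
                    n_rings = scanner$n_rings,
                    ring_radius_mm = scanner$ring_radius_mm,
                    axial_pitch_mm = scanner$axial_pitch_mm),
    specs = scanner$specs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scanner_json
#' @export
read_scanner_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_format_version(obj, "scanner file")
  g <- obj$geometry
  required <- c("crystal_positions", "crystals_per_ring", "n_rings")
  if (!all(required %in% names(g)))
    stop("scanner file: geometry must contain ",
         paste(required, collapse = ", "))
  xyz <- as.matrix(g$crystal_positions)
  if (nrow(xyz) != g$crystals_per_ring * g$n_rings)
    stop("scanner file: crystal count != crystals_per_ring * n_rings")
  sp <- obj$specs
  sp$energy_uld_kev <- if (is.null(sp$energy_uld_kev)) Inf else
    as.numeric(sp$energy_uld_kev)
  specs <- scanner_specs(sp$energy_resolution_fwhm, sp$energy_lld_kev,
                         sp$energy_uld_kev, sp$tof_resolution_ps,
                         sp$tof_range_ps, sp$n_tof_bins,
                         sp$max_ring_difference)
  sc <- build_ring_scanner(g$crystals_per_ring, g$n_rings,
                           g$ring_radius_mm %||% sqrt(sum(xyz[1, 1:2]^2)),
                           g$axial_pitch_mm %||% 4, specs)
  ## adopt the file's explicit coordinates and check ring structure
  sc$crystal_xyz <- xyz
  ring_z <- matrix(xyz[, 3], nrow = g$crystals_per_ring)
  if (any(apply(ring_z, 2, function(z) diff(range(z))) > 1e-6))
    stop("scanner file: crystals of one ring must share an axial coordinate")
  sc$ring_z <- ring_z[1, ]
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a voxel volume
#'
#' `format = "nifti"` uses NIfTI-1 via RNifti (voxel size in the header;
#' the origin is carried in an accompanying `<path>.json` sidecar).
#' `format = "rawf32"` writes raw little-endian float32 plus a JSON sidecar
#' with dimensions and geometry, a toolchain-free plain dialect.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path (extension left to the caller).
#' @param format `"nifti"` or `"rawf32"`.
#' @return Path (write) or [voxel_volume()] (read).
#' @export
write_volume <- function(volume, path, format = c("nifti", "rawf32")) {
  format <- match.arg(format)
  meta <- list(format_version = .format_version,
               dim = dim(volume$values),
               voxel_size_mm = volume$voxel_size,
               origin_mm = volume$origin,
               quantity = volume$quantity)
  if (format == "nifti") {
    img <- RNifti::asNifti(volume$values)
    RNifti::pixdim(img) <- volume$voxel_size
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(volume$values), con, size = 4, endian = "little")
    close(con)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = c("nifti", "rawf32")) {
  format <- match.arg(format)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_format_version(meta, "volume file")
  if (format == "nifti") {
    vals <- array(as.numeric(RNifti::readNifti(path)), meta$dim)
  } else {
    con <- file(path, "rb")
    vals <- array(readBin(con, "numeric", prod(meta$dim), size = 4,
                          endian = "little"), meta$dim)
    close(con)
  }
  voxel_volume(vals, meta$voxel_size_mm, meta$origin_mm, meta$quantity)
}

#' Write / read a TOF sinogram container
#'
#' Raw little-endian float32 values in column-major
#' `[angle, radial, plane, tof]` order, plus a JSON sidecar with the shape,
#' TOF bin edges, plane table, kind, and the TOF sign convention
#' (`t = t_A - t_B`, bin 1 at the most negative edge).
#'
#' @param sinogram A [tof_sinogram()].
#' @param path Output path.
#' @param scanner Scanner model used to rebuild the index on read.
#' @return Path (write) or [tof_sinogram()] (read).
#' @export
write_sinogram <- function(sinogram, path) {
  meta <- list(format_version = .format_version,
               dim = dim(sinogram$values),
               tof_bin_edges_ps = sinogram$tof_bin_edges,
               tof_convention = "t = t_A - t_B; bin 1 at most negative edge",
               plane_table = sinogram$index$plane_table,
               kind = sinogram$kind)
  con <- file(path, "wb")
  writeBin(as.numeric(sinogram$values), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path, scanner) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_format_version(meta, "sinogram file")
  index <- sinogram_index(scanner)
  if (!identical(unname(as.matrix(index$plane_table)),
                 unname(as.matrix(meta$plane_table))))
    stop("sinogram file: plane table does not match the scanner")
  con <- file(path, "rb")
  vals <- array(readBin(con, "numeric", prod(meta$dim), size = 4,
                        endian = "little"), meta$dim)
  close(con)
  tof_sinogram(vals, index, meta$tof_bin_edges_ps, meta$kind)
}

#' Write a provenance manifest
#'
#' JSON manifest for a pipeline output: parameters, input file checksums
#' (MD5, where inputs are files), and the package version, so any output
#' can be regenerated from its manifest alone.
#'
#' @param manifest Named list (e.g. from [run_scatter_estimation()]).
#' @param path Output path.
#' @param input_files Optional character vector of input paths to checksum.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path, input_files = character(0)) {
  if (length(input_files))
    manifest$input_md5 <- as.list(tools::md5sum(input_files))
  manifest$format_version <- .format_version
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
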