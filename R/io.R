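#' Write / read an aperture sequence as NIfTI
#'
#' Frames are stored as an `H x W x T` volume with the frame duration in the
#' time pixdim; grid coordinates are reconstructed from a JSON sidecar
#' written next to the volume (degrees, x right-positive, y up-positive).
#'
#' @param aperture an [ApertureSequence-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `writeApertureNifti` the path, invisibly; `readApertureNifti` an
#'   [ApertureSequence-class].
#' @name apertureNifti
NULL

#' @rdname apertureNifti
#' @export
writeApertureNifti <- function(aperture, path) {
  stopifnot(is(aperture, "ApertureSequence"))
  vol <- .framesToVolume(aperture@frames)
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(
    mean(diff(aperture@gridY)), mean(diff(aperture@gridX)),
    aperture@frameDuration)), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(
    gridX = aperture@gridX, gridY = aperture@gridY,
    frameDuration = aperture@frameDuration,
    convention = "degrees; x right-positive; y up-positive; bands half-open"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# T x H x W  <->  H x W x T
.framesToVolume <- function(frames) aperm(frames, c(2, 3, 1))
.volumeToFrames <- function(vol) aperm(vol, c(3, 1, 2))

#' @rdname apertureNifti
#' @export
readApertureNifti <- function(path) {
  vol <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  ap <- new("ApertureSequence", frames = .volumeToFrames(vol),
            gridX = meta$gridX, gridY = meta$gridY,
            frameDuration = meta$frameDuration)
  validObject(ap)
  ap
}

#' Write / read streamlines in MRtrix TCK format
#'
#' Standard TCK layout: a text header (`mrtrix tracks`, key: value lines,
#' `END`), then little-endian Float32 point triplets with NaN triplets
#' separating streamlines and an Inf triplet terminating the file.
#'
#' @param connectome a [Connectome-class].
#' @param path `.tck` file path.
#' @return `writeTCK` the path, invisibly; `readTCK` a
#'   [Connectome-class].
#' @name tck
NULL

#' @rdname tck
#' @export
writeTCK <- function(connectome, path) {
  stopifnot(is(connectome, "Connectome"))
  counts <- connectome@counts
  # header with a fixed-width 'file:' offset so its own length is stable
  render <- function(offStr) paste0(paste(c(
    "mrtrix tracks",
    "datatype: Float32LE",
    paste0("count: ", length(counts)),
    paste0("file: . ", offStr),
    "END"), collapse = "\n"), "\n")
  off <- nchar(render(sprintf("%06d", 0)), type = "bytes")
  hdr <- render(sprintf("%06d", off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  offsets <- streamlineOffsets(counts)
  for (i in seq_along(counts)) {
    seg <- connectome@points[offsets[i]:(offsets[i] + counts[i] - 1L), ,
                             drop = FALSE]
    writeBin(as.vector(t(seg)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname tck
#' @export
readTCK <- function(path) {
  if (!file.exists(path)) stop("no such TCK file: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  # locate the END marker in the text header without decoding the binary tail
  headLen <- min(length(bytes), 4096L)
  marker <- charToRaw("END\n")
  hdrEnd <- NA_integer_
  for (i in seq_len(headLen - 3L)) {
    if (identical(bytes[i:(i + 3L)], marker)) { hdrEnd <- i; break }
  }
  if (is.na(hdrEnd)) stop("malformed TCK: header not terminated")
  hdr <- strsplit(rawToChar(bytes[seq_len(hdrEnd + 3L)]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks") stop("not a TCK file")
  fileLine <- grep("^file: ", hdr, value = TRUE)
  off <- as.integer(sub("^file: \\. *", "", fileLine))
  raw <- readBin(bytes[(off + 1):length(bytes)], "numeric",
                 n = (length(bytes) - off) %/% 4, size = 4,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  isNaN3 <- rowSums(is.na(m)) == 3L
  isInf3 <- rowSums(is.infinite(m)) == 3L
  stop_at <- which(isInf3)[1]
  if (!is.na(stop_at)) m <- m[seq_len(stop_at - 1L), , drop = FALSE]
  isNaN3 <- rowSums(is.na(m)) == 3L
  id <- cumsum(c(TRUE, isNaN3[-length(isNaN3)]))
  keep <- !isNaN3
  counts <- as.integer(table(id[keep]))
  new("Connectome", points = m[keep, , drop = FALSE], counts = counts,
      metadata = list(source = path))
}

#' Write / read an eccentricity surface as a TSV vertex table
#'
#' Columns `x`, `y`, `z` (mm) and `eccentricity` (degrees).
#'
#' @param surface an [EccSurface-class].
#' @param path TSV path.
#' @return `writeSurfaceTSV` the path invisibly; `readSurfaceTSV` an
#'   [EccSurface-class].
#' @name surfaceTSV
NULL

#' @rdname surfaceTSV
#' @export
writeSurfaceTSV <- function(surface, path) {
  stopifnot(is(surface, "EccSurface"))
  utils::write.table(
    data.frame(x = surface@vertices[, 1], y = surface@vertices[, 2],
               z = surface@vertices[, 3],
               eccentricity = surface@eccentricity),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname surfaceTSV
#' @export
readSurfaceTSV <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new("EccSurface", vertices = as.matrix(d[, c("x", "y", "z")]),
      eccentricity = d$eccentricity, spacing = NA_real_)
}

#' Write / read band proportions as TSV
#'
#' @param proportions result of [centerBandProportions()] or
#'   [endpointBandProportions()].
#' @param bands the [EccBands-class] the proportions refer to.
#' @param path TSV path.
#' @return `writeBandProportionsTSV` the path invisibly;
#'   `readBandProportionsTSV` a data.frame with `bandLo`, `bandHi`,
#'   `fraction`.
#' @name bandTSV
NULL

#' @rdname bandTSV
#' @export
writeBandProportionsTSV <- function(proportions, bands, path) {
  e <- bands@edges
  utils::write.table(
    data.frame(bandLo = e[-length(e)], bandHi = e[-1],
               fraction = proportions$fractions),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bandTSV
#' @export
readBandProportionsTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop("config must be YAML or JSON")
}

#' Write a run configuration
#'
#' @param config named list.
#' @param path `.yaml`/`.yml` or `.json` target.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("config must be YAML or JSON")
  invisible(path)
}
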