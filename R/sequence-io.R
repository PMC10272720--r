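#' @include AllClasses.R
NULL

#' Read an angiographic frame sequence
#'
#' Reads a cine sequence into an [AngioSequence-class] from either
#' \itemize{
#'   \item a multi-frame DICOM file (uncompressed, little endian),
#'   \item a directory of single-frame DICOM files (sorted by Instance
#'         Number), or
#'   \item a directory image stack: numbered 16-bit TIFF frames plus a
#'         plain-text `metadata.txt` sidecar with `fps:` and `resolution:`
#'         entries.
#' }
#'
#' Metadata resolution order is: explicit argument override, then the
#' DICOM Frame Time attribute (fps = 1000 / frame time, rounded to 2
#' decimals), then Cine Rate; spatial resolution comes from Pixel Spacing,
#' then Imager Pixel Spacing.  Missing metadata with no override is an
#' error.  Pixel values are never rescaled or inverted: whatever intensity
#' the file stores is the analysis signal, in the convention that contrast
#' medium lowers intensity.
#'
#' @param path file or directory path.
#' @param fps optional frame-rate override (frames/s).
#' @param resolution optional spatial-resolution override (mm/px).
#' @return An [AngioSequence-class].
#' @examples
#' cfg <- phantomConfig(shape = c(64, 160), vesselRadiusPx = 6,
#'                      bolusVelocity = 120, nPulses = 1, noiseSd = 0)
#' ph <- generatePhantom(cfg)
#' dir <- file.path(tempdir(), "stackdemo")
#' writeSequence(ph$sequence, dir, format = "image_stack")
#' seq2 <- readSequence(dir)
#' stopifnot(identical(frames(seq2), frames(ph$sequence)))
#' @export
readSequence <- function(path, fps = NULL, resolution = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) {
    dcm <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
    if (length(dcm)) .readDicomSeries(dcm, fps, resolution)
    else .readImageStack(path, fps, resolution)
  } else {
    .readDicomMultiframe(path, fps, resolution)
  }
}

.resolveMeta <- function(fpsOverride, resOverride, fpsFile, resFile) {
  fps <- if (!is.null(fpsOverride)) fpsOverride else fpsFile
  res <- if (!is.null(resOverride)) resOverride else resFile
  if (is.null(fps)) stop("missing fps: not in file metadata and no override")
  if (is.null(res))
    stop("missing resolution: not in file metadata and no override")
  list(fps = as.numeric(fps), resolution = as.numeric(res))
}

.readDicomMultiframe <- function(path, fps, resolution) {
  el <- .parseDicom(path)
  fr <- .dicomToFrames(el, path)
  if (dim(fr)[3L] < 2L) stop("sequence must have at least 2 frames: ", path)
  meta <- .resolveMeta(fps, resolution, .dicomFps(el), .dicomResolution(el))
  AngioSequence(fr, meta$fps, meta$resolution)
}

.readDicomSeries <- function(files, fps, resolution) {
  parsed <- lapply(files, .parseDicom)
  inst <- vapply(parsed, function(el) {
    if ("00200013" %in% names(el)) el[["00200013"]][1L] else NA_integer_
  }, integer(1L))
  ord <- order(inst, files)
  parsed <- parsed[ord]; files <- files[ord]
  framesList <- mapply(.dicomToFrames, parsed, files, SIMPLIFY = FALSE)
  shapes <- vapply(framesList, function(f) dim(f)[1:2], integer(2L))
  if (any(shapes[1L, ] != shapes[1L, 1L]) ||
      any(shapes[2L, ] != shapes[2L, 1L]))
    stop("inconsistent frame shapes across DICOM series")
  fr <- array(0L, dim = c(shapes[1L, 1L], shapes[2L, 1L],
                          sum(vapply(framesList, function(f) dim(f)[3L],
                                     integer(1L)))))
  t0 <- 0L
  for (f in framesList) {
    nt <- dim(f)[3L]
    fr[, , (t0 + 1L):(t0 + nt)] <- f
    t0 <- t0 + nt
  }
  if (dim(fr)[3L] < 2L) stop("sequence must have at least 2 frames")
  meta <- .resolveMeta(fps, resolution, .dicomFps(parsed[[1L]]),
                       .dicomResolution(parsed[[1L]]))
  AngioSequence(fr, meta$fps, meta$resolution)
}

.readSidecar <- function(dir) {
  f <- file.path(dir, "metadata.txt")
  if (!file.exists(f)) return(list(fps = NULL, resolution = NULL))
  lines <- readLines(f, warn = FALSE)
  getv <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*:"), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    as.numeric(trimws(sub("^[^:]*:", "", hit[1L])))
  }
  list(fps = getv("fps"), resolution = getv("resolution"))
}

.readImageStack <- function(dir, fps, resolution) {
  files <- list.files(dir, pattern = "\\.(tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no TIFF frames found in image stack: ", dir)
  files <- sort(files)
  mats <- lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
  shapes <- vapply(mats, dim, integer(2L))
  if (any(shapes[1L, ] != shapes[1L, 1L]) ||
      any(shapes[2L, ] != shapes[2L, 1L]))
    stop("inconsistent frame shapes in image stack")
  if (length(mats) < 2L) stop("sequence must have at least 2 frames")
  fr <- array(0L, dim = c(shapes[1L, 1L], shapes[2L, 1L], length(mats)))
  for (t in seq_along(mats)) fr[, , t] <- mats[[t]]
  side <- .readSidecar(dir)
  meta <- .resolveMeta(fps, resolution, side$fps, side$resolution)
  AngioSequence(fr, meta$fps, meta$resolution)
}

#' Write an angiographic frame sequence
#'
#' Writes an [AngioSequence-class] either as a single multi-frame DICOM file
#' or as a directory image stack of 16-bit TIFF frames plus a plain-text
#' `metadata.txt` sidecar.  Both formats round-trip integer pixel data
#' bit-exactly and metadata to within 1e-6; intensities must lie in
#' 0..65535.
#'
#' @param seq an [AngioSequence-class].
#' @param path output file (dicom) or directory (image_stack).
#' @param format `"dicom"` or `"image_stack"`.
#' @return `path`, invisibly.
#' @export
writeSequence <- function(seq, path, format = c("image_stack", "dicom")) {
  stopifnot(is(seq, "AngioSequence"))
  format <- match.arg(format)
  fr <- frames(seq)
  if (min(fr) < 0 || max(fr) > 65535 || any(fr != round(fr)))
    stop("writeSequence requires integer intensities in 0..65535")
  if (format == "dicom") {
    .writeDicom(seq, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nt <- dim(fr)[3L]
    for (t in seq_len(nt)) {
      tiff::writeTIFF(fr[, , t] / 65535,
                      file.path(path, sprintf("frame_%04d.tif", t)),
                      bits.per.sample = 16L)
    }
    writeLines(c(sprintf("fps: %.10g", fps(seq)),
                 sprintf("resolution: %.10g", resolution(seq))),
               file.path(path, "metadata.txt"))
  }
  invisible(path)
}
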