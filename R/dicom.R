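# Minimal DICOM support for multi-frame grayscale secondary-capture objects:
# uncompressed pixel data, explicit or implicit VR little endian.  Covers the
# attributes the velocimetry needs (geometry, frame timing, pixel spacing,
# pixel data); vendor private tags and compressed transfer syntaxes are out
# of scope.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.SOP_MF_GRAYSCALE_SC <- "1.2.840.10008.5.1.4.1.1.7.2"

# VR lookup for implicit-VR parsing of the tags we interpret
.DICOM_DICT <- c(
  "00080016" = "UI", "00080018" = "UI", "00080060" = "CS",
  "00180040" = "IS", "00181063" = "DS", "00181164" = "DS",
  "00200013" = "IS",
  "00280002" = "US", "00280004" = "CS", "00280008" = "IS",
  "00280010" = "US", "00280011" = "US", "00280030" = "DS",
  "00280100" = "US", "00280101" = "US", "00280102" = "US",
  "00280103" = "US",
  "7FE00010" = "OW")

.u16raw <- function(x) {
  x <- as.integer(round(x))
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}

.u32raw <- function(x) {
  writeBin(as.integer(round(x)), raw(), size = 4L, endian = "little")
}

.padEven <- function(val, padByte) {
  if (length(val) %% 2L == 1L) c(val, padByte) else val
}

.dcmElement <- function(group, element, vr, val) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (long) {
    c(.u16raw(group), .u16raw(element), charToRaw(vr), as.raw(c(0L, 0L)),
      .u32raw(length(val)), val)
  } else {
    c(.u16raw(group), .u16raw(element), charToRaw(vr),
      .u16raw(length(val)), val)
  }
}

.dcmString <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  .dcmElement(group, element, vr, .padEven(charToRaw(s), pad))
}

.dcmUS <- function(group, element, x) .dcmElement(group, element, "US",
                                                  .u16raw(x))

# Deterministic content-derived UID suffix (FNV-1a over a numeric summary)
.uidSuffix <- function(frames) {
  h <- 2166136261
  probe <- c(dim(frames), sum(as.numeric(frames[1, , 1])),
             sum(as.numeric(frames[dim(frames)[1L], , dim(frames)[3L]])))
  for (v in probe) {
    for (ch in utf8ToInt(format(v, digits = 12))) {
      h <- bitwXor(as.integer(h %% 2147483647), ch) * 16777619
      h <- h %% 2147483647
    }
  }
  sprintf("%d", as.integer(h))
}

#' Write an AngioSequence as a multi-frame DICOM file
#'
#' Writes an uncompressed multi-frame grayscale secondary-capture DICOM
#' object (explicit VR little endian, 16-bit unsigned pixels).  Frame timing
#' is stored as Frame Time (0018,1063) in ms (plus Cine Rate (0018,0040)
#' when the frame rate is a whole number) and the spatial resolution as
#' Pixel Spacing (0028,0030) and Imager Pixel Spacing (0018,1164).
#'
#' @param seq an [AngioSequence-class]; intensities must lie in 0..65535.
#' @param path output file path.
#' @return `path`, invisibly.
#' @keywords internal
.writeDicom <- function(seq, path) {
  fr <- frames(seq)
  if (min(fr) < 0 || max(fr) > 65535)
    stop("DICOM writer requires intensities in 0..65535")
  d <- dim(fr)
  nbytes <- prod(d) * 2
  if (nbytes >= 2^31) stop("pixel data too large for a single DICOM object")

  sopInstance <- paste0("1.2.826.0.1.3680043.8.498.", .uidSuffix(fr))
  ts <- .TS_EXPLICIT_LE

  meta <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcmString(0x0002, 0x0002, "UI", .SOP_MF_GRAYSCALE_SC),
    .dcmString(0x0002, 0x0003, "UI", sopInstance),
    .dcmString(0x0002, 0x0010, "UI", ts))
  metaGroupLen <- .dcmElement(0x0002, 0x0000, "UL", .u32raw(length(meta)))

  # pixel order: row-major within each frame, frames concatenated
  pix <- integer(prod(d))
  ofs <- 0L
  perFrame <- d[1L] * d[2L]
  for (t in seq_len(d[3L])) {
    pix[(ofs + 1L):(ofs + perFrame)] <- as.integer(t(fr[, , t]))
    ofs <- ofs + perFrame
  }
  pixRaw <- .u16raw(pix)

  dsFmt <- function(x) format(x, digits = 10, scientific = FALSE)
  body <- c(
    .dcmString(0x0008, 0x0016, "UI", .SOP_MF_GRAYSCALE_SC),
    .dcmString(0x0008, 0x0018, "UI", sopInstance),
    .dcmString(0x0008, 0x0060, "CS", "XA"),
    if (abs(fps(seq) - round(fps(seq))) < 1e-9)
      .dcmString(0x0018, 0x0040, "IS", sprintf("%d", as.integer(round(fps(seq))))),
    .dcmString(0x0018, 0x1063, "DS", dsFmt(1000 / fps(seq))),
    .dcmString(0x0018, 0x1164, "DS",
               paste(dsFmt(resolution(seq)), dsFmt(resolution(seq)),
                     sep = "\\")),
    .dcmString(0x0020, 0x0013, "IS", "1"),
    .dcmUS(0x0028, 0x0002, 1L),
    .dcmString(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcmString(0x0028, 0x0008, "IS", sprintf("%d", d[3L])),
    .dcmUS(0x0028, 0x0010, d[1L]),
    .dcmUS(0x0028, 0x0011, d[2L]),
    .dcmString(0x0028, 0x0030, "DS",
               paste(dsFmt(resolution(seq)), dsFmt(resolution(seq)),
                     sep = "\\")),
    .dcmUS(0x0028, 0x0100, 16L),
    .dcmUS(0x0028, 0x0101, 16L),
    .dcmUS(0x0028, 0x0102, 15L),
    .dcmUS(0x0028, 0x0103, 0L),
    .dcmElement(0x7FE0, 0x0010, "OW", pixRaw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(metaGroupLen, meta, body), con)
  invisible(path)
}

.rdU16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", n = 1L, size = 2L,
          signed = FALSE, endian = "little")
}

.rdU32 <- function(bytes, pos) {
  v <- readBin(bytes[pos:(pos + 3L)], "integer", n = 1L, size = 4L,
               endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

.rawToStr <- function(val) {
  val <- val[val != as.raw(0L)]
  trimws(rawToChar(val))
}

.decodeValue <- function(vr, val) {
  switch(vr,
    US = readBin(val, "integer", n = length(val) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = .rdU32(val, 1L),
    DS = as.numeric(strsplit(.rawToStr(val), "\\", fixed = TRUE)[[1L]]),
    IS = as.integer(strsplit(.rawToStr(val), "\\", fixed = TRUE)[[1L]]),
    UI = , CS = , LO = , SH = , PN = .rawToStr(val),
    val)
}

# Parse one DICOM file into a named list of decoded elements.
.parseDicom <- function(path) {
  n <- file.info(path)$size
  con <- file(path, "rb")
  bytes <- readBin(con, raw(), n = n)
  close(con)

  pos <- 1L
  if (n > 132L && rawToChar(bytes[129:132]) == "DICM") pos <- 133L

  out <- list()
  explicit <- TRUE   # file meta is always explicit VR LE
  ts <- .TS_EXPLICIT_LE
  metaDone <- FALSE
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  while (pos + 7L <= n) {
    group <- .rdU16(bytes, pos); element <- .rdU16(bytes, pos + 2L)
    if (!metaDone && group != 0x0002) {
      metaDone <- TRUE
      if (identical(ts, .TS_IMPLICIT_LE)) explicit <- FALSE
      else if (!identical(ts, .TS_EXPLICIT_LE))
        stop("unsupported DICOM transfer syntax: ", ts)
    }
    key <- sprintf("%04X%04X", group, element)
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% longVRs) {
        len <- .rdU32(bytes, pos + 8L); vstart <- pos + 12L
      } else {
        len <- .rdU16(bytes, pos + 6L); vstart <- pos + 8L
      }
    } else {
      vr <- if (key %in% names(.DICOM_DICT)) .DICOM_DICT[[key]] else "UN"
      len <- .rdU32(bytes, pos + 4L); vstart <- pos + 8L
    }
    if (len == 2^32 - 1)
      stop("unsupported DICOM element with undefined length at tag ", key)
    if (vstart + len - 1L > n)
      stop("truncated DICOM element at tag ", key)
    if (key %in% names(.DICOM_DICT) || group == 0x0002) {
      val <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0L)
      out[[key]] <- .decodeValue(vr, val)
      if (key == "00020010") ts <- out[[key]]
    }
    pos <- vstart + len
    if (key == "7FE00010") break
  }
  out
}

# Decode one parsed DICOM element list into frames + metadata.
.dicomToFrames <- function(el, path) {
  need <- c("00280010", "00280011", "7FE00010")
  if (!all(need %in% names(el)))
    stop("not a readable image DICOM (missing Rows/Columns/PixelData): ",
         path)
  rows <- el[["00280010"]]; cols <- el[["00280011"]]
  nframes <- if ("00280008" %in% names(el)) el[["00280008"]] else 1L
  bits <- if ("00280100" %in% names(el)) el[["00280100"]] else 16L
  pixrep <- if ("00280103" %in% names(el)) el[["00280103"]] else 0L
  if (!bits %in% c(8L, 16L)) stop("unsupported bits allocated: ", bits)
  pr <- el[["7FE00010"]]
  npix <- rows * cols * nframes
  if (length(pr) < npix * bits / 8L)
    stop("pixel data shorter than Rows x Columns x NumberOfFrames: ", path)
  vals <- if (bits == 16L) {
    readBin(pr, "integer", n = npix, size = 2L, signed = pixrep == 1L,
            endian = "little")
  } else {
    readBin(pr, "integer", n = npix, size = 1L, signed = pixrep == 1L)
  }
  if (bits == 16L && pixrep == 0L) vals[vals < 0L] <- vals[vals < 0L] + 65536L
  fr <- array(0L, dim = c(rows, cols, nframes))
  perFrame <- rows * cols
  for (t in seq_len(nframes)) {
    # stored row-major; fill a cols x rows matrix and transpose
    m <- matrix(vals[((t - 1L) * perFrame + 1L):(t * perFrame)],
                nrow = cols, ncol = rows)
    fr[, , t] <- t(m)
  }
  fr
}

.dicomFps <- function(el) {
  if ("00181063" %in% names(el)) {
    ft <- el[["00181063"]][1L]
    if (is.finite(ft) && ft > 0) return(round(1000 / ft, 2L))
  }
  if ("00180040" %in% names(el)) {
    cr <- el[["00180040"]][1L]
    if (is.finite(cr) && cr > 0) return(as.numeric(cr))
  }
  NULL
}

.dicomResolution <- function(el) {
  for (key in c("00280030", "00181164")) {
    if (key %in% names(el)) {
      ps <- el[[key]][1L]
      if (is.finite(ps) && ps > 0) return(ps)
    }
  }
  NULL
}
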