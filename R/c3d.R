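# Minimal C3D reader/writer.
#
# Covers the subset of the standard the pipeline needs: Intel-byte-order
# files, 3D point data in integer or floating-point representation, the
# POINT parameter group (USED, FRAMES, RATE, SCALE, DATA_START, UNITS,
# LABELS) and optional analog data (skipped on read). Invalid points
# (negative residual) are returned as NA for downstream gap handling.

.rawInt8 <- function(raw, i) readBin(raw[i], "integer", size = 1, signed = TRUE)
.rawUint8 <- function(raw, i) readBin(raw[i], "integer", size = 1, signed = FALSE)
.rawInt16 <- function(raw, i, n = 1) {
  readBin(raw[i:(i + 2L * n - 1L)], "integer", size = 2, n = n,
          signed = TRUE, endian = "little")
}
.rawFloat <- function(raw, i, n = 1) {
  readBin(raw[i:(i + 4L * n - 1L)], "double", size = 4, n = n,
          endian = "little")
}

# Parse the parameter section into list(groups = id -> name,
# params = list(GROUP.PARAM = value)).
.c3dParseParameters <- function(raw, paramStart) {
  proc <- .rawUint8(raw, paramStart + 3L)
  if (proc != 84L)
    stop("unsupported C3D processor type ", proc, " (only Intel/PC is supported)")
  pos <- paramStart + 4L
  groups <- character()
  params <- list()
  repeat {
    if (pos > length(raw)) break
    nameLen <- .rawInt8(raw, pos)
    if (nameLen == 0L) break
    nameLen <- abs(nameLen)
    id <- .rawInt8(raw, pos + 1L)
    name <- toupper(rawToChar(raw[(pos + 2L):(pos + 1L + nameLen)]))
    cur <- pos + 2L + nameLen
    offset <- .rawInt16(raw, cur)
    # the offset counts from the first byte of the pointer itself
    nextPos <- cur + offset
    body <- cur + 2L
    if (id < 0L) {
      groups[as.character(-id)] <- name
    } else if (id > 0L) {
      type <- .rawInt8(raw, body)
      nDims <- .rawUint8(raw, body + 1L)
      dims <- if (nDims > 0) {
        vapply(seq_len(nDims), function(k) .rawUint8(raw, body + 1L + k), 0L)
      } else integer()
      nEl <- if (nDims > 0) prod(dims) else 1L
      dpos <- body + 2L + nDims
      value <- switch(as.character(type),
        "-1" = {
          ch <- rawToChar(raw[dpos:(dpos + nEl - 1L)])
          if (nDims >= 2) {
            # fixed-width strings: dims[1] chars per entry
            w <- dims[1]
            n <- nEl %/% w
            trimws(substring(ch, (seq_len(n) - 1L) * w + 1L, seq_len(n) * w))
          } else trimws(ch)
        },
        "1" = vapply(seq_len(nEl), function(k) .rawInt8(raw, dpos + k - 1L), 0L),
        "2" = .rawInt16(raw, dpos, nEl),
        "4" = .rawFloat(raw, dpos, nEl),
        stop("unsupported C3D parameter type ", type))
      params[[paste0("#", id, ".", name)]] <- value
    }
    if (offset == 0L) break
    pos <- nextPos
  }
  # resolve group ids to names
  out <- list()
  for (key in names(params)) {
    m <- regmatches(key, regexec("^#([0-9]+)\\.(.*)$", key))[[1]]
    gname <- groups[m[2]]
    if (is.na(gname)) gname <- paste0("GROUP", m[2])
    out[[paste0(gname, ".", m[3])]] <- params[[key]]
  }
  out
}

#' Read a C3D motion-capture file
#'
#' Parses header, parameter section and 3D point data. Positions are
#' returned in meters regardless of the stored \code{POINT:UNITS}
#' (millimeter files are divided by 1000). Points flagged invalid
#' (negative residual) become \code{NA}.
#'
#' @param path path to a C3D file.
#' @return list with \code{positions} (frames x points x 3, meters),
#'   \code{labels}, \code{rate}.
#' @export
readC3D <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 512L || .rawUint8(raw, 2L) != 0x50)
    stop("not a C3D file: ", path)
  paramBlock <- .rawUint8(raw, 1L)
  nPoints <- .rawInt16(raw, 3L)
  analogPerFrame <- .rawInt16(raw, 5L)
  firstFrame <- .rawInt16(raw, 7L)
  lastFrame <- .rawInt16(raw, 9L)
  headerScale <- .rawFloat(raw, 13L)
  dataBlock <- .rawInt16(raw, 17L)
  headerRate <- .rawFloat(raw, 21L)

  p <- .c3dParseParameters(raw, (paramBlock - 1L) * 512L + 1L)
  scale <- if (!is.null(p[["POINT.SCALE"]])) p[["POINT.SCALE"]][1] else headerScale
  rate <- if (!is.null(p[["POINT.RATE"]])) p[["POINT.RATE"]][1] else headerRate
  if (!is.null(p[["POINT.USED"]])) nPoints <- as.integer(p[["POINT.USED"]][1])
  if (!is.null(p[["POINT.DATA_START"]])) dataBlock <- as.integer(p[["POINT.DATA_START"]][1])
  nFrames <- lastFrame - firstFrame + 1L
  if (!is.null(p[["POINT.FRAMES"]])) nFrames <- as.integer(p[["POINT.FRAMES"]][1])
  labels <- p[["POINT.LABELS"]]
  if (is.null(labels)) labels <- paste0("M", seq_len(nPoints))
  labels <- labels[seq_len(min(nPoints, length(labels)))]
  if (length(labels) < nPoints)
    labels <- c(labels, paste0("M", seq.int(length(labels) + 1L, nPoints)))
  units <- if (!is.null(p[["POINT.UNITS"]])) tolower(p[["POINT.UNITS"]][1]) else "m"

  floatData <- scale < 0
  offset <- (dataBlock - 1L) * 512L + 1L
  if (floatData) {
    perFrame <- 4L * nPoints + analogPerFrame
    vals <- .rawFloat(raw, offset, perFrame * nFrames)
    dim(vals) <- c(perFrame, nFrames)
    xyz <- vals[seq_len(4L * nPoints), , drop = FALSE]
    dim(xyz) <- c(4L, nPoints, nFrames)
    pos <- aperm(xyz[1:3, , , drop = FALSE], c(3, 2, 1))
    resid <- xyz[4, , ]
  } else {
    perFrame <- 4L * nPoints + analogPerFrame
    vals <- .rawInt16(raw, offset, perFrame * nFrames)
    dim(vals) <- c(perFrame, nFrames)
    xyz <- vals[seq_len(4L * nPoints), , drop = FALSE]
    dim(xyz) <- c(4L, nPoints, nFrames)
    pos <- aperm(xyz[1:3, , , drop = FALSE], c(3, 2, 1)) * abs(scale)
    resid <- xyz[4, , ]
  }
  # residual layout after the slice above is points x frames
  bad <- t(resid < 0)
  if (any(bad)) {
    for (a in 1:3) {
      slab <- pos[, , a]
      slab[bad] <- NA_real_
      pos[, , a] <- slab
    }
  }
  conv <- switch(units, "mm" = 1e-3, "cm" = 1e-2, "m" = 1,
                 stop("unknown POINT:UNITS '", units, "'"))
  list(positions = pos * conv, labels = labels, rate = rate)
}

# --- writer ------------------------------------------------------------

.c3dParamItem <- function(name, groupId, type, dims, data, group = FALSE) {
  nameRaw <- charToRaw(name)
  body <- raw(0)
  if (!group) {
    dims <- as.integer(dims)
    dimBytes <- as.raw(dims)
    dataRaw <- switch(as.character(type),
      "-1" = charToRaw(paste(data, collapse = "")),
      "2"  = writeBin(as.integer(data), raw(), size = 2, endian = "little"),
      "4"  = writeBin(as.numeric(data), raw(), size = 4, endian = "little"))
    body <- c(writeBin(as.integer(type), raw(), size = 1),
              as.raw(length(dims)), dimBytes, dataRaw, as.raw(0L))
  } else {
    body <- as.raw(0L)  # empty description
  }
  offset <- length(body) + 2L
  c(writeBin(length(nameRaw), raw(), size = 1),
    writeBin(as.integer(if (group) -groupId else groupId), raw(), size = 1),
    nameRaw,
    writeBin(as.integer(offset), raw(), size = 2, endian = "little"),
    body)
}

#' Write a C3D motion-capture file
#'
#' Writes Intel-order, floating-point 3D point data with the POINT
#' parameter group. \code{positions} are always supplied in meters;
#' \code{units} selects the unit the file stores (millimeter files are
#' what most vendor exports produce). Files round-trip through
#' \code{\link{readC3D}}, which converts back to meters.
#'
#' @param path output path.
#' @param positions frames x points x 3 array in meters.
#' @param labels one name per point.
#' @param rate sampling rate in Hz.
#' @param units stored unit, "m" (default) or "mm".
#' @export
writeC3D <- function(path, positions, labels, rate, units = c("m", "mm")) {
  units <- match.arg(units)
  if (units == "mm") positions <- positions * 1000
  d <- dim(positions)
  if (length(d) != 3L || d[3] != 3L)
    stop("positions must be frames x points x 3")
  if (d[1] < 1L) stop("cannot write a C3D file with zero frames")
  nFrames <- d[1]; nPoints <- d[2]
  if (nFrames > 32760) stop("frame count exceeds the 16-bit header limit")
  if (length(labels) != nPoints) stop("one label per point is required")

  width <- max(nchar(labels), 4L)
  padded <- formatC(labels, width = width, flag = "-")

  items <- c(
    .c3dParamItem("POINT", 1L, group = TRUE),
    .c3dParamItem("USED", 1L, 2L, integer(0), nPoints),
    .c3dParamItem("FRAMES", 1L, 2L, integer(0), nFrames),
    .c3dParamItem("RATE", 1L, 4L, integer(0), rate),
    .c3dParamItem("SCALE", 1L, 4L, integer(0), -1.0),
    .c3dParamItem("UNITS", 1L, -1L, nchar(units), units),
    .c3dParamItem("LABELS", 1L, -1L, c(width, nPoints), padded),
    .c3dParamItem("ANALOG", 2L, group = TRUE),
    .c3dParamItem("USED", 2L, 2L, integer(0), 0L)
  )
  # DATA_START depends on parameter-section length; it occupies a fixed
  # number of bytes, so compute with a placeholder first.
  mkParams <- function(dataStart) {
    body <- c(as.raw(c(0x01, 0x50)), as.raw(0L), as.raw(84L),
              items, .c3dParamItem("DATA_START", 1L, 2L, integer(0), dataStart),
              as.raw(0L))
    body
  }
  probe <- mkParams(0L)
  paramBlocks <- as.integer(ceiling(length(probe) / 512))
  dataStart <- 2L + paramBlocks
  paramRaw <- mkParams(dataStart)
  paramRaw[3] <- as.raw(paramBlocks)
  paramRaw <- c(paramRaw, raw(paramBlocks * 512L - length(paramRaw)))

  header <- raw(512)
  header[1] <- as.raw(2L)        # parameter section starts at block 2
  header[2] <- as.raw(0x50)
  put16 <- function(h, wordIndex, value) {
    b <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
    h[(2L * wordIndex - 1L):(2L * wordIndex)] <- b
    h
  }
  putFloat <- function(h, wordIndex, value) {
    b <- writeBin(as.numeric(value), raw(), size = 4, endian = "little")
    h[(2L * wordIndex - 1L):(2L * wordIndex + 2L)] <- b
    h
  }
  header <- put16(header, 2L, nPoints)
  header <- put16(header, 3L, 0L)            # no analog
  header <- put16(header, 4L, 1L)            # first frame
  header <- put16(header, 5L, nFrames)       # last frame
  header <- put16(header, 6L, 10L)           # max interpolation gap
  header <- putFloat(header, 7L, -1.0)       # scale (float data)
  header <- put16(header, 9L, dataStart)
  header <- put16(header, 10L, 0L)
  header <- putFloat(header, 11L, rate)

  # frame-major interleave: x, y, z, residual per point
  frameMajor <- aperm(positions, c(3, 2, 1))       # 3 x points x frames
  out <- array(0, dim = c(4L, nPoints, nFrames))
  out[1:3, , ] <- frameMajor
  bad <- is.na(out[1, , ]) | is.na(out[2, , ]) | is.na(out[3, , ])
  out[4, , ][bad] <- -1
  out[is.na(out)] <- 0
  dataRaw <- writeBin(as.numeric(out), raw(), size = 4, endian = "little")
  pad <- (512L - length(dataRaw) %% 512L) %% 512L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(paramRaw, con)
  writeBin(dataRaw, con)
  if (pad) writeBin(raw(pad), con)
  invisible(path)
}
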