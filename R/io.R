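# Readers and writers for the package's canonical on-disk formats:
#  - event lists: delimited text with header row + a YAML sidecar holding
#    acquisition metadata (replaces a binary event-tree format so files stay
#    inspectable and language-neutral),
#  - projection stacks: Interfile-dialect text header (.hdr) + little-endian
#    unsigned 16-bit raw payload (.img), projection-major order,
#  - spectra: two-column CSV (bin_lo_keV, counts) + YAML sidecar,
#  - run configs: YAML.

eventColumns <- c("energy_keV", "x_mm", "y_mm", "projection_index", "time_s")

sidecarPath <- function(path) paste0(path, ".meta.yaml")

#' Write a detected-event list to delimited text
#'
#' Writes a header row plus one row per event in a canonical numeric format
#' (9 significant digits), and a YAML sidecar `<path>.meta.yaml` with the
#' acquisition metadata. Re-writing a file read with [readEvents()]
#' reproduces it byte-for-byte.
#'
#' @param events a [DetectedEvents-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
  stopIfNot(is(events, "DetectedEvents"), "events must be DetectedEvents")
  ev <- events@events
  lines <- c(paste(eventColumns, collapse = ","),
             sprintf("%.9g,%.9g,%.9g,%d,%.9g",
                     ev$energy_keV, ev$x_mm, ev$y_mm,
                     as.integer(ev$projection_index), ev$time_s))
  writeLines(lines, path)
  yaml::write_yaml(list(n_projections = events@nProjections,
                        duration_s = events@durationS,
                        n_events = nrow(ev)),
                   sidecarPath(path))
  invisible(path)
}

#' Read a detected-event list
#'
#' @param path event file written by [writeEvents()] (header row
#'   `energy_keV,x_mm,y_mm,projection_index,time_s`, one CSV row per event),
#'   with its YAML metadata sidecar alongside.
#' @return a [DetectedEvents-class].
#' @export
readEvents <- function(path) {
  stopIfNot(file.exists(path), paste("event file not found:", path))
  mpath <- sidecarPath(path)
  stopIfNot(file.exists(mpath), paste("metadata sidecar not found:", mpath))
  meta <- yaml::read_yaml(mpath)
  for (k in c("n_projections", "duration_s"))
    if (is.null(meta[[k]])) stop("schema error: sidecar missing ", k)
  lines <- readLines(path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  miss <- setdiff(eventColumns, header)
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  body <- lines[-1]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != length(header))
    if (length(bad))
      stop("parse error at line ", bad[1] + 1L, ": expected ",
           length(header), " fields")
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = length(header), byrow = TRUE)
    colnames(m) <- header
    na <- which(rowSums(is.na(m)) > 0)
    if (length(na))
      stop("parse error at line ", na[1] + 1L, ": non-numeric field")
    ev <- as.data.frame(m)[, eventColumns]
  } else {
    ev <- as.data.frame(setNames(rep(list(numeric(0)), 5), eventColumns))
  }
  ev$projection_index <- as.integer(ev$projection_index)
  detectedEvents(ev, meta$n_projections, meta$duration_s)
}

# --- projection stacks ------------------------------------------------------

uint16ToRaw <- function(v) {
  v <- as.integer(round(v))
  as.vector(rbind(as.raw(v %% 256L), as.raw(v %/% 256L)))
}

rawToUint16 <- function(b) {
  m <- matrix(as.integer(b), nrow = 2L)
  m[1, ] + 256L * m[2, ]
}

#' Write a projection stack as Interfile-style header + raw payload
#'
#' `path` should end in `.hdr`; the pixel payload is written alongside with
#' extension `.img` as little-endian unsigned 16-bit integers in
#' projection-major order (within a projection, rows are written in
#' sequence).
#'
#' @param stack a [ProjectionStack-class].
#' @param path output header path (`.hdr`).
#' @return `path`, invisibly.
#' @export
writeProjectionStack <- function(stack, path) {
  stopIfNot(is(stack, "ProjectionStack"), "stack must be a ProjectionStack")
  imgPath <- sub("\\.hdr$", ".img", path)
  if (imgPath == path) imgPath <- paste0(path, ".img")
  d <- dim(stack@pixels)
  hdr <- c(
    "!INTERFILE :=",
    "!imagedata byte order := LITTLEENDIAN",
    "!number format := unsigned integer",
    "!number of bytes per pixel := 2",
    sprintf("!name of data file := %s", basename(imgPath)),
    sprintf("!total number of images := %d", d[1]),
    sprintf("!matrix size [1] := %d", d[3]),
    sprintf("!matrix size [2] := %d", d[2]),
    sprintf("!scaling factor (mm/pixel) [1] := %.9g", stack@pixelSizeMm),
    sprintf("!scaling factor (mm/pixel) [2] := %.9g", stack@pixelSizeMm),
    sprintf("!image duration (sec) := %.9g", stack@timePerProjectionS),
    sprintf("!number of detector heads := %d", stack@nHeads),
    sprintf("!projections per head := %d", stack@projectionsPerHead),
    "!END OF INTERFILE :=")
  writeLines(hdr, path)
  # projection-major, row-sequential payload
  v <- aperm(stack@pixels, c(3L, 2L, 1L))
  con <- file(imgPath, "wb")
  on.exit(close(con))
  writeBin(uint16ToRaw(as.vector(v)), con)
  invisible(path)
}

#' Read a projection stack written by [writeProjectionStack()]
#'
#' @param path header file path (`.hdr`).
#' @return a [ProjectionStack-class].
#' @export
readProjectionStack <- function(path) {
  stopIfNot(file.exists(path), paste("header not found:", path))
  lines <- readLines(path)
  getKey <- function(key) {
    hit <- grep(paste0("^!", key, " :="), lines, value = TRUE)
    if (!length(hit)) stop("format error: header key missing: ", key)
    trimws(sub("^[^=]*:=", "", hit[1]))
  }
  nproj <- as.integer(getKey("total number of images"))
  ncols <- as.integer(getKey("matrix size \\[1\\]"))
  nrows <- as.integer(getKey("matrix size \\[2\\]"))
  psize <- as.numeric(getKey("scaling factor \\(mm/pixel\\) \\[1\\]"))
  tproj <- as.numeric(getKey("image duration \\(sec\\)"))
  nheads <- as.integer(getKey("number of detector heads"))
  pph <- as.integer(getKey("projections per head"))
  imgPath <- file.path(dirname(path), getKey("name of data file"))
  stopIfNot(file.exists(imgPath), paste("payload not found:", imgPath))
  nExpected <- as.numeric(nproj) * nrows * ncols
  bytes <- readBin(imgPath, "raw", n = file.size(imgPath))
  if (length(bytes) != 2 * nExpected)
    stop("format error: payload size ", length(bytes),
         " bytes does not match header (expected ", 2 * nExpected, ")")
  v <- rawToUint16(bytes)
  pixels <- aperm(array(v, dim = c(ncols, nrows, nproj)), c(3L, 2L, 1L))
  projectionStack(pixels, pixelSizeMm = psize, timePerProjectionS = tproj,
                  nHeads = nheads, projectionsPerHead = pph)
}

# --- spectra ----------------------------------------------------------------

#' Write an energy spectrum as two-column CSV plus metadata sidecar
#'
#' Columns are `bin_lo_keV` and `counts`; the YAML sidecar stores the live
#' time and the bin width (which, with the last `bin_lo_keV`, fixes the
#' upper edge).
#'
#' @param spectrum an [EnergySpectrum-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopIfNot(is(spectrum, "EnergySpectrum"), "need an EnergySpectrum")
  lo <- spectrum@binEdgesKeV[-length(spectrum@binEdgesKeV)]
  writeLines(c("bin_lo_keV,counts",
               sprintf("%.9g,%.9g", lo, spectrum@counts)), path)
  yaml::write_yaml(list(live_time_s = spectrum@liveTimeS,
                        bin_width_keV = binWidth(spectrum)),
                   sidecarPath(path))
  invisible(path)
}

#' Read an energy spectrum written by [writeSpectrum()]
#'
#' @param path CSV path with YAML sidecar alongside.
#' @return an [EnergySpectrum-class].
#' @export
readSpectrum <- function(path) {
  stopIfNot(file.exists(path), paste("spectrum file not found:", path))
  mpath <- sidecarPath(path)
  stopIfNot(file.exists(mpath), paste("metadata sidecar not found:", mpath))
  meta <- yaml::read_yaml(mpath)
  df <- utils::read.csv(path)
  if (!all(c("bin_lo_keV", "counts") %in% names(df)))
    stop("schema error: expected columns bin_lo_keV, counts")
  w <- meta$bin_width_keV
  edges <- c(df$bin_lo_keV, df$bin_lo_keV[nrow(df)] + w)
  energySpectrum(edges, df$counts, meta$live_time_s)
}

#' Read a run configuration
#'
#' A YAML file listing windows, binning, seeds and input paths; see
#' [runValidation()] for the recognised fields.
#'
#' @param path YAML config path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), paste("config not found:", path))
  yaml::read_yaml(path)
}
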