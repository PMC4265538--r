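#' Validate and construct a grayscale raster
#'
#' A GrayRaster is a plain numeric matrix with all values finite and inside
#' `[0, 1]`.  `gray_raster()` checks the invariants and returns the matrix
#' unchanged (unclassed), so downstream arithmetic stays ordinary matrix
#' algebra.
#'
#' @param values numeric matrix.
#' @return the validated numeric matrix.
#' @export
gray_raster <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("GrayRaster must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("GrayRaster must have at least one row and one column")
  }
  if (!all(is.finite(values))) stop("GrayRaster values must all be finite")
  if (any(values < 0 | values > 1)) {
    stop("GrayRaster values must lie in [0, 1]")
  }
  values
}

#' Validate and construct a binary edge map
#'
#' An EdgeMap is a plain logical matrix; `TRUE` marks edge/foreground pixels.
#' The "black pixels" of printed edge images are a display convention only:
#' internally there is one canonical polarity, foreground = `TRUE`.
#'
#' @param values logical matrix (NAs are not allowed).
#' @return the validated logical matrix.
#' @export
edge_map <- function(values) {
  if (!is.matrix(values) || !is.logical(values)) {
    stop("EdgeMap must be a logical matrix")
  }
  if (anyNA(values)) stop("EdgeMap must not contain NA")
  values
}

#' Cast an edge map to a grayscale raster
#'
#' Foreground becomes 1.0, background 0.0.  Used when a binary detector
#' output is fed back into an intensity-based detector (refined/variant ACO).
#'
#' @param map logical matrix (EdgeMap).
#' @return numeric matrix in `[0, 1]`.
#' @export
as_gray <- function(map) {
  map <- edge_map(map)
  out <- matrix(as.numeric(map), nrow(map), ncol(map))
  out
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = file.info(path)$size)
  # header tokens: magic, width, height, maxval; '#' comments run to newline
  txt <- rawToChar(raw)
  pos <- 1L
  tokens <- character(0)
  nc <- nchar(txt)
  while (length(tokens) < 4L && pos <= nc) {
    ch <- substr(txt, pos, pos)
    if (ch == "#") {
      while (pos <= nc && substr(txt, pos, pos) != "\n") pos <- pos + 1L
    } else if (grepl("[[:space:]]", ch)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= nc && !grepl("[[:space:]]", substr(txt, pos, pos))) {
        pos <- pos + 1L
      }
      tokens <- c(tokens, substr(txt, start, pos - 1L))
    }
  }
  if (length(tokens) < 4L || !(tokens[1] %in% c("P2", "P5"))) {
    stop("cannot read PGM file: ", path)
  }
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval < 1L) {
    stop("malformed PGM header in ", path)
  }
  n <- w * h
  if (tokens[1] == "P2") {
    body <- substr(txt, pos, nc)
    body <- gsub("#[^\n]*", " ", body)
    vals <- as.numeric(strsplit(trimws(body), "[[:space:]]+")[[1]])
    if (length(vals) < n) stop("truncated PGM data in ", path)
    vals <- vals[seq_len(n)]
  } else {
    pos <- pos + 1L # single whitespace byte after maxval
    bytes <- raw[seq.int(pos, length.out = n * (if (maxval > 255) 2L else 1L))]
    if (maxval > 255) {
      hi <- as.integer(bytes[seq(1L, length(bytes), 2L)])
      lo <- as.integer(bytes[seq(2L, length(bytes), 2L)])
      vals <- hi * 256 + lo # big-endian per PGM spec
    } else {
      vals <- as.integer(bytes)
    }
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

read_tiff_single <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) > 1L) {
    stop("multi-frame TIFF: ", path,
         " has ", length(frames),
         " frames; extract the desired frame to its own file first")
  }
  frames[[1L]]
}

#' Load a grayscale raster from PNG, TIFF or PGM
#'
#' Values are linearly rescaled from the native bit depth to `[0, 1]`
#' (e.g. 8-bit 255 -> 1.0, 16-bit 32768 -> 32768/65535).  RGB images are
#' averaged across the three colour channels; an alpha channel is ignored.
#'
#' @param path path to a PNG, TIFF or PGM file.
#' @return numeric matrix in `[0, 1]` (GrayRaster).
#' @export
load_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = read_tiff_single(path),
    tiff = read_tiff_single(path),
    pgm  = read_pgm(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    img <- if (nch >= 3L) {
      (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    } else {
      img[, , 1]
    }
  }
  gray_raster(pmin(pmax(img, 0), 1))
}

#' Save a grayscale raster as an 8-bit PNG
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
save_gray <- function(img, path) {
  img <- gray_raster(img)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Save an edge map as an 8-bit PNG (foreground 255, background 0)
#'
#' Round-trips bit-exactly through [load_edge_map()].
#'
#' @param map logical matrix (EdgeMap).
#' @param path output path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
save_edge_map <- function(map, path) {
  map <- edge_map(map)
  png::writePNG(matrix(as.numeric(map), nrow(map), ncol(map)), target = path)
  invisible(path)
}

#' Load an edge map from a single-channel image
#'
#' Pixels above half of full scale become `TRUE` (8-bit: 128 -> TRUE,
#' 127 -> FALSE).
#'
#' @param path path to a single-channel PNG, TIFF or PGM file.
#' @return logical matrix (EdgeMap).
#' @export
load_edge_map <- function(path) {
  img <- load_gray(path)
  edge_map(img > 0.5)
}
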