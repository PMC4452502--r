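# Image input/output: PGM (P2/P5), PNG and TIFF, all normalized to a
# numeric matrix of intensities in [0, 255].

#' Read a grayscale image
#'
#' Reads PGM (P2 ascii or P5 binary), PNG or TIFF by file extension and
#' returns a 2-D numeric matrix in `[0, 255]`. Multi-channel input is
#' converted to luminance with Rec. 601 weights (0.299 R + 0.587 G +
#' 0.114 B); an alpha channel is ignored. Sample values are rescaled from
#' the format's full-scale value, so 16-bit full scale maps to 255.
#'
#' @param path File path; extension one of `.pgm`, `.png`, `.tif`, `.tiff`.
#' @return Numeric matrix (rows x cols) in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("input image not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    stop("unsupported image format: .", ext, " (use PGM, PNG or TIFF)",
         call. = FALSE)
  )
  to_gray(img)
}

# Collapse an H x W x C array to luminance; pass matrices through.
to_gray <- function(img) {
  if (is.matrix(img)) {
    return(img)
  }
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    if (ch >= 3) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
    return(img[, , 1])
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Write a grayscale image
#'
#' Writes a numeric matrix in `[0, 255]` as PGM (P2 ascii by default), PNG
#' or TIFF, chosen by file extension.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param path Output path.
#' @param ascii For PGM: write ascii P2 (default) or binary P5.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, ascii = TRUE) {
  stopifnot(is.matrix(image))
  img <- pmin(pmax(image, 0), 255)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(img, path, ascii = ascii),
    png = png::writePNG(img / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(img / 255, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read a PGM image (P2 or P5)
#'
#' Plain (P2) and raw (P5) portable graymaps, including `#` comments and
#' 16-bit raw samples (big-endian, per the format). Values are rescaled so
#' the file's maxval maps to 255.
#'
#' @param path File path.
#' @return Numeric matrix in `[0, 255]`.
#' @export
read_pgm <- function(path) {
  magic <- rawToChar(readBin(path, "raw", 2))
  if (magic == "P2") {
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    width <- as.integer(toks[2])
    height <- as.integer(toks[3])
    maxval <- as.numeric(toks[4])
    vals <- as.numeric(toks[-(1:4)])
  } else if (magic == "P5") {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 2)
    # header tokens (width, height, maxval), skipping whitespace and
    # '#' comments; a single whitespace byte terminates the header
    tokens <- integer(0)
    buf <- character(0)
    while (length(tokens) < 3) {
      ch <- rawToChar(readBin(con, "raw", 1))
      if (length(ch) == 0 || identical(ch, "")) {
        if (length(buf) == 0) stop("truncated PGM header: ", path,
                                   call. = FALSE)
        ch <- " "
      }
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1))
          if (ch %in% c("\n", "\r", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(buf) > 0) {
          tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
          buf <- character(0)
        }
        next
      }
      buf <- c(buf, ch)
    }
    width <- tokens[1]
    height <- tokens[2]
    maxval <- tokens[3]
    n <- width * height
    vals <- if (maxval < 256) {
      as.integer(readBin(con, "raw", n))
    } else {
      readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
    }
  } else {
    stop("not a PGM file (expected P2 or P5): ", path, call. = FALSE)
  }
  n <- width * height
  if (length(vals) != n || anyNA(vals)) {
    stop("truncated or malformed PGM pixel data: ", path, call. = FALSE)
  }
  matrix(vals, nrow = height, ncol = width, byrow = TRUE) * (255 / maxval)
}

#' Write a PGM image
#'
#' @param image Numeric matrix in `[0, 255]`; values are rounded to
#'   integers.
#' @param path Output path.
#' @param ascii Write plain P2 (default) or raw P5.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, ascii = TRUE) {
  stopifnot(is.matrix(image))
  vals <- round(pmin(pmax(image, 0), 255))
  header <- sprintf("%s\n%d %d\n255\n",
                    if (ascii) "P2" else "P5", ncol(image), nrow(image))
  if (ascii) {
    rows <- apply(vals, 1, paste, collapse = " ")
    writeLines(c(sub("\n$", "", header), rows), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeBin(as.raw(as.integer(t(vals))), con)
  }
  invisible(path)
}
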