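## File I/O: baseline multi-page TIFF (uncompressed, grayscale, one sample
## per pixel; 8/16-bit unsigned or 32-bit float) and CSV spectra. No TIFF
## package exists in the supported dependency set, so the subset of the
## format this package needs is read and written directly.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  endian <- if (raw[1L] == as.raw(0x49) && raw[2L] == as.raw(0x49)) "little"
            else if (raw[1L] == as.raw(0x4d) && raw[2L] == as.raw(0x4d)) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path,
                      call. = FALSE)
  rint <- function(off, size, n = 1L, signed = (size >= 4L))
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  magic <- rint(2L, 2L)
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path, call. = FALSE)
  ifd_off <- rint(4L, 4L)
  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  pages <- list()
  descr <- NULL
  while (ifd_off != 0L) {
    nent <- rint(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(nent)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rint(eo, 2L)
      typ <- rint(eo + 2L, 2L)
      cnt <- rint(eo + 4L, 4L)
      if (typ < 1L || typ > 5L) next
      sz <- type_size[typ]
      voff <- if (sz * cnt <= 4L) eo + 8L else rint(eo + 8L, 4L)
      val <- if (typ == 2L) {
        rawToChar(raw[(voff + 1L):(voff + cnt)], multiple = FALSE)
      } else if (typ == 5L) {
        num <- rint(voff, 4L, n = 2L * cnt)
        num[seq(1L, 2L * cnt, 2L)] / num[seq(2L, 2L * cnt, 2L)]
      } else {
        rint(voff, sz, n = cnt)
      }
      tags[[as.character(tag)]] <- val
    }
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    wd <- gt(256L); ht <- gt(257L)
    if (is.null(wd) || is.null(ht))
      stop("malformed TIFF page (missing dimensions): ", path, call. = FALSE)
    if (gt(259L, 1L) != 1L)
      stop("unsupported TIFF: compressed data; expected an uncompressed ",
           "grayscale channels-as-pages stack", call. = FALSE)
    if (gt(277L, 1L) != 1L)
      stop("unsupported TIFF: interleaved samples (e.g. RGB); expected an ",
           "uncompressed grayscale channels-as-pages stack", call. = FALSE)
    bits <- gt(258L, 1L)
    fmt <- gt(339L, 1L)
    offs <- gt(273L)
    bcnt <- gt(279L, as.integer(ceiling(wd * ht * bits / 8)))
    if (is.null(offs))
      stop("malformed TIFF page (no strip offsets): ", path, call. = FALSE)
    bytes <- raw(0)
    for (k in seq_along(offs))
      bytes <- c(bytes, raw[(offs[k] + 1L):(offs[k] + bcnt[k])])
    px <- if (fmt == 3L && bits == 32L) {
      readBin(bytes, "double", n = wd * ht, size = 4L, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bits %in% c(8L, 16L)) {
      readBin(bytes, "integer", n = wd * ht, size = bits / 8L,
              signed = (fmt == 2L), endian = endian)
    } else if (fmt == 1L && bits == 32L) {
      readBin(bytes, "integer", n = wd * ht, size = 4L, endian = endian)
    } else {
      stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt,
           ")", call. = FALSE)
    }
    ## TIFF data is row-major; build H x W matrix
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = wd, ncol = ht))
    if (is.null(descr)) descr <- gt(270L)
    ifd_off <- rint(ifd_off + 2L + nent * 12L, 4L)
  }
  if (!length(pages)) stop("TIFF has no pages: ", path, call. = FALSE)
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) all(dim(p) == d1), logical(1))))
    stop("inconsistent page shapes in TIFF: ", path, call. = FALSE)
  cube <- array(0, c(length(pages), d1[1L], d1[2L]))
  for (k in seq_along(pages)) cube[k, , ] <- pages[[k]]
  attr(cube, "description") <- descr
  cube
}

write_tiff_stack <- function(cube, path, description = NULL,
                             float = TRUE) {
  d <- dim(cube)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeBin(charToRaw("II"), con)
  wi(42L, 2L)
  desc_raw <- if (!is.null(description)) {
    c(charToRaw(description), as.raw(0L))
  } else NULL
  nent <- 10L + as.integer(!is.null(desc_raw))
  ifd_size <- 2L + nent * 12L + 4L
  page_bytes <- H * W * 4L
  ## layout: header(8) | per page: [pixel data | desc (page 1) | IFD]
  off <- 8L
  offsets <- list()
  for (p in seq_len(C)) {
    data_off <- off
    cur <- data_off + page_bytes
    desc_off <- NA_integer_
    if (p == 1L && !is.null(desc_raw)) {
      desc_off <- cur
      cur <- cur + length(desc_raw)
      if (cur %% 2L == 1L) cur <- cur + 1L   # word alignment
    }
    ifd_off <- cur
    offsets[[p]] <- list(data = data_off, desc = desc_off, ifd = ifd_off)
    off <- ifd_off + ifd_size
  }
  wi(offsets[[1L]]$ifd, 4L)
  entry <- function(tag, typ, cnt, val) {
    wi(tag, 2L); wi(typ, 2L); wi(cnt, 4L)
    if (typ == 3L && cnt == 1L) { wi(val, 2L); wi(0L, 2L) } else wi(val, 4L)
  }
  for (p in seq_len(C)) {
    plane <- t(cube[p, , , drop = TRUE])      # row-major pixel order
    if (is.null(dim(plane))) plane <- matrix(plane, nrow = W)
    writeBin(as.numeric(plane), con, size = 4L, endian = "little")
    if (p == 1L && !is.null(desc_raw)) {
      writeBin(desc_raw, con)
      if ((offsets[[p]]$desc + length(desc_raw)) %% 2L == 1L)
        writeBin(as.raw(0L), con)
    }
    wi(nent, 2L)
    entry(256L, 4L, 1L, W)
    entry(257L, 4L, 1L, H)
    entry(258L, 3L, 1L, 32L)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    if (!is.null(desc_raw))
      entry(270L, 2L, length(desc_raw), offsets[[1L]]$desc)
    entry(273L, 4L, 1L, offsets[[p]]$data)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, H)
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, 3L)
    wi(if (p < C) offsets[[p + 1L]]$ifd else 0L, 4L)
  }
  invisible(path)
}

#' Read a multichannel spectral image from a multi-page TIFF
#'
#' Pages are interpreted as spectral channels (channels-first). Supported
#' layout: uncompressed, grayscale (one sample per pixel), 8/16-bit integer
#' or 32-bit data. Negative values are clamped to zero with a warning.
#'
#' @param path TIFF file path.
#' @return a [spectral_image()].
#' @export
read_spectral_tiff <- function(path) {
  cube <- read_tiff_stack(path)
  nneg <- sum(cube < 0)
  if (nneg > 0) {
    warning(sprintf("clamped %d negative pixel values to 0 in %s",
                    nneg, path), call. = FALSE)
    cube[cube < 0] <- 0
  }
  attr(cube, "description") <- NULL
  spectral_image(cube)
}

#' Write an abundance image as a multi-page 32-bit float TIFF
#'
#' One page per endmember, page order = endmember order; the endmember names
#' and the count-rescaling factor are stored as JSON in the image
#' description.
#'
#' @param A an [abundance_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tiff <- function(A, path) {
  stopifnot(inherits(A, "abundance_image"))
  desc <- jsonlite::toJSON(list(names = A$names, scale = A$scale),
                           auto_unbox = TRUE)
  write_tiff_stack(A$values, path, description = as.character(desc))
}

#' Read an abundance image written by [write_abundance_tiff()]
#'
#' @param path TIFF file path.
#' @return an [abundance_image()]; names and scale are restored from the
#'   image description when present.
#' @export
read_abundance_tiff <- function(path) {
  cube <- read_tiff_stack(path)
  descr <- attr(cube, "description")
  attr(cube, "description") <- NULL
  nm <- NULL; sc <- 1
  if (!is.null(descr)) {
    meta <- tryCatch(jsonlite::fromJSON(descr), error = function(e) NULL)
    if (!is.null(meta)) {
      nm <- meta$names
      if (!is.null(meta$scale)) sc <- meta$scale
    }
  }
  cube[cube < 0] <- 0
  abundance_image(cube, names = nm, scale = sc)
}

#' Write endmember spectra as CSV
#'
#' Header row of fluorophore names, one row per channel, plain decimal
#' values.
#'
#' @param M an [endmember_matrix()] (or C x R matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(M, path) {
  M <- as.matrix(M)
  df <- as.data.frame(M)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read endmember spectra from CSV
#'
#' Expects a header row of fluorophore names and one row per channel.
#' Columns are renormalized to unit sum; the original column sums are kept
#' in the `original_sums` attribute.
#'
#' @param path CSV path.
#' @return an [endmember_matrix()].
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!ncol(df)) stop("spectra CSV has no columns: ", path, call. = FALSE)
  numeric_names <- !is.na(suppressWarnings(as.numeric(names(df))))
  if (is.null(names(df)) || any(!nzchar(names(df))) || all(numeric_names))
    stop("spectra CSV must have a header row of fluorophore names: ", path,
         call. = FALSE)
  for (j in seq_len(ncol(df))) {
    bad <- which(!is.na(df[[j]]) & !is.numeric(df[[j]]))
    if (!is.numeric(df[[j]]))
      stop(sprintf("non-numeric value in spectra CSV column '%s' (%s)",
                   names(df)[j], path), call. = FALSE)
    nb <- which(is.na(df[[j]]))
    if (length(nb))
      stop(sprintf("missing/non-numeric value in spectra CSV at row %d, column '%s'",
                   nb[1L], names(df)[j]), call. = FALSE)
  }
  M <- as.matrix(df)
  sums <- colSums(M)
  out <- endmember_matrix(M, names = names(df))
  attr(out, "original_sums") <- sums
  out
}
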