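# Minimal baseline TIFF codec: uncompressed, little-endian, single-sample
# grayscale, float32 or uint16, one strip per page, multi-page. This is the
# interchange format for holograms and phase stacks. Written from scratch
# because no TIFF package is available in the deployment environment; only the
# baseline subset needed for these stacks is supported.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               spp = 277L, rows_per_strip = 278L, strip_counts = 279L,
               sample_format = 339L)

#' Write a grayscale multi-page TIFF
#'
#' Writes one or more matrices as an uncompressed little-endian grayscale
#' TIFF. Matrices are written page by page in list order. `float32` preserves
#' fractional values (phase maps, radians); `uint16` is for raw detector-style
#' intensity frames and requires values in `[0, 65535]`.
#'
#' @param pages a matrix, or list of matrices of identical storage type.
#' @param path output file path.
#' @param type `"float32"` or `"uint16"`.
#' @param description optional character scalar stored in the first page's
#'   ImageDescription tag (used for JSON provenance).
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(pages, path, type = c("float32", "uint16"),
                       description = NULL) {
  type <- match.arg(type)
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  if (type == "uint16") {
    rng <- range(vapply(pages, function(p) range(p), numeric(2)))
    if (rng[1] < 0 || rng[2] > 65535)
      stop("uint16 TIFF requires values in [0, 65535]")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  ifd_ptr_pos <- 4                       # position of "offset of next IFD"
  writeBin(0L, con, size = 4, endian = "little")
  pos <- 8
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    bps <- if (type == "float32") 32L else 16L
    bytes <- h * w * (bps / 8L)
    data_off <- pos
    if (type == "float32") {
      writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(t(m))), con, size = 2, endian = "little")
    }
    pos <- pos + bytes
    desc <- if (i == 1 && !is.null(description)) description else NULL
    desc_raw <- if (!is.null(desc)) c(charToRaw(desc), as.raw(0)) else raw(0)
    desc_off <- pos
    if (length(desc_raw)) {
      if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
      writeBin(desc_raw, con)
      pos <- pos + length(desc_raw)
    }
    entries <- list(
      list(TIFF_TAGS[["width"]], 3L, 1L, w),
      list(TIFF_TAGS[["length"]], 3L, 1L, h),
      list(TIFF_TAGS[["bits"]], 3L, 1L, bps),
      list(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    )
    if (length(desc_raw))
      entries <- c(entries, list(list(TIFF_TAGS[["description"]], 2L,
                                      length(desc_raw), desc_off)))
    entries <- c(entries, list(
      list(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off),
      list(TIFF_TAGS[["spp"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, h),
      list(TIFF_TAGS[["strip_counts"]], 4L, 1L, bytes),
      list(TIFF_TAGS[["sample_format"]], 3L, 1L,
           if (type == "float32") 3L else 1L)
    ))
    entries <- entries[order(vapply(entries, function(e) e[[1]], integer(1)))]
    ifd_off <- pos
    # patch the previous "next IFD" pointer to point here
    seek(con, ifd_ptr_pos, origin = "start", rw = "write")
    writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
    seek(con, ifd_off, origin = "start", rw = "write")
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(as.integer(e[[1]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[[2]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[[3]]), con, size = 4, endian = "little")
      if (e[[2]] == 3L && e[[3]] == 1L) {        # SHORT packed left-justified
        writeBin(as.integer(e[[4]]), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(e[[4]]), con, size = 4, endian = "little")
      }
    }
    ifd_ptr_pos <- ifd_off + 2 + 12 * length(entries)
    writeBin(0L, con, size = 4, endian = "little")
    pos <- ifd_ptr_pos + 4
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Reads uncompressed single-sample grayscale TIFFs (uint8/uint16/uint32 or
#' float32, little- or big-endian, any strip layout) as written by
#' [write_tiff()] or comparable exporters.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices (one per page); the ImageDescription of
#'   the first page, when present, is attached as attribute `"description"`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2)
  if (rint(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rint(4, 4)
  pages <- list()
  description <- NULL
  while (ifd != 0) {
    n_entries <- rint(ifd, 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- ifd + 2 + 12 * (k - 1)
      tag <- rint(e, 2); typ <- rint(e + 2, 2); cnt <- rint(e + 4, 4)
      tsize <- c(1L, 1L, 2L, 4L, 8L)[typ]
      inline <- tsize * cnt <= 4
      voff <- if (inline) e + 8 else rint(e + 8, 4)
      val <- switch(as.character(typ),
        "2" = rawToChar(raw[(voff + 1):(voff + cnt - 1)]),
        "3" = rint(voff, 2, cnt),
        "4" = rint(voff, 4, cnt),
        rint(voff, tsize, cnt))
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256); h <- g(257)
    bits <- g(258, 1L); fmt <- g(339, 1L)
    if (g(259, 1L) != 1L) stop("compressed TIFF not supported")
    if (g(277, 1L) != 1L) stop("multi-sample TIFF not supported")
    offs <- g(273); cnts <- g(279)
    if (is.null(description) && !is.null(g(270))) description <- g(270)
    nbytes <- bits / 8L
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    vals <- if (fmt == 3L) {
      readBin(buf, "double", n = w * h, size = 4, endian = endian)
    } else {
      readBin(buf, "integer", n = w * h, size = nbytes, endian = endian,
              signed = nbytes > 2)
    }
    if (fmt == 1L && nbytes == 2) vals[vals < 0] <- vals[vals < 0] + 65536
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w,
                                         byrow = TRUE)
    ifd <- rint(ifd + 2 + 12 * n_entries, 4)
  }
  if (!is.null(description)) attr(pages, "description") <- description
  pages
}
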