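## Minimal multi-page TIFF I/O for MBR stacks.
##
## No TIFF package ships with this environment, so the package carries a
## tiny baseline-TIFF implementation sufficient for its own interchange
## format: little-endian, uncompressed, one strip per page, one sample per
## pixel, 32-bit IEEE float. The reader supports exactly (and only) the
## layout the writer emits. A JSON sidecar carries acquisition metadata.

TIFF_IFD_TAGS <- 10L # tags written per page (see write_mbr_tiff)

#' Write an MBR frame sequence as multi-page TIFF plus JSON sidecar
#'
#' One page per frame, 32-bit float, arbitrary MBR units; metadata
#' (`frame_rate_hz`, `acquisition_s`, `units`) goes to `<path>.json` next
#' to the stack.
#'
#' @param seq An [mbr_frames()].
#' @param path Output `.tif` path.
#' @param sidecar Sidecar path (default: `path` with a `.json` extension).
#' @return Invisibly, `c(tiff = path, sidecar = sidecar)`.
#' @export
write_mbr_tiff <- function(seq, path,
                           sidecar = paste0(tools::file_path_sans_ext(path),
                                            ".json")) {
  stopifnot(inherits(seq, "mbr_frames"))
  d <- dim(seq$frames)
  h <- d[1L]; w <- d[2L]; nt <- d[3L]
  page_bytes <- w * h * 4L
  ifd_bytes <- 2L + TIFF_IFD_TAGS * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2A, 0x00)), con) # "II", magic 42
  writeBin(as.integer(8L + page_bytes), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT packed into the low half of the value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  offset <- 8L
  for (k in seq_len(nt)) {
    # page data (row-major), then its IFD
    writeBin(as.numeric(t(seq$frames[, , k])), con, size = 4,
             endian = "little")
    data_off <- offset
    ifd_off <- data_off + page_bytes
    next_off <- if (k < nt) ifd_off + ifd_bytes + page_bytes else 0L
    writeBin(as.integer(TIFF_IFD_TAGS), con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)            # ImageWidth
    entry(257L, 4L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)     # StripOffsets
    entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
    entry(278L, 4L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)   # StripByteCounts
    entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_bytes
  }
  jsonlite::write_json(
    list(frame_rate_hz = seq$frame_rate_hz,
         acquisition_s = seq$acquisition_s, units = "AU"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = path, sidecar = sidecar))
}

#' Read an MBR frame sequence written by [write_mbr_tiff()]
#'
#' @param path `.tif` path.
#' @param sidecar Sidecar JSON path (default: `path` with `.json`).
#' @return An [mbr_frames()].
#' @export
read_mbr_tiff <- function(path,
                          sidecar = paste0(tools::file_path_sans_ext(path),
                                           ".json")) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (!identical(as.integer(raw[1:2]), c(0x49L, 0x49L)) || u16(2L) != 42L) {
    stop("not a little-endian TIFF written by this package", call. = FALSE)
  }
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0L) {
    n_tags <- u16(ifd)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd + 2L + (i - 1L) * 12L
      tag <- u16(base)
      type <- u16(base + 2L)
      tags[[as.character(tag)]] <- if (type == 3L) u16(base + 8L) else u32(base + 8L)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) {
      stop("unsupported TIFF layout: missing required tags", call. = FALSE)
    }
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
      stop("unsupported TIFF layout: compressed data", call. = FALSE)
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    off <- tags[["273"]]; nb <- tags[["279"]]
    vals <- readBin(raw[(off + 1):(off + nb)], "numeric", n = w * h,
                    size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2L + n_tags * 12L)
  }
  meta <- jsonlite::read_json(sidecar)
  arr <- array(unlist(pages),
               dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  mbr_frames(arr, meta$frame_rate_hz, meta$acquisition_s)
}

#' Write region masks as a single-page TIFF
#'
#' Vessel pixels are written as 255, tissue as 0 (float samples, same
#' minimal layout as [write_mbr_tiff()]).
#'
#' @param masks A [region_masks()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_masks_tiff <- function(masks, path) {
  stopifnot(inherits(masks, "region_masks"))
  m <- array(ifelse(masks$vessel, 255, 0), dim = c(dim(masks$vessel), 1L))
  fake <- structure(list(frames = m, frame_rate_hz = 1, acquisition_s = 1),
                    class = "mbr_frames")
  write_mbr_tiff(fake, path)
  invisible(path)
}
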