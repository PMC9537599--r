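# Image and metadata I/O.
#
# Float images are serialized as 16-bit grayscale PNG (quantization error
# bounded by 1/65535) or as NIfTI float32; label masks as 8-bit PNG or NIfTI
# integers. The png package reads 16-bit PNGs but only writes 8-bit ones, so
# the 16-bit encoder (filter-0 scanlines over a zlib stream) lives here.

# CRC-32 in unsigned double arithmetic. R's native integers cannot hold
# 0x80000000 (that bit pattern is NA_integer_), so 32-bit states are kept as
# doubles in [0, 2^32) and xor-ed in 16-bit halves.
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

crc32_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (c %% 2) xor32(3988292384, c %/% 2) else c %/% 2
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- 4294967295
  for (b in as.integer(bytes))
    c <- xor32(crc32_table[bitwXor(c %% 256, b) + 1], c %/% 256)
  xor32(c, 4294967295)
}

u32be <- function(x) {
  b <- numeric(4)
  for (i in 4:1) { b[i] <- x %% 256; x <- x %/% 256 }
  as.raw(b)
}

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(u32be(length(data)), td, u32be(crc32(td)))
}

write_png16 <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  q <- round(pmin(pmax(img, 0), 1) * 65535)
  hi <- q %/% 256; lo <- q %% 256
  sl <- raw(h * (1 + 2 * w))
  idx <- 1
  for (r in seq_len(h)) {
    sl[idx] <- as.raw(0)
    sl[(idx + 1):(idx + 2 * w)] <- as.raw(as.vector(rbind(hi[r, ], lo[r, ])))
    idx <- idx + 1 + 2 * w
  }
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(sl, type = "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

img_format <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop(sprintf("unsupported image format: '%s' (use .png, .nii, .nii.gz)",
                    basename(path)))
}

#' Read / write 2-D grayscale images
#'
#' Float images round-trip within 1/65535 through 16-bit PNG and exactly
#' through NIfTI float32; integer label masks round-trip exactly.
#'
#' @param path file with extension `.png`, `.nii` or `.nii.gz`.
#' @param img matrix of intensities in `[0, 1]` (`write_image`) or of small
#'   non-negative integer labels (`write_mask`).
#' @return `read_image` returns a numeric matrix in `[0, 1]`; `read_mask` an
#'   integer matrix.
#' @export
read_image <- function(path) {
  fmt <- img_format(path)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (fmt == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) {
      if (dim(x)[3] > 2) stop("multi-channel PNG input is unsupported")
      x <- x[, , 1]
    }
    x
  } else {
    x <- as.array(RNifti::readNifti(path))
    x <- drop(x)
    if (length(dim(x)) != 2L) stop("NIfTI input must contain a single 2-D slice")
    x
  }
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  if (img_format(path) == "png") write_png16(img, path)
  else RNifti::writeNifti(RNifti::asNifti(array(img, c(dim(img), 1L)),
                                          datatype = "float"), path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  if (img_format(path) == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  } else {
    x <- drop(as.array(RNifti::readNifti(path)))
    matrix(as.integer(round(x)), nrow(x), ncol(x))
  }
}

#' @rdname read_image
#' @export
write_mask <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 255))
  if (img_format(path) == "png") png::writePNG(img / 255, path)
  else RNifti::writeNifti(RNifti::asNifti(array(as.integer(img),
                                                c(dim(img), 1L)),
                                          datatype = "int16"), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, package versions, a checksum of
#' the input cohort CSV and the output paths, as JSON. Written before a run
#' produces any other output so that every run is replayable.
#'
#' @param path output JSON path.
#' @param config arbitrary configuration list.
#' @param seed root seed.
#' @param cohort_csv optional path to the input cohort table.
#' @param outputs character vector of intended output paths.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, cohort_csv = NULL,
                           outputs = character()) {
  man <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cardiosynth")),
    r_version = R.version.string,
    seed = seed,
    cohort_checksum = if (!is.null(cohort_csv))
      unname(tools::md5sum(cohort_csv)) else NULL,
    config = config,
    outputs = outputs)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", force = TRUE), path)
  invisible(man)
}
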