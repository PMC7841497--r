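#' Read / write numeric arrays in NPY format
#'
#' Minimal NPY (version 1.0) support for exchanging phase movies with
#' Python-based tooling: little-endian float64 arrays of any rank, C or
#' Fortran element order on read, C order on write.
#'
#' `write_phase_movie_npy` / `read_phase_movie_npy` wrap these for
#' [phase_movie] objects, carrying `dt_ms` and `pixel_mm` in a JSON sidecar
#' (`<path>.json`) and the mask in `<path>.mask.npy`.
#'
#' @param x numeric array or vector.
#' @param path file path.
#' @return `read_npy` returns an array with the stored shape; writers return
#'   `path` invisibly.
#' @export
write_npy <- function(x, path) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%s), }",
                    paste0(paste(d, collapse = ", "),
                           if (length(d) == 1L) "," else ""))
  unpadded <- 10L + nchar(header) + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  # C order: last axis fastest
  v <- if (length(d) > 1L) as.vector(aperm(array(x, d), rev(seq_along(d)))) else as.vector(x)
  writeBin(as.numeric(v), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  if (!length(shape)) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  x <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    stop("unsupported NPY dtype: ", descr))
  if (length(shape) <= 1L) return(x)
  if (fortran) array(x, shape)
  else aperm(array(x, rev(shape)), rev(seq_along(shape)))
}

#' @rdname write_npy
#' @param movie a [phase_movie].
#' @export
write_phase_movie_npy <- function(movie, path) {
  write_npy(movie$values, path)
  write_npy(movie$mask * 1, paste0(path, ".mask.npy"))
  jsonlite::write_json(list(dt_ms = movie$dt_ms, pixel_mm = movie$pixel_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_npy
#' @export
read_phase_movie_npy <- function(path) {
  values <- read_npy(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(dt_ms = 1, pixel_mm = 1)
  mask_path <- paste0(path, ".mask.npy")
  mask <- if (file.exists(mask_path)) read_npy(mask_path) > 0 else NULL
  phase_movie(values, dt_ms = as.numeric(meta$dt_ms),
              pixel_mm = as.numeric(meta$pixel_mm), mask = mask)
}
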