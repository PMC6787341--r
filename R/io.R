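# File formats. Spot tables travel as TSV, observation tables as CSV,
# scalar/tensor volumes as NIfTI-1, tractograms as MRtrix TCK, ground
# truth and manifests as JSON, configs as YAML. The NIfTI-1 and TCK
# routines are deliberately minimal (single-file .nii/.nii.gz, float
# data, sform affine) since no R NIfTI/TCK reader is available here.

#' Read / write an RPPM spot table (TSV)
#'
#' Columns: `sample_id`, `block_id`, `dilution_step`, `deposition`,
#' `raw`, `background`, `snr`.
#'
#' @param path File path.
#' @return `read_spot_table()`: a spot-table tibble.
#' @export
read_spot_table <- function(path) {
  spots <- readr::read_tsv(path, show_col_types = FALSE)
  validate_spot_table(spots)
  spots
}

#' @param spots Spot-table tibble.
#' @rdname read_spot_table
#' @export
write_spot_table <- function(spots, path) {
  validate_spot_table(spots)
  readr::write_tsv(spots, path)
  invisible(path)
}

#' Read / write observation tables (long-format CSV)
#'
#' @param path File path.
#' @return A tibble (`subject_id`, `injury`, `day`, `value`, ...).
#' @export
read_observations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @param obs Observation tibble.
#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs, path)
  invisible(path)
}

nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64")

#' Write a volume as NIfTI-1
#'
#' Single-file NIfTI-1 (`.nii` or `.nii.gz`), float32 data, affine
#' stored in the sform. Accepts a [scalar_volume()], [tensor_volume()]
#' or a bare 3D/4D array plus affine.
#'
#' @param volume Volume object or array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 affine when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, affine = NULL) {
  if (inherits(volume, c("scalar_volume", "tensor_volume"))) {
    affine <- volume$affine
    dat <- volume$data
  } else {
    dat <- volume
    if (is.null(affine)) affine <- diag(4)
  }
  nd <- length(dim(dat))
  stopifnot(nd %in% c(3, 4))
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(dat)
  dims[dims == 0] <- 1L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, type = "integer") {
    writeBin(x, con, size = size, endian = "little")
  }
  pad <- function(n) writeBin(raw(n), con)
  wchar <- function(s, n) {
    r <- raw(n)
    b <- utf8ToInt(substr(s, 1, n - 1))
    if (length(b)) r[seq_along(b)] <- as.raw(b)
    writeBin(r, con)
  }
  writeBin(348L, con, size = 4, endian = "little")
  pad(36)                                   # data_type..dim_info
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")   # intent_p1..p3
  writeBin(c(0L, 16L, 32L, 0L), con, size = 2, endian = "little")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, vs, rep(1, 4))
  writeBin(as.numeric(pixdim[1:8]), con, size = 4, endian = "little")
  writeBin(c(352, 1, 0), con, size = 4, endian = "little") # vox_offset, scl
  writeBin(0L, con, size = 2, endian = "little")           # slice_end
  writeBin(as.raw(c(0, 2)), con)                           # slice_code, units=mm
  writeBin(numeric(4), con, size = 4, endian = "little")   # cal/slice/toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")    # glmax, glmin
  wchar("tbimarkers", 80)
  wchar("", 24)
  writeBin(c(0L, 1L), con, size = 2, endian = "little")    # qform=0, sform=1
  writeBin(numeric(6), con, size = 4, endian = "little")   # quatern + qoffset
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4, endian = "little")
  wchar("", 16)
  writeBin(c(as.raw(utf8ToInt("n")), as.raw(utf8ToInt("+")),
             as.raw(utf8ToInt("1")), raw(1)), con)
  pad(4)                                                   # no extensions
  writeBin(as.numeric(dat), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Minimal single-file reader: little-endian, datatypes uint8/int16/
#' int32/float32/float64, affine from the sform (falling back to pixdim
#' spacing). Returns the array with its affine attached.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return Array (3D or 4D) with attribute `affine`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = "little")
  }
  sizeof <- rd(0, "integer", 1, 4)
  if (sizeof != 348) stop("not a little-endian NIfTI-1 file", call. = FALSE)
  dims <- rd(40, "integer", 8, 2)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  datatype <- rd(70, "integer", 1, 2)
  dt <- nifti_datatypes[as.character(datatype)]
  if (is.na(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  vox_offset <- rd(108, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  affine <- diag(4)
  if (sform_code > 0) {
    srow <- rd(280, "numeric", 12, 4)
    affine[1:3, ] <- matrix(srow, 3, 4, byrow = TRUE)
  } else {
    pixdim <- rd(76, "numeric", 8, 4)
    diag(affine)[1:3] <- pixdim[2:4]
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  dat <- switch(dt,
    uint8 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    int16 = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    int32 = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8, endian = "little"))
  arr <- array(dat, dim = shape)
  attr(arr, "affine") <- affine
  arr
}

#' Write / read a tractogram as MRtrix TCK
#'
#' Streamlines are stored as float32 triplets in world mm, separated by
#' NaN triplets and terminated by an Inf triplet, following the MRtrix
#' track-file layout.
#'
#' @param tractogram List of n x 3 streamline matrices.
#' @param path Output `.tck` path.
#' @return `write_tck()`: `path` invisibly; `read_tck()`: list of
#'   streamline matrices.
#' @export
write_tck <- function(tractogram, path) {
  stopifnot(length(tractogram) >= 1)
  base <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                 length(tractogram), "\nfile: . ")
  # fixed-point search for the data offset (header length depends on it)
  offset <- nchar(base) + nchar("END\n") + 4
  repeat {
    hdr <- paste0(base, offset, "\nEND\n")
    if (nchar(hdr) <= offset) break
    offset <- nchar(hdr)
  }
  hdr <- paste0(base, offset, "\nEND\n")
  hdr <- paste0(hdr, strrep(" ", offset - nchar(hdr)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in tractogram) {
    writeBin(as.numeric(t(as.matrix(s))), con, size = 4, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: text lines until END
  lines <- character()
  repeat {
    ln <- character()
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == charToRaw("\n")) break
      ln <- c(ln, rawToChar(ch))
    }
    line <- paste(ln, collapse = "")
    lines <- c(lines, line)
    if (grepl("^END", line)) break
    if (length(lines) > 1000) stop("malformed TCK header", call. = FALSE)
  }
  if (lines[1] != "mrtrix tracks") stop("not a TCK file", call. = FALSE)
  fl <- grep("^file:", lines, value = TRUE)
  offset <- as.integer(sub("^file:\\s*\\.\\s*", "", fl[1]))
  dt <- grep("^datatype:", lines, value = TRUE)
  if (length(dt) && !grepl("Float32LE", dt[1])) {
    stop("only Float32LE TCK supported", call. = FALSE)
  }
  close(con)
  con <- file(path, "rb")
  readBin(con, "raw", offset)
  vals <- readBin(con, "numeric", file.size(path), size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur)) out[[length(out) + 1]] <- do.call(rbind, cur)
      cur <- NULL
    } else {
      cur <- c(cur, list(p))
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- do.call(rbind, cur)
  out
}

#' Write ground truth / manifests as JSON
#'
#' @param x A list (ground-truth record, manifest, ...).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_json_sidecar <- function(x, path) {
  x <- rapply(x, unclass, classes = c("fivepl", "slide_sim_config",
                                      "tract_sim_config", "tensor_sim_config",
                                      "behavior_sim_config"),
              how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", force = TRUE)
  invisible(path)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path `.yaml` path.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @param config Named list.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
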