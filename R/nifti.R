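# Minimal NIfTI-1 single-file (.nii) I/O.  No pre-installed R package
# provides the format in this environment, so the 348-byte header is read
# and written directly.  Supported datatypes: uint8 (2), int16 (4),
# int32 (8), float32 (16), float64 (64).  Orientation metadata beyond
# pixdim is not interpreted; images are treated as plain grids.

nifti_datatypes <- list(
  "2"  = list(what = "integer", size = 1, signed = FALSE, r = "uint8"),
  "4"  = list(what = "integer", size = 2, signed = TRUE,  r = "int16"),
  "8"  = list(what = "integer", size = 4, signed = TRUE,  r = "int32"),
  "16" = list(what = "double",  size = 4, signed = TRUE,  r = "float32"),
  "64" = list(what = "double",  size = 8, signed = TRUE,  r = "float64")
)

#' Write a 3-D or 4-D array as a NIfTI-1 file
#'
#' @param img numeric/integer array (3-D or 4-D).
#' @param path output path ending in `.nii` (uncompressed).
#' @param voxel_size voxel dimensions in mm (scalar or 3-vector).
#' @param tr repetition time in seconds for the 4th dimension.
#' @param datatype `"float32"` (default), `"int16"`, `"int32"`,
#'   `"uint8"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = 1.5, tr = 2.5,
                        datatype = c("float32", "int16", "int32",
                                     "uint8", "float64")) {
  datatype <- match.arg(datatype)
  code <- as.integer(names(nifti_datatypes)[vapply(nifti_datatypes,
                                                   function(d) d$r,
                                                   "") == datatype])
  spec <- nifti_datatypes[[as.character(code)]]
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L)) stop("img must be a 3-D or 4-D array")
  dims <- c(nd, dim(img), rep(1L, 7 - nd))
  voxel_size <- rep(voxel_size, length.out = 3)
  pixdim <- c(1, voxel_size, if (nd == 4) tr else 1, rep(0, 3))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused through dim_info
  wi(dims, 2)                                   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1-3, intent_code
  wi(code, 2); wi(spec$size * 8L, 2)            # datatype, bitpix
  wi(0L, 2)                                     # slice_start
  wf(pixdim)                                    # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max/min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wf(rep(0, 18))                                # quatern + srows
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  if (spec$what == "integer") {
    writeBin(as.integer(round(img)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(img), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] (or any uncompressed
#' single-file NIfTI-1 with a supported datatype)
#'
#' @param path path to a `.nii` file.
#' @return list with `data` (array), `voxel_size`, `tr`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed,
            endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  sizeof <- ri(1, 4)
  if (sizeof != 348) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dims <- ri(8, 2)
  rf(3); ri(1, 2)                    # intent_p1-3, intent_code
  code <- ri(1, 2)
  spec <- nifti_datatypes[[as.character(code)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", code)
  ri(1, 2); ri(1, 2)                 # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  seek(con, vox_offset)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  data <- if (spec$what == "integer")
    ri(n, spec$size, signed = spec$signed) else
    readBin(con, "double", n = n, size = spec$size, endian = "little")
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  list(data = array(data, shape), voxel_size = pixdim[2:4],
       tr = if (nd >= 4) pixdim[5] else NA_real_, datatype = spec$r)
}

#' Export a BOLD simulation to NIfTI + events TSV
#'
#' Writes the 4-D series (`bold.nii`, float32), the ROI label image
#' (`roi_labels.nii`, int16) and the events table (`events.tsv`) into a
#' directory.
#'
#' @param bold a `bold_series`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bold_dataset <- function(bold, dir) {
  stopifnot(inherits(bold, "bold_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(bold$data, file.path(dir, "bold.nii"),
              voxel_size = bold$voxel_size, tr = bold$tr, "float32")
  write_nifti(bold$roi_labels, file.path(dir, "roi_labels.nii"),
              voxel_size = bold$voxel_size, datatype = "int16")
  write_events_tsv(bold$ground_truth$design, file.path(dir, "events.tsv"))
  invisible(dir)
}
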