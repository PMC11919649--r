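# Minimal NIfTI-1 reader/writer (float32 payloads, plain or gzip).
# No NIfTI-capable R package is available in the deployment environment,
# so the 348-byte header is handled directly. Only the features the
# pipeline needs are implemented: dim/pixdim, sform affine, common
# datatypes on read, float32 on write.

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as NIfTI-1 (float32)
#'
#' @param volume numeric array, 3 or 4 dimensions; axis order `(x, y, z[,
#'   acquisition])`
#' @param path output path (`.nii` or `.nii.gz`)
#' @param pixdim voxel dimensions (mm / ms), recycled to 4
#' @param affine optional 3x4 (or 4x4) voxel-to-world matrix; default
#'   `diag(pixdim)`
#' @param description up to 79 characters stored in the header
#' @return `path`, invisibly
#' @export
write_nifti <- function(volume, path, pixdim = c(1, 1, 1, 1), affine = NULL,
                        description = "impulsedr") {
  nd <- length(dim(volume))
  stopifnot(nd %in% c(3L, 4L))
  dims <- dim(volume)
  pixdim <- rep_len(pixdim, 4)
  if (is.null(affine)) {
    affine <- cbind(diag(pixdim[1:3]), c(0, 0, 0))
  } else {
    affine <- affine[1:3, 1:4]
  }
  con <- .nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(len, length(raw)))],
               raw(max(0, len - length(raw)))), con)
  }
  wi(348, 4)                        # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name (unused)
  wi(0, 4); wi(0, 2); wc("", 1); wc("r", 1)  # extents, session_error, regular, dim_info
  wi(c(nd, dims, rep(1, 7 - nd)), 2)          # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0, 2)                          # intent_code
  wi(16, 2)                         # datatype = float32
  wi(32, 2)                         # bitpix
  wi(0, 2)                          # slice_start
  wf(c(1, pixdim, rep(1, 8 - 1 - 4)))  # pixdim[8] (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)    # slice_end, slice_code, xyzt_units
  wf(0); wf(0)                      # cal_max, cal_min
  wf(0); wi(0, 4); wi(0, 4)         # slice_duration, toffset, glmax
  wi(0, 4)                          # glmin
  wc(description, 80); wc("", 24)   # descrip, aux_file
  wi(0, 2); wi(1, 2)                # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                     # quatern b,c,d, qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc("", 16)                        # intent_name
  wc("n+1", 4)                      # magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.numeric(volume), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports datatypes uint8, int16, int32, float32, float64 with
#' slope/intercept scaling; returns the sform affine when present.
#'
#' @param path `.nii` or `.nii.gz` file
#' @return list with `data` (array), `affine` (3x4), `pixdim`
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (hdr_size != 348) stop("not a NIfTI-1 file (sizeof_hdr = ", hdr_size, ")",
                            call. = FALSE)
  readBin(con, "raw", n = 36)  # data_type..dim_info
  dims <- ri(8, 2)
  rf(3); ri(1, 2)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  readBin(con, "raw", n = 2 + 1 + 1)
  rf(2); rf(1); ri(1, 4); ri(1, 4); ri(1, 4)
  readBin(con, "raw", n = 80 + 24)
  ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- rbind(rf(4), rf(4), rf(4))
  readBin(con, "raw", n = 16 + 4)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  nvox <- prod(shape)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n = nvox, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n = nvox, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = nvox, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0) srow else cbind(diag(pixdim[2:4]), c(0, 0, 0))
  list(data = array(data, shape), affine = affine, pixdim = pixdim[2:5])
}

#' Validate a mask volume against an acquisition volume
#' @param mask 3D array expected to contain only 0/1
#' @param vol4d 4D array whose spatial grid the mask must match
#' @return TRUE invisibly; error otherwise
#' @export
validate_mask <- function(mask, vol4d) {
  if (!all(unique(as.vector(mask)) %in% c(0, 1)))
    stop("mask must contain only 0/1 values", call. = FALSE)
  if (!identical(dim(mask), dim(vol4d)[1:3]))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ",
         paste(dim(vol4d)[1:3], collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
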