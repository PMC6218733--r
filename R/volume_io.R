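# Volume and label-map I/O: NIfTI-1 (.nii, .nii.gz) and MetaImage (.mha).
#
# Volumes are kept in the index order delivered by the file header; the third
# index is treated as the axial (slice) axis throughout the package. No
# reorientation is performed: inputs are assumed co-registered and
# skull-stripped, so the only masking ever needed is intensity > 0.

MODALITIES <- c("T1", "T1c", "T2", "FLAIR")
BRATS_LABELS <- 0:4

#' MRI volume container
#'
#' A light S3 container for one modality's 3D intensity grid. Intensities are
#' nonnegative reals in arbitrary scanner units (BraTS volumes are stored as
#' signed 16-bit integers but only positive values carry signal; negatives are
#' clipped on construction).
#'
#' @param data 3D numeric array of intensities; negatives are clipped to 0.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param modality one of `"T1"`, `"T1c"`, `"T2"`, `"FLAIR"`.
#' @return An object of class `glioseg_volume` with fields `data`, `spacing`,
#'   `modality`, `axis_order`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), modality = "T2") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_glioseg("not_3d", "volume data must be a 3D array")
  modality <- match.arg(modality, MODALITIES)
  data[data < 0] <- 0
  storage.mode(data) <- "double"
  if (any(dim(data) < 1L))
    stop_glioseg("not_3d", "all three axis lengths must be >= 1")
  structure(
    list(data = data, spacing = as.numeric(spacing), modality = modality,
         axis_order = "as-stored (third index = axial slice)"),
    class = "glioseg_volume")
}

#' @export
print.glioseg_volume <- function(x, ...) {
  cat(sprintf("<glioseg_volume> %s  %s voxels  spacing %s mm  range [%g, %g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' BraTS-convention label map
#'
#' Integer 3D grid over \{0,1,2,3,4\}: 1 necrosis, 2 edema, 3 nonenhancing
#' tumor, 4 enhancing tumor, 0 everything else.
#'
#' @param data 3D integer-valued array with values in 0..4.
#' @param spacing numeric length-3 voxel size in mm.
#' @return Object of class `glioseg_label_map`.
#' @export
label_map <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_glioseg("not_3d", "label map must be a 3D array")
  if (anyNA(data) || !all(data %in% BRATS_LABELS))
    stop_glioseg("invalid_labels", "label map values must all lie in {0,1,2,3,4}")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "glioseg_label_map")
}

#' @export
print.glioseg_label_map <- function(x, ...) {
  tab <- table(factor(x$data, levels = BRATS_LABELS))
  cat(sprintf("<glioseg_label_map> %s voxels  counts: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " ")))
  invisible(x)
}

stop_glioseg <- function(kind, msg) {
  stop(structure(class = c(paste0("glioseg_", kind), "glioseg_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# ---- NIfTI-1 ----------------------------------------------------------------

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE))  # uint16

read_nifti_raw <- function(path) {
  con <- gzfile(path, "rb")  # transparently handles both .nii and .nii.gz
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop_glioseg("unsupported_format", sprintf("'%s': truncated NIfTI header", path))
  endian <- "little"
  if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != 348L)
      stop_glioseg("unsupported_format",
                   sprintf("'%s': not a NIfTI-1 file (sizeof_hdr != 348)", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_glioseg("unsupported_format",
                 sprintf("'%s': bad NIfTI magic '%s'", path, magic))
  int16 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L, endian = endian)
  flt32 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L, endian = endian)
  dims <- int16(40L, 8L)
  ndim <- dims[1L]
  shape <- dims[2L:(1L + max(ndim, 1L))]
  shape <- shape[shape > 0L]
  if (length(shape) > 3L && prod(shape[-(1:3)]) == 1L) shape <- shape[1:3]
  if (length(shape) != 3L)
    stop_glioseg("not_3d", sprintf("'%s': expected 3D data, got dims %s",
                                   path, paste(shape, collapse = "x")))
  datatype <- int16(70L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop_glioseg("unsupported_format",
                 sprintf("'%s': unsupported NIfTI datatype code %d", path, datatype))
  pixdim <- flt32(76L, 8L)
  vox_offset <- flt32(108L)
  scl_slope <- flt32(112L); scl_inter <- flt32(116L)
  skip <- vox_offset - 348L
  if (magic == "ni1") {  # separate .img not supported
    stop_glioseg("unsupported_format",
                 sprintf("'%s': two-file NIfTI (.hdr/.img) is not supported", path))
  }
  if (skip > 0L) readBin(con, "raw", n = as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    stop_glioseg("unsupported_format", sprintf("'%s': truncated voxel data", path))
  vals <- as.double(vals)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape), spacing = abs(pixdim[2:4]))
}

write_nifti <- function(data, spacing, path, datatype = c("float32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  code <- c(float32 = 16L, int16 = 4L, uint8 = 2L)[[datatype]]
  bitpix <- c(float32 = 32L, int16 = 16L, uint8 = 8L)[[datatype]]
  shape <- dim(data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                    # sizeof_hdr
  wr(36L)                         # data_type..dim_info
  wi(c(3L, shape, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wr(14L)                         # intent_p1..intent_code
  wi(code, 2L); wi(bitpix, 2L); wi(0L, 2L)  # datatype, bitpix, slice_start
  wf(c(1, spacing, 0, 0, 0, 0))   # pixdim[8]
  wf(352)                         # vox_offset
  wf(1); wf(0)                    # scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(c(2L, 0L)), con)  # slice_end, slice_code, xyzt_units=mm
  wf(c(0, 0, 0)); wi(0L, 4L)      # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)               # glmax, glmin
  wr(80L + 24L)                   # descrip, aux_file
  wi(c(0L, 0L), 2L)               # qform_code, sform_code
  wf(numeric(18))                 # quatern/qoffset/srow
  wr(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wr(4L)                          # extension flag
  vals <- as.vector(data)
  if (datatype == "float32") writeBin(as.double(vals), con, size = 4L, endian = "little")
  else writeBin(as.integer(round(vals)), con, size = bitpix %/% 8L, endian = "little")
  invisible(path)
}

# ---- MetaImage (.mha, local uncompressed) -----------------------------------

MET_TYPES <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE))

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  keys <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop_glioseg("unsupported_format",
                   sprintf("'%s': no ElementDataFile key in MetaImage header", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L)
      stop_glioseg("unsupported_format", sprintf("'%s': bad MetaImage header line '%s'", path, line))
    keys[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(keys$ElementDataFile, "LOCAL"))
    stop_glioseg("unsupported_format", "only ElementDataFile = LOCAL MetaImage files are supported")
  if (!is.null(keys$CompressedData) && toupper(keys$CompressedData) == "TRUE")
    stop_glioseg("unsupported_format", "compressed MetaImage data is not supported")
  if (!is.null(keys$NDims) && as.integer(keys$NDims) != 3L)
    stop_glioseg("not_3d", sprintf("'%s': expected NDims = 3", path))
  shape <- as.integer(strsplit(trimws(keys$DimSize), "\\s+")[[1]])
  if (length(shape) != 3L)
    stop_glioseg("not_3d", sprintf("'%s': DimSize must have 3 entries", path))
  spacing <- if (!is.null(keys$ElementSpacing))
    as.numeric(strsplit(trimws(keys$ElementSpacing), "\\s+")[[1]]) else c(1, 1, 1)
  dt <- MET_TYPES[[keys$ElementType]]
  if (is.null(dt))
    stop_glioseg("unsupported_format",
                 sprintf("'%s': unsupported ElementType %s", path, keys$ElementType))
  msb <- !is.null(keys$BinaryDataByteOrderMSB) && toupper(keys$BinaryDataByteOrderMSB) == "TRUE"
  vals <- readBin(con, dt$what, n = prod(shape), size = dt$size, signed = dt$signed,
                  endian = if (msb) "big" else "little")
  if (length(vals) < prod(shape))
    stop_glioseg("unsupported_format", sprintf("'%s': truncated voxel data", path))
  list(data = array(as.double(vals), dim = shape), spacing = spacing)
}

write_mha <- function(data, spacing, path, datatype = c("float32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  met <- c(float32 = "MET_FLOAT", int16 = "MET_SHORT", uint8 = "MET_UCHAR")[[datatype]]
  size <- c(float32 = 4L, int16 = 2L, uint8 = 1L)[[datatype]]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %s", paste(dim(data), collapse = " ")),
           sprintf("ElementSpacing = %s", paste(spacing, collapse = " ")),
           sprintf("ElementType = %s", met),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  vals <- as.vector(data)
  if (datatype == "float32") writeBin(as.double(vals), con, size = 4L, endian = "little")
  else writeBin(as.integer(round(vals)), con, size = size, endian = "little")
  invisible(path)
}

# ---- public I/O -------------------------------------------------------------

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.mha$", path, ignore.case = TRUE)) "mha"
  else stop_glioseg("unsupported_format",
                    sprintf("'%s': unrecognized extension (expected .nii, .nii.gz or .mha)", path))
}

#' Read an MRI volume
#'
#' Reads a 3D NIfTI-1 (`.nii`, `.nii.gz`) or local uncompressed MetaImage
#' (`.mha`) volume. Negative intensities (BraTS stores signed 16-bit but only
#' positive values carry signal) are clipped to 0; shape and voxel spacing are
#' taken from the header.
#'
#' @param path path to the volume file.
#' @param modality modality tag to attach (`"T1"`, `"T1c"`, `"T2"`, `"FLAIR"`).
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = "T2") {
  if (!file.exists(path))
    stop_glioseg("missing_file", sprintf("file not found: '%s'", path))
  raw <- switch(volume_format(path), nifti = read_nifti_raw(path), mha = read_mha(path))
  volume(raw$data, spacing = raw$spacing, modality = modality)
}

#' Write an MRI volume
#'
#' @param vol a [volume()].
#' @param path destination (`.nii`, `.nii.gz` or `.mha`).
#' @param datatype on-disk element type; `"float32"` (default) is lossless for
#'   this package's volumes, `"int16"` matches BraTS storage.
#' @export
write_volume <- function(vol, path, datatype = "float32") {
  stopifnot(inherits(vol, "glioseg_volume"))
  switch(volume_format(path),
         nifti = write_nifti(vol$data, vol$spacing, path, datatype),
         mha = write_mha(vol$data, vol$spacing, path, datatype))
  invisible(path)
}

#' Read a BraTS label map
#'
#' @param path path to a NIfTI or MetaImage integer label volume.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path))
    stop_glioseg("missing_file", sprintf("file not found: '%s'", path))
  raw <- switch(volume_format(path), nifti = read_nifti_raw(path), mha = read_mha(path))
  label_map(raw$data, spacing = raw$spacing)
}

#' Write a BraTS label map
#'
#' Label maps are written as unsigned 8-bit integers; the round trip through
#' [read_label_map()] is integer-exact.
#'
#' @param map a [label_map()].
#' @param path destination (`.nii`, `.nii.gz` or `.mha`).
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "glioseg_label_map"))
  if (!all(map$data %in% BRATS_LABELS))
    stop_glioseg("invalid_labels", "label map values must all lie in {0,1,2,3,4}")
  switch(volume_format(path),
         nifti = write_nifti(map$data, map$spacing, path, "uint8"),
         mha = write_mha(map$data, map$spacing, path, "uint8"))
  invisible(path)
}

#' Brain mask of a skull-stripped volume
#'
#' Inputs are assumed skull-stripped with zero background, so the brain mask
#' is simply intensity > 0. No morphological cleanup is applied.
#'
#' @param vol a [volume()].
#' @return A logical 3D array of the volume's shape.
#' @export
brain_mask <- function(vol) {
  stopifnot(inherits(vol, "glioseg_volume"))
  vol$data > 0
}
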