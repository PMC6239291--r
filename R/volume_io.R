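#' Read and write density volumes
#'
#' Volumes are exchanged as NIfTI (`.nii`, `.nii.gz`) through RNifti or as
#' uncompressed MetaImage (`.mhd` + `.raw`, or self-contained `.mha`).
#' The array is stored with this package's `(slice, row, col)` axis
#' labelling; spacing is taken from the file's voxel-dimension metadata in
#' the same axis order as the array.
#'
#' @param vol A [density_volume()] (or, for masks, a logical array plus
#'   `spacing_mm`).
#' @param path Output/input file path; the extension selects the format.
#' @return `read_volume()` returns a [density_volume()];
#'   `write_volume()` returns `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  if (ext == "nii") {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing_mm
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("mhd", "mha")) {
    write_metaimage(vol$values, vol$spacing_mm, path)
  } else {
    stop_bad_input("unsupported volume format: .", ext)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param units `"density"` (default) or `"hu"`; HU volumes are converted
#'   with `cal`.
#' @param cal A [hu_calibration()] used when `units = "hu"`.
#' @export
read_volume <- function(path, units = c("density", "hu"),
                        cal = hu_calibration()) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_bad_input("volume file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    values <- array(as.numeric(img), dim(img))
    spacing <- RNifti::pixdim(img)[seq_len(3)]
  } else if (ext %in% c("mhd", "mha")) {
    mi <- read_metaimage(path)
    values <- mi$values
    spacing <- mi$spacing
  } else {
    stop_bad_input("unsupported volume format: .", ext)
  }
  if (units == "hu") hu_to_density(values, spacing, cal)
  else density_volume(values, spacing)
}

# --- minimal uncompressed MetaImage support -------------------------------

write_metaimage <- function(values, spacing, path) {
  ext <- tolower(tools::file_ext(path))
  local_data <- ext == "mha"
  raw_name <- if (local_data) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(values), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, scientific = FALSE),
                                    collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", raw_name))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), raw_name), "wb")
    writeBin(as.numeric(values), rawcon, size = 8, endian = "little")
    close(rawcon)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  keys <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop_bad_input("MetaImage header lacks ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    keys[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(keys$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(keys$ElementSpacing, "\\s+")[[1]])
  type <- keys$ElementType
  spec <- switch(type,
                 MET_DOUBLE = list(what = "double", size = 8),
                 MET_FLOAT = list(what = "double", size = 4),
                 MET_SHORT = list(what = "integer", size = 2),
                 MET_USHORT = list(what = "integer", size = 2),
                 MET_UCHAR = list(what = "integer", size = 1),
                 stop_bad_input("unsupported MetaImage ElementType: ", type))
  n <- prod(dims)
  if (identical(keys$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, spec$what, n = n, size = spec$size,
                    endian = "little",
                    signed = !type %in% c("MET_USHORT", "MET_UCHAR"))
  } else {
    rawcon <- file(file.path(dirname(path), keys$ElementDataFile), "rb")
    vals <- readBin(rawcon, spec$what, n = n, size = spec$size,
                    endian = "little",
                    signed = !type %in% c("MET_USHORT", "MET_UCHAR"))
    close(rawcon)
  }
  if (length(vals) != n) stop_bad_input("MetaImage data is truncated")
  list(values = array(as.numeric(vals), dims), spacing = spacing)
}
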