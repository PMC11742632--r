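# NIfTI-1 volume, label-table and results-table I/O. All volumes of one
# study must share grid shape and affine; compatibility is enforced where
# volumes are combined, not silently resampled.

.niftiIntCodes <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [VolumeGrid-class]. Integer-typed
#' files keep integer storage so label volumes round-trip exactly.
#'
#' @param path NIfTI file path.
#' @return A [VolumeGrid-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # strip niftiImage class/attrs
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  }
  hdr <- RNifti::niftiHeader(img)
  if (hdr$datatype %in% .niftiIntCodes) storage.mode(arr) <- "integer"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  .checkAffine(aff)
  volumeGrid(arr, aff)
}

#' Write a 3D volume as NIfTI
#'
#' @param vol a [VolumeGrid-class] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`; gzip inferred from suffix).
#' @param affine used when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, affine = diag(4)) {
  arr <- .vox(vol)
  aff <- .affineOf(vol, affine)
  datatype <- if (is.integer(arr) || is.logical(arr)) "int32" else "double"
  arr <- arr * 1  # drop logical
  img <- RNifti::asNifti(arr, reference = NULL, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a dynamic 4D series
#'
#' Frame times are taken as `k * dtS` from the protocol (NIfTI carries no
#' per-frame timing); the injection time comes from the protocol.
#'
#' @param path 4D NIfTI path.
#' @param protocol an [AcquisitionProtocol-class].
#' @return A [DynamicSeries-class].
#' @export
readDynamic <- function(path, protocol) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # strip niftiImage class/attrs
  if (length(dim(arr)) != 4L) {
    stop("expected a 4D dynamic series: ", path, call. = FALSE)
  }
  n <- dim(arr)[4]
  if (!is.na(protocol@nFrames) && as.integer(protocol@nFrames) != n) {
    stop("frame count mismatch: file has ", n, ", protocol expects ",
         as.integer(protocol@nFrames), call. = FALSE)
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  dynamicSeries(arr, protocolFrameTimes(protocol, n),
                protocol@injectionTimeS, aff)
}

#' Write a dynamic series as 4D NIfTI
#'
#' @param dyn a [DynamicSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDynamic <- function(dyn, path) {
  stopifnot(is(dyn, "DynamicSeries"))
  img <- RNifti::asNifti(dyn@data, reference = NULL, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(dyn@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a region label table
#'
#' Tab-separated with columns `region_id`, `name`, `hemisphere`
#' (`L`/`R`/`midline`) and `lobe`. With `path = NULL` the packaged default
#' 124-region table (matching the synthetic parcellation) is read.
#'
#' @param path TSV path, or `NULL` for the packaged default.
#' @return A data.frame.
#' @export
readLabelTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atlas_labels_124_synthetic.tsv",
                        package = "bbbdmap", mustWork = TRUE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(region_id = "integer", name = "character",
                                   hemisphere = "character", lobe = "character"))
  need <- c("region_id", "name", "hemisphere", "lobe")
  if (!all(need %in% names(tab))) {
    stop("label table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname readLabelTable
#' @param table data.frame as above.
#' @export
writeLabelTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a results table from subject results
#'
#' One row per subject x region plus a `WHOLE_BRAIN` row per subject.
#'
#' @param results list of [SubjectResult-class] objects.
#' @return data.frame with columns `subject_id`, `region_id`, `percent`,
#'   `z`, `flag`.
#' @export
resultsTable <- function(results) {
  if (length(results) == 0L) stop("no subject results", call. = FALSE)
  do.call(rbind, lapply(results, function(r) {
    stopifnot(is(r, "SubjectResult"))
    rbind(
      data.frame(subject_id = r@subjectId, region_id = "WHOLE_BRAIN",
                 percent = r@bbbPercent, z = NA_real_, flag = NA,
                 stringsAsFactors = FALSE),
      data.frame(subject_id = r@subjectId,
                 region_id = as.character(r@regions$region_id),
                 percent = r@regions$percent, z = r@regions$z,
                 flag = r@regions$flag, stringsAsFactors = FALSE))
  }))
}

#' Read / write a results table
#'
#' Tab-separated with header. Integers round-trip exactly; floating-point
#' columns are written with full precision (round-trip error below 1e-12).
#'
#' @param table data.frame as produced by [resultsTable()].
#' @param path TSV path.
#' @return `writeResults` returns `path` invisibly; `readResults` the
#'   data.frame.
#' @export
writeResults <- function(table, path) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("results table is empty", call. = FALSE)
  }
  num <- vapply(table, is.double, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}
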