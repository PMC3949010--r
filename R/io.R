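## Thin volume and table I/O. NIfTI is handled by RNifti, multi-page TIFF
## by the tiff package (both in Suggests); masks travel as unsigned-integer
## label volumes with the table 0 background, 1 bone, 2 fracture, 3 cement,
## 4 cap_lower, 5 cap_upper, 6 marker.

.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Read and write voxel volumes
#'
#' `readVoxelImage()` loads a NIfTI (`.nii`, `.nii.gz`) or multi-page TIFF
#' volume into a [VoxelImage]; NIfTI voxel sizes come from the header,
#' TIFF stacks need `voxelMm` supplied. `writeVoxelImage()` writes the
#' corresponding format (TIFF grayscale is rescaled to \[0,1\] by its
#' maximum, as the format requires).
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @param voxelMm voxel size (mm); required for TIFF, overrides the header
#'   if given for NIfTI.
#' @param originMm physical origin (mm), default 0.
#' @return a [VoxelImage].
#' @export
readVoxelImage <- function(path, voxelMm = NULL, originMm = c(0, 0, 0)) {
  if (.isNifti(path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    img <- RNifti::readNifti(path)
    vox <- voxelMm %||% RNifti::pixdim(img)[1:3]
    return(VoxelImage(array(as.numeric(img), dim(img)[1:3]), vox, originMm))
  }
  if (.isTiff(path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    if (is.null(voxelMm))
      stop("TIFF stacks carry no voxel size; supply voxelMm")
    pages <- tiff::readTIFF(path, all = TRUE)
    a <- simplify2array(lapply(pages, function(p)
      if (length(dim(p)) == 3L) p[, , 1L] else p))
    return(VoxelImage(a, voxelMm, originMm))
  }
  stop("unsupported volume format: ", path)
}

#' @rdname readVoxelImage
#' @param image a [VoxelImage] (or, for `writeMasks()`, a [SpecimenMasks]).
#' @export
writeVoxelImage <- function(image, path) {
  if (.isNifti(path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("writing NIfTI requires the RNifti package")
    img <- RNifti::asNifti(image@data)
    RNifti::pixdim(img) <- image@voxelMm
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (.isTiff(path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the tiff package")
    mx <- max(image@data)
    a <- if (mx > 0) image@data / mx else image@data
    tiff::writeTIFF(lapply(seq_len(dim(a)[3L]), function(k) a[, , k]),
                    path, bits.per.sample = 16L)
    return(invisible(path))
  }
  stop("unsupported volume format: ", path)
}

#' Read and write label-volume masks
#'
#' Masks are stored as unsigned-integer NIfTI label volumes using the
#' package's label table (0 background .. 6 marker).
#'
#' @param masks a [SpecimenMasks].
#' @param path a `.nii` / `.nii.gz` path.
#' @param voxelMm voxel size (mm) recorded in the header.
#' @return `readMasks()` returns a [SpecimenMasks].
#' @export
writeMasks <- function(masks, path, voxelMm = 1) {
  if (!.isNifti(path)) stop("masks are written as NIfTI label volumes")
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package")
  img <- RNifti::asNifti(masks@labels)
  RNifti::pixdim(img) <- rep(voxelMm, length.out = 3L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMasks
#' @export
readMasks <- function(path) {
  if (!.isNifti(path)) stop("masks are read from NIfTI label volumes")
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  new("SpecimenMasks", labels = array(as.integer(img), dim(img)[1:3]))
}

#' Read and write load-displacement curves
#'
#' Plain CSV with header `displacement_mm,load_N`.
#'
#' @param curve data.frame with columns `displacement_mm`, `load_N`.
#' @param path CSV file path.
#' @return `readCurve()` returns the curve data.frame.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(all(c("displacement_mm", "load_N") %in% names(curve)))
  utils::write.csv(curve[c("displacement_mm", "load_N")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write a cohort to disk with a JSON manifest
#'
#' Writes each specimen's image and truth-mask volumes (and, for
#' augmented specimens, their pre-augmentation twins), the simulated
#' load-displacement curves, and a `manifest.json` recording specimen
#' ids, arms, file paths, truth volumes, measured stiffnesses and seeds.
#'
#' @param cohort a cohort list from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing the cohort manifest requires the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(e) {
    vox <- e$specimen@spec@voxelMm
    paths <- list(image = file.path(dir, paste0(e$id, "_image.nii.gz")),
                  masks = file.path(dir, paste0(e$id, "_masks.nii.gz")))
    writeVoxelImage(specimenImage(e$specimen), paths$image)
    writeMasks(truthMasks(e$specimen), paths$masks, voxelMm = vox)
    if (!is.null(e$preSpecimen)) {
      paths$preImage <- file.path(dir, paste0(e$id, "_pre_image.nii.gz"))
      paths$preMasks <- file.path(dir, paste0(e$id, "_pre_masks.nii.gz"))
      writeVoxelImage(specimenImage(e$preSpecimen), paths$preImage)
      writeMasks(truthMasks(e$preSpecimen), paths$preMasks, voxelMm = vox)
    }
    if (!is.null(e$measurement) && nrow(e$measurement@curve) > 0) {
      paths$curve <- file.path(dir, paste0(e$id, "_curve.csv"))
      writeCurve(e$measurement@curve, paths$curve)
    }
    list(id = e$id, arm = e$arm, files = paths,
         truthFractureVolumeMm3 = e$specimen@truthFractureVolumeMm3,
         truthCementVolumeMm3 = e$specimen@truthCementVolumeMm3,
         measuredStiffnessNPerMm = if (!is.null(e$measurement))
           stiffness(e$measurement) else NA_real_,
         seed = e$specimen@spec@seed)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
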