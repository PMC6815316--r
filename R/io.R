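#' Read a 3D volume from NIfTI
#'
#' The canonical on-disk format is NIfTI (optionally gzip-compressed).
#' Volumes are assumed axis-aligned: an orientation matrix with nonzero
#' off-diagonal terms or negative axis directions is rejected with a
#' clear message rather than silently reinterpreted. Files carrying no
#' spatial transform fall back to their pixdim spacing and origin
#' (0, 0, 0).
#'
#' @param path file path (.nii or .nii.gz).
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("format error: cannot read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))  # drop niftiImage attributes
  nd <- length(dim(a))
  if (nd == 4L && dim(a)[4] == 1L) {
    a <- array(a, dim(a)[1:3])
    nd <- 3L
  }
  if (nd != 3L)
    stop("dimensionality error: ", path, " holds ", nd,
         "D data; select a single 3D volume", call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot
  diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop("format error: ", path, " has an oblique orientation matrix; ",
         "only axis-aligned volumes are supported", call. = FALSE)
  if (any(diag(rot) <= 0))
    stop("format error: ", path, " uses a flipped axis convention; ",
         "reorient the volume to positive axis-aligned directions",
         call. = FALSE)
  volume(a, spacing = diag(rot), origin = xf[1:3, 4])
}

#' Write a 3D volume as NIfTI
#'
#' Spacing goes to pixdim and to a diagonal sform/qform whose translation
#' column is the origin, so [read_volume()] round-trips data, spacing and
#' origin exactly.
#'
#' @param vol a [volume()].
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type; `"double"` for intensities,
#'   `"uint8"` for masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "hep_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write a binary liver mask as NIfTI
#'
#' Masks are stored with an integer datatype and must contain only 0 and
#' 1.
#'
#' @param path file path.
#' @return `read_mask` returns a [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$data %in% c(0, 1)))
    stop("format error: ", path, " is not binary ({0,1} voxels expected)",
         call. = FALSE)
  binary_mask(v$data, v$spacing, v$origin)
}

#' @rdname read_mask
#' @param mask a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_mask(mask))
  write_volume(mask, path, datatype = "uint8")
}

#' Read / write landmark tables
#'
#' Tab-delimited with a header row: `label`, `x`, `y`, `z` (mm).
#'
#' @param path file path.
#' @return `read_landmarks` returns a [landmarks()] set.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tb)))
    stop("format error: landmark table must have columns label, x, y, z: ",
         path, call. = FALSE)
  landmarks(tb$label, tb$x, tb$y, tb$z)
}

#' @rdname read_landmarks
#' @param lms a [landmarks()] set.
#' @export
write_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "hep_landmarks"))
  utils::write.table(as.data.frame(lms), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# run manifests ---------------------------------------------------------------

run_manifest <- function(command, config, inputs, outputs, seed, started) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  list(schema_version = "hepalign-manifest-1",
       tool_version = as.character(utils::packageVersion("hepalign")),
       command = command,
       seed = seed,
       config = config,
       inputs = lapply(inputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       outputs = outputs,
       started = started, finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
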