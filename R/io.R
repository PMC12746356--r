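# NIfTI + JSON-sidecar study I/O. Complex volumes are stored as paired
# magnitude and phase files (phase in radians, [-pi, pi]), which is how
# scanner exports usually arrive.

STUDY_VOLUME_NAMES <- c("ref", "tp", "rl", "fh")

#' Write an encoded study to NIfTI files plus a JSON sidecar
#'
#' Emits 8 NIfTI volumes (magnitude and phase for each of the four
#' encoding volumes; deterministic names \code{<vol>_mag.nii} /
#' \code{<vol>_phase.nii} for vol in ref, tp, rl, fh) and
#' \code{study.json} carrying VENC, TE, TR, acceleration, encoding-scheme
#' name and per-axis time offsets. Geometry (spacing, origin) goes in the
#' NIfTI headers.
#'
#' @param study an \code{\link{encoded_study}}.
#' @param dir output directory.
#' @param overwrite overwrite an existing study in `dir`? Default FALSE.
#' @return Invisibly, the character vector of files written.
#' @export
write_study <- function(study, dir, overwrite = FALSE) {
  if (!inherits(study, "encoded_study")) stop("`study` must be an encoded_study")
  sidecar <- file.path(dir, "study.json")
  if (file.exists(sidecar) && !overwrite)
    stop("study already exists in '", dir, "' (set overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in 1:4) {
    g <- study$volumes[[k]]
    for (part in c("mag", "phase")) {
      a <- if (part == "mag") Mod(g$data) else Arg(g$data)
      img <- RNifti::asNifti(a)
      RNifti::pixdim(img) <- g$spacing
      aff <- diag(c(g$spacing, 1)); aff[1:3, 4] <- g$origin
      img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
      f <- file.path(dir, sprintf("%s_%s.nii", STUDY_VOLUME_NAMES[k], part))
      RNifti::writeNifti(img, f, datatype = "double")
      files <- c(files, f)
    }
  }
  meta <- list(venc_cm_s = study$params$venc, te_ms = study$params$te,
               tr_ms = study$params$tr, accel = study$params$accel,
               flip_deg = study$params$flip_deg,
               scheme_name = study$scheme$name,
               axis_time_offsets_ms = study$params$axis_time_offsets)
  if (!is.null(study$true_translations))
    meta$true_translations_mm <- study$true_translations
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' Read an encoded study from NIfTI files plus a JSON sidecar
#'
#' The inverse of [write_study()]: can be pointed at a directory written
#' by it, or given explicit paths for user-supplied data.
#'
#' @param dir directory containing the 8 volumes and \code{study.json};
#'   alternatively pass `paths` and `meta` explicitly.
#' @param paths optional named layout: a list with elements \code{mag} and
#'   \code{phase}, each a character vector of 4 NIfTI paths in the order
#'   reference, TP, RL, FH.
#' @param meta optional path of the JSON sidecar (required with `paths`).
#' @return An \code{\link{encoded_study}}.
#' @export
read_study <- function(dir = NULL, paths = NULL, meta = NULL) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("give either `dir` or `paths` + `meta`")
    paths <- list(mag = file.path(dir, sprintf("%s_mag.nii", STUDY_VOLUME_NAMES)),
                  phase = file.path(dir, sprintf("%s_phase.nii", STUDY_VOLUME_NAMES)))
    meta <- file.path(dir, "study.json")
  }
  if (length(paths$mag) != 4L || length(paths$phase) != 4L)
    stop("expected 4 magnitude and 4 phase volumes (reference, TP, RL, FH)")
  if (!file.exists(meta)) stop("sidecar metadata file not found: ", meta)
  md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  if (is.null(md$venc_cm_s)) stop("sidecar is missing venc_cm_s")
  vols <- vector("list", 4)
  shp <- NULL
  for (k in 1:4) {
    m <- RNifti::readNifti(paths$mag[k])
    p <- RNifti::readNifti(paths$phase[k])
    if (!identical(dim(m), dim(p))) stop("magnitude/phase shape mismatch for volume ", k)
    if (is.null(shp)) shp <- dim(m) else if (!identical(dim(m), shp))
      stop("volume ", k, " has a different shape than volume 1")
    pa <- as.array(p)
    if (max(abs(pa)) > pi + 1e-6)
      stop("phase volume ", k, " has values outside [-pi, pi] (radians expected)")
    xf <- RNifti::xform(m)
    spacing <- abs(diag(xf)[1:3]); origin <- xf[1:3, 4]
    vols[[k]] <- voxel_grid(as.array(m) * exp(1i * pa), spacing, origin)
  }
  params <- acq_params(venc = md$venc_cm_s, te = md$te_ms %||% 3.95,
                       tr = md$tr_ms %||% 5.98,
                       flip_deg = md$flip_deg %||% 15,
                       accel = md$accel %||% 1,
                       axis_time_offsets = md$axis_time_offsets_ms %||%
                         c(0, md$te_ms %||% 3.95, md$te_ms %||% 3.95))
  scheme <- encoding_scheme(md$scheme_name %||% "balanced")
  tt <- md$true_translations_mm
  if (!is.null(tt) && !is.matrix(tt)) tt <- matrix(unlist(tt), ncol = 3, byrow = TRUE)
  encoded_study(vols, params, scheme, true_translations = tt)
}
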