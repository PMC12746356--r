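#' Acquisition parameters for a four-point phase-contrast scan
#'
#' Metadata describing the simulated (or ingested) acquisition. Defaults
#' follow a 3 T coronary protocol: VENC 50 cm/s, TE 3.95 ms, TR 5.98 ms,
#' flip 15 degrees, nominal undersampling factor 14, isotropic 1.2 mm
#' resolution.
#'
#' @param venc velocity-encoding sensitivity in cm/s; the speed mapped to a
#'   phase shift of pi.
#' @param te echo time in ms.
#' @param tr repetition time in ms.
#' @param flip_deg excitation flip angle in degrees.
#' @param accel nominal k-space undersampling factor (>= 1).
#' @param axis_time_offsets per-axis delay (ms) between flow encoding and
#'   spatial encoding, used by the flow-displacement correction. Default:
#'   0 for the readout axis (axis 1) and TE for the two phase-encode axes.
#' @param seed optional integer seed recorded with the study.
#' @return An object of class \code{acq_params}.
#' @export
acq_params <- function(venc = 50, te = 3.95, tr = 5.98, flip_deg = 15,
                       accel = 14, axis_time_offsets = c(0, te, te),
                       seed = NULL) {
  stopifnot(venc > 0, accel >= 1, length(axis_time_offsets) == 3L)
  structure(list(venc = venc, te = te, tr = tr, flip_deg = flip_deg,
                 accel = accel, axis_time_offsets = as.numeric(axis_time_offsets),
                 seed = seed),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> VENC %g cm/s, TE %g ms, TR %g ms, flip %g deg, accel %g\n",
              x$venc, x$te, x$tr, x$flip_deg, x$accel))
  invisible(x)
}

#' Four-point velocity-encoding scheme
#'
#' A 4 x 3 first-moment design matrix: row k gives the coefficients with
#' which the three velocity components enter the phase of volume k,
#' \eqn{\phi_k = (\pi/VENC)\, m_k \cdot v + \phi_0}. Two schemes are
#' shipped:
#' \describe{
#'   \item{balanced}{Hadamard-like symmetric encoding, rows
#'     \eqn{\tfrac12(-1,-1,-1), \tfrac12(+1,+1,-1), \tfrac12(+1,-1,+1),
#'     \tfrac12(-1,+1,+1)} (the default).}
#'   \item{referenced}{a flow-compensated reference (zero row) followed by
#'     three unit rows, one per axis.}
#' }
#' Both have rank 3 and both decode exactly through the least-squares
#' inverse in [decode_velocity()].
#'
#' @param name \code{"balanced"} or \code{"referenced"}.
#' @return Object of class \code{encoding_scheme} with fields
#'   \code{matrix} (4 x 3) and \code{name}.
#' @export
encoding_scheme <- function(name = c("balanced", "referenced")) {
  name <- match.arg(name)
  m <- switch(name,
    balanced = 0.5 * rbind(c(-1, -1, -1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1)),
    referenced = rbind(c(0, 0, 0), diag(3)))
  structure(list(matrix = m, name = name), class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme> '%s'\n", x$name))
  print(x$matrix)
  invisible(x)
}

#' Bundle four flow-encoded complex volumes into a study
#'
#' Volume order is fixed: reference, through-plane (TP), right-left (RL),
#' foot-head (FH).
#'
#' @param volumes list of 4 complex \code{\link{voxel_grid}}s sharing
#'   shape and spacing.
#' @param params an \code{\link{acq_params}}.
#' @param scheme an \code{\link{encoding_scheme}}.
#' @param true_translations optional 4 x 3 matrix of simulator ground-truth
#'   inter-scan translations in mm (row 1 conventionally zero).
#' @return Object of class \code{encoded_study}.
#' @export
encoded_study <- function(volumes, params, scheme, true_translations = NULL) {
  if (length(volumes) != 4L)
    stop("an encoded study holds exactly 4 volumes (reference, TP, RL, FH)")
  shp <- volumes[[1]]$shape
  for (v in volumes) {
    if (!identical(v$shape, shp)) stop("all four volumes must share one shape")
    if (!identical(v$spacing, volumes[[1]]$spacing))
      stop("all four volumes must share one spacing")
  }
  if (qr(scheme$matrix)$rank < 3L) stop("encoding scheme matrix must have rank 3")
  structure(list(volumes = volumes, params = params, scheme = scheme,
                 true_translations = true_translations),
            class = "encoded_study")
}

#' @export
print.encoded_study <- function(x, ...) {
  cat(sprintf("<encoded_study> 4 volumes %s, scheme '%s', VENC %g cm/s\n",
              paste(x$volumes[[1]]$shape, collapse = "x"),
              x$scheme$name, x$params$venc))
  invisible(x)
}
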