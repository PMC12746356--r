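#' Bland-Altman agreement analysis of two velocity curves
#'
#' Per-slice differences \code{a - b} with pairwise exclusion of missing
#' slices; bias is the mean difference, the limits of agreement are
#' \eqn{bias \pm 1.96\,SD} (sample SD, n-1), and \code{mean_level} is the
#' mean across slices of the pairwise averages.
#'
#' @param curve_a,curve_b \code{\link{velocity_curve}}s matched by slice
#'   index, or plain numeric vectors of per-slice values.
#' @return Object of class \code{bland_altman}: \code{bias}, \code{sd},
#'   \code{loa} (lower, upper), \code{mean_level}, \code{n}, and
#'   \code{pairs} (data frame of slice index, mean, difference).
#' @examples
#' ba <- bland_altman(c(10, 12, 14), c(9, 10, 11))
#' ba$loa
#' @export
bland_altman <- function(curve_a, curve_b) {
  a <- if (inherits(curve_a, "velocity_curve")) curve_a$vmax else as.numeric(curve_a)
  b <- if (inherits(curve_b, "velocity_curve")) curve_b$vmax else as.numeric(curve_b)
  if (length(a) != length(b)) stop("curves must be matched by slice index")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("need at least 3 paired slices")
  d <- a[ok] - b[ok]
  m <- (a[ok] + b[ok]) / 2
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  structure(list(bias = bias, sd = s,
                 loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 mean_level = mean(m), n = sum(ok),
                 pairs = data.frame(slice = which(ok), mean = m, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.2f +/- %.2f cm/s, LOA (%.2f, %.2f), mean level %.2f, n = %d\n",
              x$bias, x$sd, x$loa[1], x$loa[2], x$mean_level, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...,
                              xlab = "mean of pair [cm/s]",
                              ylab = "difference [cm/s]") {
  graphics::plot(x$pairs$mean, x$pairs$difference, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Paired two-tailed t-test on matched velocity samples
#'
#' Thin wrapper over \code{stats::t.test(paired = TRUE)} with an explicit
#' degenerate-input guard (zero difference variance is an error rather
#' than NaN).
#'
#' @param a,b equal-length numeric vectors (>= 3 values).
#' @return Named numeric vector \code{c(t = , p = )}.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("zero difference variance: paired t-test is degenerate")
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' FFR trace with arc-length positions
#'
#' External CT-FFR results arrive as ordered (world coordinate, value)
#' pairs; the arc position of each measurement is the cumulative
#' Euclidean distance along the coordinate sequence.
#'
#' @param coords ordered n x 3 matrix of world coordinates in mm.
#' @param values dimensionless FFR values in (0, 1], one per coordinate.
#' @return Object of class \code{ffr_trace}: \code{coords},
#'   \code{values}, \code{arc} (mm, \code{arc[1] == 0}).
#' @export
ffr_trace <- function(coords, values) {
  coords <- rbind(coords)
  stopifnot(nrow(coords) == length(values), all(values > 0), all(values <= 1))
  structure(list(coords = coords, values = as.numeric(values),
                 arc = align_ffr_arc(coords)),
            class = "ffr_trace")
}

#' Cumulative arc length of an ordered coordinate sequence
#'
#' @param coords ordered n x 3 matrix (mm).
#' @return Numeric vector: \code{arc[k]} is the summed Euclidean
#'   distance from the first coordinate through coordinate k.
#' @export
align_ffr_arc <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) == 1L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
}

#' Maximum intensity projection of a masked speed volume
#'
#' Per-pixel maximum of speed along the projection axis, restricted to
#' the union of the selected vessel masks. Per-vessel visibility toggles
#' allow hiding overlapping vessels.
#'
#' @param field a \code{\link{velocity_field}}.
#' @param masks list of \code{vessel_mask}s (or logical
#'   \code{\link{voxel_grid}}s) on the field's grid.
#' @param axis projection axis (1, 2 or 3).
#' @param visible logical vector, one flag per mask (default all TRUE).
#' @return 2D numeric matrix of projected maxima (0 where nothing
#'   projects); warns and returns all zeros for an empty mask union.
#' @export
render_mip <- function(field, masks, axis = 3L, visible = NULL) {
  if (inherits(masks, "vessel_mask") || inherits(masks, "voxel_grid"))
    masks <- list(masks)
  visible <- visible %||% rep(TRUE, length(masks))
  stopifnot(length(visible) == length(masks))
  shape <- field$speed$shape
  u <- array(FALSE, shape)
  for (k in seq_along(masks)) {
    if (!visible[k]) next
    mk <- masks[[k]]
    md <- if (inherits(mk, "vessel_mask")) mk$mask$data else mk$data
    u <- u | md
  }
  if (!any(u)) {
    warning("empty mask union; MIP is blank")
    return(matrix(0, shape[setdiff(1:3, axis)][1], shape[setdiff(1:3, axis)][2]))
  }
  s <- field$speed$data
  s[!u] <- 0
  apply(s, setdiff(1:3, axis), max)
}

#' Scan-rescan reproducibility report
#'
#' Per pair of repeated measurements: the deviation of the proximal
#' average and peak velocity, plus a per-slice Bland-Altman row; closed
#' by a cohort summary row (mean +/- SD of the deviations).
#'
#' @param pairs list of two-element lists (or a named list of them), each
#'   holding two \code{\link{velocity_curve}}s of the same vessel.
#' @return data.frame with one row per pair plus one summary row:
#'   columns \code{pair}, \code{avg_dev}, \code{peak_dev}, \code{bias},
#'   \code{sd}, \code{loa_lower}, \code{loa_upper}, \code{mean_level}.
#' @export
scan_rescan_report <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  rows <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    sa <- summary(p[[1]]); sb <- summary(p[[2]])
    ba <- bland_altman(p[[1]], p[[2]])
    nm <- names(pairs)[k]
    if (is.null(names(pairs)) || is.na(nm) || nm == "") nm <- as.character(k)
    data.frame(pair = nm,
               avg_dev = sa[["average"]] - sb[["average"]],
               peak_dev = sa[["peak"]] - sb[["peak"]],
               bias = ba$bias, sd = ba$sd,
               loa_lower = ba$loa[[1]], loa_upper = ba$loa[[2]],
               mean_level = ba$mean_level)
  })
  tab <- do.call(rbind, rows)
  summary_row <- data.frame(pair = "cohort mean +/- SD",
                            avg_dev = mean(tab$avg_dev),
                            peak_dev = mean(tab$peak_dev),
                            bias = mean(tab$bias), sd = stats::sd(tab$bias),
                            loa_lower = NA, loa_upper = NA,
                            mean_level = mean(tab$mean_level))
  rbind(tab, summary_row)
}
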