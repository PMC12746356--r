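# Published reference statistics used to validate the agreement
# arithmetic and as realistic inputs for worked examples. Values are from
# a 3 T in-vivo coronary flow-velocity study (12 intra-session
# scan-rescan pairs plus a flow phantom); they are inputs to the
# statistics layer, not quantities this package can re-measure.

#' Reference scan-rescan agreement statistics
#'
#' Per-subject bias and SD of per-slice peak-velocity differences between
#' repeated scans, with the printed limits of agreement, for the LCA
#' (combined left main + LAD) and RCA of 12 volunteers, a flow phantom,
#' and one inter-session volunteer repeat. Used to validate that
#' [bland_altman()]'s limits-of-agreement arithmetic (bias +/- 1.96 SD)
#' reproduces the printed cells; rows whose printed inputs are rounded
#' inconsistently with their printed LOA by one unit in the last decimal
#' are flagged \code{self_consistent = FALSE}.
#'
#' @return data.frame with columns \code{subject}, \code{vessel},
#'   \code{bias}, \code{sd}, \code{mean_level}, \code{loa_lower},
#'   \code{loa_upper}, \code{self_consistent}.
#' @export
scan_rescan_reference <- function() {
  df <- rbind(
    data.frame(subject = c(paste0("volunteer", 1:12), "phantom", "volunteer1_intersession"),
               vessel = "LCA",
               bias = c(0.65, 8.10, 0.16, 0.59, -0.32, -3.33, 2.15, 1.79, -1.38,
                        -4.08, -4.87, -3.07, -0.14, 0.18),
               sd = c(2.25, 2.30, 2.36, 3.95, 1.60, 5.31, 4.68, 3.24, 3.28,
                      4.05, 4.34, 4.89, 1.91, 3.06),
               mean_level = c(8.09, 15.12, 10.20, 7.50, 9.42, 14.87, 14.75,
                              13.70, 10.34, 10.59, 12.75, 12.92, 6.04, 7.85),
               loa_lower = c(-3.77, 3.59, -4.46, -7.15, -3.46, -13.74, -7.01,
                             -4.57, -7.81, -12.03, -13.38, -12.65, -3.89, -5.81),
               loa_upper = c(5.07, 12.61, 4.78, 8.33, 2.81, 7.08, 11.32, 8.15,
                             5.05, 3.86, 3.64, 6.52, 3.62, 6.16)),
    data.frame(subject = c(paste0("volunteer", 1:12), "phantom", "volunteer1_intersession"),
               vessel = "RCA",
               bias = c(-0.93, 5.12, 1.93, 0.37, 1.16, -2.80, 0.12, 0.77, -0.49,
                        2.05, -1.01, 1.80, 0.25, -3.03),
               sd = c(2.35, 5.43, 2.64, 1.55, 1.87, 2.05, 2.38, 2.34, 3.08,
                      1.91, 3.11, 5.89, 1.01, 2.93),
               mean_level = c(7.62, 12.48, 8.27, 5.35, 6.14, 7.48, 10.06, 8.06,
                              7.04, 8.39, 7.53, 12.15, 9.72, 6.57),
               loa_lower = c(-5.54, -5.52, -3.23, -2.67, -2.50, -6.81, -4.54,
                             -3.81, -6.52, -1.70, -7.11, -9.73, -1.74, -8.75),
               loa_upper = c(3.68, 15.76, 7.11, 3.41, 4.83, 1.21, 4.78, 5.35,
                             5.54, 5.81, 5.10, 13.34, 2.24, 2.72)))
  df$self_consistent <-
    round(df$bias - 1.96 * df$sd, 2) == df$loa_lower &
    round(df$bias + 1.96 * df$sd, 2) == df$loa_upper
  df
}

#' Reference cohort velocity statistics
#'
#' Cohort mean +/- SD of diastolic proximal coronary flow velocities
#' (cm/s) measured in 16 healthy adults at 3 T: peak and average of the
#' per-slice maxima over the proximal 25 mm, for the LCA and RCA. The
#' LCA/RCA ratios of these means (about 1.4 for average, 1.3 for peak
#' velocity) are the scale-free quantities this package's cohort analysis
#' reproduces.
#'
#' @return data.frame with columns \code{vessel}, \code{metric},
#'   \code{mean}, \code{sd}.
#' @export
cohort_velocity_reference <- function() {
  data.frame(vessel = c("LCA", "RCA", "LCA", "RCA"),
             metric = c("peak", "peak", "average", "average"),
             mean = c(17.6, 13.3, 11.9, 8.4),
             sd = c(5.3, 4.4, 3.3, 2.6))
}
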