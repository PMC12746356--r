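#' Pipeline configuration
#'
#' Fully defaulted configuration for [run_pipeline()]. Every run writes
#' the resolved configuration next to its outputs as
#' \code{config.json}.
#'
#' @param vessels list of \code{\link{vessel_spec}}s, or a path to a
#'   vessel-spec JSON file.
#' @param shape,spacing,origin phantom grid geometry.
#' @param params an \code{\link{acq_params}}.
#' @param scheme an \code{\link{encoding_scheme}}.
#' @param translations 4 x 3 matrix of inter-scan shifts in mm, or
#'   \code{"random"} to draw each flow-encoded volume's shift uniformly
#'   from \code{[-motion_max_mm, motion_max_mm]} per axis.
#' @param motion_max_mm bound for random motion (default 3).
#' @param noise_snr peak-signal-to-noise-SD ratio (default 30).
#' @param recon_mode \code{"image"} (no undersampling),
#'   \code{"zero_fill"} or \code{"cs"}.
#' @param recon a \code{\link{recon_config}} (used when
#'   \code{recon_mode = "cs"}).
#' @param calib_size calibration-region width for the sampling mask.
#' @param moco,background,displacement logical correction toggles.
#' @param quantify_vessel name of the vessel to quantify (default: first).
#' @param radius_mm,threshold_frac,n_slices,max_n quantification settings
#'   (see [segment_vessel()], [extract_curve()], [prune_ostium()]).
#' @param seed master RNG seed for motion and noise.
#' @param myocardium optional static-tissue blob forwarded to
#'   [build_phantom()].
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(vessels = straight_tube_spec(),
                            shape = c(48, 48, 48),
                            spacing = c(1.2, 1.2, 1.2), origin = c(0, 0, 0),
                            params = acq_params(), scheme = encoding_scheme("balanced"),
                            translations = matrix(0, 4, 3), motion_max_mm = 3,
                            noise_snr = 30,
                            recon_mode = c("image", "zero_fill", "cs"),
                            recon = recon_config(), calib_size = 8L,
                            moco = TRUE, background = FALSE, displacement = TRUE,
                            quantify_vessel = NULL, radius_mm = 2.5,
                            threshold_frac = 0.5, n_slices = 100L, max_n = 8L,
                            seed = 1L, myocardium = NULL) {
  if (is.character(vessels)) {
    if (!file.exists(vessels)) stop("vessel spec file not found: ", vessels)
    vessels <- read_vessel_spec(vessels)
  }
  structure(list(vessels = vessels, shape = shape, spacing = spacing,
                 origin = origin, params = params, scheme = scheme,
                 translations = translations, motion_max_mm = motion_max_mm,
                 noise_snr = noise_snr, recon_mode = match.arg(recon_mode),
                 recon = recon, calib_size = calib_size, moco = moco,
                 background = background, displacement = displacement,
                 quantify_vessel = quantify_vessel, radius_mm = radius_mm,
                 threshold_frac = threshold_frac, n_slices = n_slices,
                 max_n = max_n, seed = seed, myocardium = myocardium),
            class = "pipeline_config")
}

resolve_translations <- function(cfg) {
  if (is.character(cfg$translations) && cfg$translations[1] == "random") {
    tr <- with_seed(cfg$seed,
      rbind(0, matrix(stats::runif(9, -cfg$motion_max_mm, cfg$motion_max_mm), 3, 3)))
    return(tr)
  }
  rbind(cfg$translations)
}

#' Run the full simulation + post-processing pipeline
#'
#' Fixed stage order: simulate -> (undersample + reconstruct) ->
#' motion-correct -> decode -> background-correct -> displacement-correct
#' -> segment -> extract curve -> prune -> summarize. Deterministic given
#' the config seed. When `outdir` is given, every stage's key output is
#' persisted there (NIfTI volumes, CSV curve and shift tables, JSON
#' config and summary).
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @param outdir optional output directory.
#' @return List of class \code{pipeline_result}: \code{phantom},
#'   \code{study} (as simulated), \code{corrected_study}, \code{shifts}
#'   (3 x 3 matrix, mm), \code{field} (final velocity field),
#'   \code{background} (model or NULL), \code{mask}, \code{curve}
#'   (pruned), \code{curve_raw}, \code{truth_curve}, \code{summary}
#'   (peak/average), \code{config}.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  trans <- resolve_translations(cfg)
  phantom <- build_phantom(cfg$vessels, cfg$shape, cfg$spacing, cfg$origin,
                           myocardium = cfg$myocardium, venc = cfg$params$venc)

  mask <- NULL
  if (cfg$recon_mode != "image")
    mask <- make_mask(cfg$shape[2:3], cfg$params$accel, cfg$calib_size,
                      seed = cfg$seed + 1L)
  study <- encode_study(phantom, cfg$params, cfg$scheme, trans,
                        noise_snr = cfg$noise_snr, mask = mask,
                        seed = cfg$seed, keep_kspace = (cfg$recon_mode == "cs"))

  if (cfg$recon_mode == "cs") {
    ks <- attr(study, "kspace")
    for (k in 1:4) {
      rec <- cs_reconstruct(ks[[k]], mask, cfg$recon, cfg$spacing, cfg$origin)
      study$volumes[[k]] <- voxel_grid(rec$data, cfg$spacing, cfg$origin)
    }
  }

  shifts <- NULL
  corrected <- study
  if (cfg$moco) {
    sh <- estimate_study_shifts(study, search_mm = max(cfg$motion_max_mm * 1.5, 6))
    corrected <- apply_correction(study, sh)
    shifts <- do.call(rbind, lapply(sh, `[[`, "t"))
  }

  field <- decode_velocity(corrected,
                           magnitude = if (cfg$moco) corrected$avg_magnitude else NULL)

  bg_model <- NULL
  if (cfg$background) {
    static <- grid_like(field$magnitude,
                        field$magnitude$data > 0.15 * max(field$magnitude$data) &
                        field$magnitude$data < 0.7 * max(field$magnitude$data))
    if (sum(static$data) >= 10) {
      bg <- fit_background(field, static, lumen_mask = phantom$lumen_mask)
      bg_model <- bg$model
      field <- bg$corrected
    }
  }
  if (cfg$displacement) field <- displacement_correct(field, cfg$params)

  vname <- cfg$quantify_vessel %||% cfg$vessels[[1]]$name
  vi <- match(vname, vapply(cfg$vessels, `[[`, "", "name"))
  path <- build_centerline(cfg$vessels[[vi]]$control_points, cfg$n_slices)
  mask_v <- segment_vessel(field$magnitude, path, cfg$radius_mm, cfg$threshold_frac)
  curve_raw <- extract_curve(field, path, mask_v)
  curve <- prune_ostium(curve_raw, cfg$max_n)
  truth_curve <- sample_truth_curve(phantom, vname, cfg$n_slices)

  result <- structure(list(phantom = phantom, study = study,
                           corrected_study = corrected, shifts = shifts,
                           field = field, background = bg_model,
                           mask = mask_v, curve = curve, curve_raw = curve_raw,
                           truth_curve = truth_curve,
                           summary = summary(curve), config = cfg),
                      class = "pipeline_result")
  if (!is.null(outdir)) persist_pipeline(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> vessel '%s': proximal peak %.2f, average %.2f cm/s\n",
              x$config$quantify_vessel %||% x$config$vessels[[1]]$name,
              x$summary[["peak"]], x$summary[["average"]]))
  invisible(x)
}

persist_pipeline <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  jsonlite::write_json(
    list(shape = cfg$shape, spacing = cfg$spacing, origin = cfg$origin,
         venc_cm_s = cfg$params$venc, te_ms = cfg$params$te,
         accel = cfg$params$accel, scheme = cfg$scheme$name,
         noise_snr = cfg$noise_snr, recon_mode = cfg$recon_mode,
         corrections = list(moco = cfg$moco, background = cfg$background,
                            displacement = cfg$displacement),
         quantify = list(radius_mm = cfg$radius_mm,
                         threshold_frac = cfg$threshold_frac,
                         n_slices = cfg$n_slices, max_n = cfg$max_n),
         seed = cfg$seed),
    file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA)
  write_curve(result$curve, file.path(outdir, "curve.csv"))
  write_curve(result$curve_raw, file.path(outdir, "curve_raw.csv"))
  write_curve(result$truth_curve, file.path(outdir, "curve_truth.csv"))
  if (!is.null(result$shifts)) {
    sh <- as.data.frame(result$shifts)
    names(sh) <- c("tx_mm", "ty_mm", "tz_mm")
    sh <- cbind(volume = 2:4, sh)
    utils::write.csv(sh, file.path(outdir, "shifts.csv"), row.names = FALSE)
  }
  if (!is.null(result$background))
    jsonlite::write_json(
      list(static_residual_rms = result$background$static_residual_rms,
           lumen_fraction_pct = result$background$lumen_fraction_pct),
      file.path(outdir, "background.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(result$summary), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  mip <- render_mip(result$field, result$mask)
  utils::write.csv(mip, file.path(outdir, "mip_axial.csv"), row.names = FALSE)
  invisible(outdir)
}

#' Canonical test fixtures
#'
#' Builds the four canonical simulated studies used throughout testing
#' and validation, each bundled with its analytic ground-truth curve:
#' \describe{
#'   \item{a}{straight axis-aligned tube (v_c = 15 cm/s), full sampling,
#'     no motion, no noise — the clean baseline isolating discretization
#'     effects.}
#'   \item{b}{curved two-vessel phantom with inter-scan motion.}
#'   \item{c}{straight tube with a 50\% area stenosis (v_c = 10 cm/s).}
#'   \item{d}{scan-rescan pair: same phantom, independent noise draws.}
#' }
#'
#' @param seed master seed; all randomness derives from it.
#' @param outdir optional directory; if given, each fixture's study is
#'   written via [write_study()] and truth curves as CSV.
#' @return Named list of fixtures; each has \code{phantom}, \code{study}
#'   (fixture d: \code{study} and \code{study2}), \code{truth_curve},
#'   and \code{vessels}.
#' @export
make_fixtures <- function(seed = 1L, outdir = NULL) {
  fx <- list()
  vs_a <- straight_tube_spec(peak_speed = 15)
  ph_a <- build_phantom(vs_a, c(48, 48, 48))
  fx$a <- list(phantom = ph_a, vessels = vs_a,
               study = encode_study(ph_a, translations = matrix(0, 4, 3),
                                    noise_snr = Inf, seed = seed),
               truth_curve = sample_truth_curve(ph_a, "tube"))

  vs_b <- curved_two_vessel_spec()
  ph_b <- build_phantom(vs_b, c(48, 48, 48))
  trans_b <- with_seed(seed + 1L,
    rbind(0, matrix(stats::runif(9, -3, 3), 3, 3)))
  fx$b <- list(phantom = ph_b, vessels = vs_b, translations = trans_b,
               study = encode_study(ph_b, translations = trans_b,
                                    noise_snr = 30, seed = seed + 2L),
               truth_curve = sample_truth_curve(ph_b, "LCA"))

  vs_c <- stenosed_tube_spec(peak_speed = 10, severity = 0.5)
  ph_c <- build_phantom(vs_c, c(48, 48, 48))
  fx$c <- list(phantom = ph_c, vessels = vs_c,
               study = encode_study(ph_c, translations = matrix(0, 4, 3),
                                    noise_snr = 30, seed = seed + 3L),
               truth_curve = sample_truth_curve(ph_c, "tube"))

  fx$d <- list(phantom = ph_a, vessels = vs_a,
               study = encode_study(ph_a, translations = matrix(0, 4, 3),
                                    noise_snr = 30, seed = seed + 4L),
               study2 = encode_study(ph_a, translations = matrix(0, 4, 3),
                                     noise_snr = 30, seed = seed + 5L),
               truth_curve = sample_truth_curve(ph_a, "tube"))

  if (!is.null(outdir)) {
    for (nm in names(fx)) {
      d <- file.path(outdir, paste0("fixture_", nm))
      write_study(fx[[nm]]$study, d, overwrite = TRUE)
      write_curve(fx[[nm]]$truth_curve, file.path(d, "truth_curve.csv"))
      if (!is.null(fx[[nm]]$study2))
        write_study(fx[[nm]]$study2, file.path(d, "rescan"), overwrite = TRUE)
    }
  }
  fx
}
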