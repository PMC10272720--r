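#' @include AllClasses.R
NULL

#' Analysis configuration for the velocimetry pipeline
#'
#' Collects every threshold and window of the stage chain with its default.
#' Each [CaseReport-class] embeds the resolved configuration so that per-case
#' choices (ROI placement, first-peak exclusion) stay reproducible.
#'
#' @param threshold_mode,threshold vessel segmentation, see
#'   [extractVesselMask()].
#' @param smooth_window,smooth_order,inflow centerline extraction, see
#'   [extractCenterline()].
#' @param roi_strategy "auto" or "manual"; with "manual" give
#'   `roi_indices_before` / `roi_indices_after` (length-2 centerline
#'   indices).
#' @param roi_edge_px,roi_step_px,roi_prom_frac,roi_fade_frac ROI
#'   placement, see [placeRois()].
#' @param peak_order,peak_min_prominence peak detection, see
#'   [detectPeaks()] (NULL = per-TIC defaults).
#' @param exclude_first_before,exclude_first_after drop the first detected
#'   peak of the before / after acquisition.
#' @param refine_subframe sub-frame parabolic peak refinement (off: frame
#'   shifts are integer frame counts).
#' @param site_fractions named arc fractions of the diameter sites.
#' @param seed seed recorded in the report provenance.
#' @return A named list of settings.
#' @export
angioConfig <- function(threshold_mode = "temporal_range", threshold = 0.5,
                        smooth_window = 21L, smooth_order = 3L,
                        inflow = "left", roi_strategy = "auto",
                        roi_indices_before = NULL,
                        roi_indices_after = NULL, roi_edge_px = 20L,
                        roi_step_px = 10, roi_prom_frac = 0.5,
                        roi_fade_frac = 0.2, peak_order = NULL,
                        peak_min_prominence = NULL,
                        exclude_first_before = FALSE,
                        exclude_first_after = FALSE,
                        refine_subframe = FALSE,
                        site_fractions = c(proximal = 0.15, middle = 0.5),
                        seed = 1L) {
  list(threshold_mode = threshold_mode, threshold = threshold,
       smooth_window = smooth_window, smooth_order = smooth_order,
       inflow = inflow, roi_strategy = roi_strategy,
       roi_indices_before = roi_indices_before,
       roi_indices_after = roi_indices_after, roi_edge_px = roi_edge_px,
       roi_step_px = roi_step_px, roi_prom_frac = roi_prom_frac,
       roi_fade_frac = roi_fade_frac, peak_order = peak_order,
       peak_min_prominence = peak_min_prominence,
       exclude_first_before = exclude_first_before,
       exclude_first_after = exclude_first_after,
       refine_subframe = refine_subframe, site_fractions = site_fractions,
       seed = seed)
}

# short FNV-1a hash of the serialized config, for provenance
.configHash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch) * 16777619
    h <- h %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.stageLog <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# full single-sequence stage chain: mask -> centerline -> ROIs -> TICs
.analyzeSequence <- function(seq, config, roiIndices, excludeFirst,
                             label, verbose) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' (%s): %s", name, label,
                   conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("segment",
                extractVesselMask(seq, config$threshold_mode,
                                  config$threshold))
  .stageLog(verbose, "segment", "%s: %d vessel px (mode=%s, thr=%.2f)",
            label, sum(maskMatrix(mask)), config$threshold_mode,
            config$threshold)
  cl <- stage("centerline",
              extractCenterline(mask, config$smooth_window,
                                config$smooth_order, config$inflow))
  .stageLog(verbose, "centerline", "%s: %d points, arc %.1f px", label,
            nrow(centerlinePoints(cl)), max(cumulativeArcPx(cl)))
  rois <- stage("rois", {
    if (config$roi_strategy == "manual") {
      placeRois(cl, seq, "manual", indices = roiIndices,
                edgePx = config$roi_edge_px)
    } else {
      placeRois(cl, seq, "auto", edgePx = config$roi_edge_px,
                stepPx = config$roi_step_px,
                promFrac = config$roi_prom_frac,
                fadeFrac = config$roi_fade_frac)
    }
  })
  dxMm <- arcDistance(cl, rois$proximal@centerIndex,
                      rois$distal@centerIndex, resolution(seq))
  .stageLog(verbose, "rois", "%s: centers %d/%d, dx = %.2f mm", label,
            rois$proximal@centerIndex, rois$distal@centerIndex, dxMm)
  ticP <- stage("tic", computeTic(seq, rois$proximal))
  ticD <- stage("tic", computeTic(seq, rois$distal))
  vel <- stage("velocity",
               estimateVelocity(ticP, ticD, dxMm,
                                order = config$peak_order,
                                minProminence = config$peak_min_prominence,
                                excludeFirst = excludeFirst,
                                refineSubframe = config$refine_subframe))
  .stageLog(verbose, "velocity",
            "%s: %.1f +/- %.1f mm/s, dt = {%s} frames", label,
            meanVelocity(vel), sdVelocity(vel),
            paste(format(vel@perPeakDtFrames), collapse = ", "))
  list(mask = mask, centerline = cl, rois = rois, ticProx = ticP,
       ticDist = ticD, velocity = vel)
}

.asSequence <- function(x, what) {
  if (is(x, "AngioSequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(readSequence(x))
  stop(what, " must be an AngioSequence or a readable path")
}

.writeArtifacts <- function(dir, prefix, res) {
  png::writePNG(maskMatrix(res$mask) * 1,
                file.path(dir, paste0(prefix, "_mask.png")))
  cl <- res$centerline
  utils::write.csv(
    data.frame(row = centerlinePoints(cl)[, 1L],
               col = centerlinePoints(cl)[, 2L],
               cum_arc_px = cumulativeArcPx(cl)),
    file.path(dir, paste0(prefix, "_centerline.csv")), row.names = FALSE)
  for (side in c("ticProx", "ticDist")) {
    tic <- res[[side]]
    utils::write.csv(
      data.frame(frame = seq_along(ticValues(tic)),
                 seconds = (seq_along(ticValues(tic)) - 1L) / fps(tic),
                 mean_intensity = ticValues(tic)),
      file.path(dir, paste0(prefix, "_",
                            if (side == "ticProx") "tic_proximal"
                            else "tic_distal", ".csv")),
      row.names = FALSE)
  }
}

#' Run the full before/after velocimetry analysis for one case
#'
#' Executes the complete stage chain — segmentation, centerline extraction,
#' ROI placement, TIC construction, peak detection, velocity estimation and
#' FWHM diameter measurement — on a pre-stent and a post-stent sequence
#' with identical settings, and reports the velocity retention ratio and
#' the per-site diameter expansion.
#'
#' @param before,after [AngioSequence-class] objects or readable paths.
#' @param config an [angioConfig()] list.
#' @param caseId,vessel identifiers recorded in the report.
#' @param outputDir optional directory for intermediate artifacts (mask
#'   PNG, centerline CSV, TIC CSVs, report JSON).
#' @param verbose log each stage with its parameters and derived
#'   quantities.
#' @return A [CaseReport-class].
#' @export
runCase <- function(before, after, config = angioConfig(),
                    caseId = "case", vessel = "", outputDir = NULL,
                    verbose = TRUE) {
  seqB <- .asSequence(before, "before")
  seqA <- .asSequence(after, "after")
  if (!is.null(outputDir))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  resB <- .analyzeSequence(seqB, config, config$roi_indices_before,
                           config$exclude_first_before, "before", verbose)
  resA <- .analyzeSequence(seqA, config, config$roi_indices_after,
                           config$exclude_first_after, "after", verbose)
  if (!is.null(outputDir)) {
    .writeArtifacts(outputDir, paste0(caseId, "_before"), resB)
    .writeArtifacts(outputDir, paste0(caseId, "_after"), resA)
  }

  retention <- retentionRatio(resB$velocity, resA$velocity)
  .stageLog(verbose, "retention", "%s: %.1f %%", caseId, retention)

  sites <- config$site_fractions
  diam <- do.call(rbind, lapply(names(sites), function(sn) {
    dB <- measureDiameter(seqB, resB$centerline, sites[[sn]], site = sn)
    dA <- measureDiameter(seqA, resA$centerline, sites[[sn]], site = sn)
    data.frame(site = sn, arc_fraction = sites[[sn]],
               before_mm = diameterMm(dB), after_mm = diameterMm(dA),
               expansion_pct = expansionPercent(diameterMm(dB),
                                                diameterMm(dA)))
  }))
  for (i in seq_len(nrow(diam)))
    .stageLog(verbose, "diameter", "%s %s: %.3f -> %.3f mm (%.1f %%)",
              caseId, diam$site[i], diam$before_mm[i], diam$after_mm[i],
              diam$expansion_pct[i])

  report <- new("CaseReport", caseId = caseId, vessel = vessel,
                before = resB$velocity, after = resA$velocity,
                retentionPct = retention, diameters = diam,
                provenance = list(
                  config = config, config_hash = .configHash(config),
                  before_path = if (is.character(before)) before else NA,
                  after_path = if (is.character(after)) after else NA,
                  seed = config$seed))
  if (!is.null(outputDir)) writeCaseReport(report, outputDir)
  report
}

#' Write a CaseReport as JSON
#'
#' @param report a [CaseReport-class].
#' @param dir output directory.
#' @return the JSON path, invisibly.
#' @export
writeCaseReport <- function(report, dir) {
  path <- file.path(dir, paste0(report@caseId, "_report.json"))
  out <- list(
    case_id = report@caseId, vessel = report@vessel,
    before = list(mean_velocity_mm_s = report@before@meanVelocity,
                  sd_velocity_mm_s = report@before@sdVelocity,
                  per_peak_velocities = report@before@perPeakVelocities,
                  per_peak_dt_frames = report@before@perPeakDtFrames,
                  dx_mm = report@before@dxMm),
    after = list(mean_velocity_mm_s = report@after@meanVelocity,
                 sd_velocity_mm_s = report@after@sdVelocity,
                 per_peak_velocities = report@after@perPeakVelocities,
                 per_peak_dt_frames = report@after@perPeakDtFrames,
                 dx_mm = report@after@dxMm),
    retention_pct = report@retentionPct,
    diameters = report@diameters,
    provenance = list(
      config_hash = report@provenance$config_hash,
      before_path = report@provenance$before_path,
      after_path = report@provenance$after_path,
      seed = report@provenance$seed,
      config = report@provenance$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Integer-rounded across-case mean velocity of a stent arm
#'
#' @param velocities mean before-stent velocities (mm/s) of the cases in
#'   one stent arm.
#' @return the arm mean, rounded to an integer (mm/s).
#' @examples
#' armMeanVelocity(c(441.4, 285.3, 255.6))  # 327
#' @export
armMeanVelocity <- function(velocities) {
  round(mean(velocities))
}

#' Run a batch of cases from a manifest
#'
#' The manifest is a data.frame with columns `case_id`, `vessel` (stent-arm
#' label, e.g. "straight" / "helical"), `before` and `after` (paths or
#' [AngioSequence-class]s in list columns).  Per-case failures are recorded
#' and the batch continues.  The summary table mirrors the per-case
#' velocity/retention layout, and the across-case mean of before-velocities
#' is reported per stent arm.
#'
#' @param manifest manifest data.frame.
#' @param config an [angioConfig()] list applied to every case.
#' @param outputDir optional artifact directory.
#' @param verbose per-stage logging.
#' @return list(reports, summary, arm_means, failures).
#' @export
runBatch <- function(manifest, config = angioConfig(), outputDir = NULL,
                     verbose = FALSE) {
  reports <- list(); failures <- list()
  summary <- data.frame()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cid <- as.character(row$case_id)
    res <- tryCatch({
      runCase(if (is.list(manifest$before)) row$before[[1L]]
              else as.character(row$before),
              if (is.list(manifest$after)) row$after[[1L]]
              else as.character(row$after),
              config = config, caseId = cid,
              vessel = as.character(row$vessel), outputDir = outputDir,
              verbose = verbose)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[cid]] <- conditionMessage(res)
      next
    }
    reports[[cid]] <- res
    summary <- rbind(summary, data.frame(
      case_id = cid, vessel = as.character(row$vessel),
      before_mean_mm_s = res@before@meanVelocity,
      before_sd_mm_s = res@before@sdVelocity,
      after_mean_mm_s = res@after@meanVelocity,
      after_sd_mm_s = res@after@sdVelocity,
      retention_pct = res@retentionPct))
  }
  armMeans <- if (nrow(summary)) {
    vapply(split(summary$before_mean_mm_s, summary$vessel),
           armMeanVelocity, numeric(1L))
  } else numeric(0L)
  if (!is.null(outputDir) && nrow(summary)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(outputDir, "batch_summary.csv"),
                     row.names = FALSE)
  }
  list(reports = reports, summary = summary, arm_means = armMeans,
       failures = failures)
}
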