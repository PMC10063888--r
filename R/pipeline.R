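# Cohort-level experiments: generate a synthetic cohort, measure every
# image under the configured protocols, and emit the paired-comparison /
# Bland-Altman tables for the three analyses (right vs left eye,
# constant vs individual conversion factor, disc- vs macula-centered).

#' Experiment configuration
#'
#' Validated configuration for the cohort experiments.  `icfModes` and
#' `views` select the protocols to compare; `scaleFactor` is the render
#' resolution relative to the native ground-truth scale; `outDir`, when
#' given, receives CSV tables and a JSON-lines log of per-image quality
#' flags and exclusions.
#'
#' @param nEyes number of eyes (>= 3).
#' @param seed integer master seed; per-eye seeds are derived from it.
#' @param icfModes subset of `c("constant", "individual")`.
#' @param views subset of `c("ODC", "MC")`.
#' @param scaleFactor unitless render scale.
#' @param fovDeg field of view of the rendered frames, degrees.
#' @param outDir optional output directory.
#' @param referenceOdUm reference disc size, um.
#' @param alpha significance level before Bonferroni correction.
#' @param maxClipFrac maximum tolerated clipped fraction of the zone C
#'   annulus before an image is excluded from a comparison.
#' @param widthNoiseUm caliber noise of the mirrored fellow eye, um.
#' @param params generator parameters, see [eyeParams()].
#' @return a validated configuration list.
#' @export
experimentConfig <- function(nEyes = 20L, seed = 1L,
                             icfModes = c("constant", "individual"),
                             views = "ODC", scaleFactor = 1,
                             fovDeg = 60,
                             outDir = NULL, referenceOdUm = 1800,
                             alpha = 0.05, maxClipFrac = 0.05,
                             widthNoiseUm = 2, params = eyeParams()) {
  cfg <- list(nEyes = as.integer(nEyes), seed = as.integer(seed),
              icfModes = icfModes, views = views,
              scaleFactor = scaleFactor, fovDeg = fovDeg,
              outDir = outDir,
              referenceOdUm = referenceOdUm, alpha = alpha,
              maxClipFrac = maxClipFrac, widthNoiseUm = widthNoiseUm,
              params = utils::modifyList(eyeParams(), params))
  if (cfg$nEyes < 3L) stop("nEyes must be >= 3")
  if (!length(cfg$icfModes) ||
      !all(cfg$icfModes %in% c("constant", "individual")))
    stop("icfModes must be a non-empty subset of constant/individual")
  if (!length(cfg$views) || !all(cfg$views %in% c("ODC", "MC")))
    stop("views must be a non-empty subset of ODC/MC")
  if (any(cfg$scaleFactor <= 0)) stop("scaleFactor must be positive")
  if (cfg$fovDeg <= 0) stop("fovDeg must be positive")
  cfg
}

#' Read an experiment configuration from a YAML file
#'
#' Fields are validated against the [experimentConfig()] schema; unknown
#' top-level keys are an error.
#'
#' @param path YAML file.
#' @return a validated configuration list.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(experimentConfig))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$params)) y$params <- utils::modifyList(eyeParams(), y$params)
  do.call(experimentConfig, y)
}

# Derive per-eye integer seeds from the master seed.
.eyeSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}

#' Generate a synthetic cohort
#'
#' @param n number of eyes.
#' @param seed master seed.
#' @param params generator parameters, see [eyeParams()].
#' @return list of [SyntheticEye-class].
#' @export
generateCohort <- function(n, seed, params = eyeParams()) {
  seeds <- .eyeSeeds(seed, n)
  lapply(seeds, function(s) generateEye(params, seed = s))
}

# A VesselMap stripped of its raster once the point table is computed:
# keeps metadata-driven steps working without holding the frame.
.mapLite <- function(map) {
  new("VesselMap", labels = matrix(0L, 1, 1), meta = map@meta)
}

.measureRender <- function(eye, view) {
  map <- renderView(eye, view)
  pt <- skeletonPointTable(map)
  lite <- .mapLite(map)
  rm(map)
  list(map = lite, pointTable = pt,
       odPx = (lite@meta$odHDiameterPx + lite@meta$odVDiameterPx) / 2)
}

.rvgcRow <- function(res, imageId) {
  cbind(data.frame(image_id = imageId), as.data.frame(res))
}

.agreementTable <- function(xs, ys, labels, alpha) {
  # xs, ys: matrices [image, characteristic]
  rows <- lapply(RVGC_NAMES, function(v) {
    s <- pairedSeries(xs[, v], ys[, v], labels)
    ba <- as.data.frame(blandAltman(s))
    pc <- pairedCompare(s)
    cbind(data.frame(rvgc = v), ba,
          data.frame(paired_p = pc$p, paired_test = pc$test))
  })
  tab <- do.call(rbind, rows)
  tab$bonferroni_threshold <- bonferroniThreshold(alpha, length(RVGC_NAMES))
  tab$significant <- !is.na(tab$paired_p) &
    tab$paired_p < tab$bonferroni_threshold
  tab
}

.valuesMatrix <- function(results) {
  m <- do.call(rbind, lapply(results, rvgcValues))
  colnames(m) <- RVGC_NAMES
  m
}

.writeLog <- function(outDir, entries, file) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(outDir, file), "w")
  on.exit(close(con))
  for (e in entries)
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), con)
  invisible(NULL)
}

.writeCsv <- function(outDir, df, file) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(outDir, file), row.names = FALSE)
  invisible(NULL)
}

#' Constant vs individual conversion factor on disc-centered images
#'
#' Renders the cohort's disc-centered images, computes the constant
#' conversion factor from all cohort discs and an individual factor per
#' eye, measures every image under both, and summarizes per
#' characteristic with a paired test and a Bland-Altman analysis of
#' individual minus constant, at the Bonferroni-corrected threshold.
#'
#' @param cfg configuration from [experimentConfig()].
#' @return list with `rvgc` (per-image long table), `agreement`
#'   (Bland-Altman table), `constantIcf`, `icfTable` (per-image disc and
#'   factor), `threshold`, and `log` (per-image flag entries).  When
#'   `cfg$outDir` is set, `rvgc_icf.csv`, `agreement_icf.csv`,
#'   `icf_table.csv` and `log_icf.jsonl` are written there.
#' @export
runICFComparison <- function(cfg = experimentConfig()) {
  eyes <- generateCohort(cfg$nEyes, cfg$seed, cfg$params)
  view <- viewSpec("ODC", fovDeg = cfg$fovDeg, scaleFactor = cfg$scaleFactor)
  meas <- lapply(eyes, .measureRender, view = view)
  odPx <- vapply(meas, `[[`, 0, "odPx")
  cicf <- constantICF(odPx, cfg$referenceOdUm)
  if (sd(odPx) < 1e-9)
    message("degenerate cohort: all discs equal, constant ICF coincides ",
            "with the individual ICFs")
  ids <- sprintf("eye%03d", seq_along(eyes))
  resI <- resC <- vector("list", length(eyes))
  log <- list()
  for (k in seq_along(meas)) {
    iicf <- individualICF(meas[[k]]$odPx, cfg$referenceOdUm)
    resI[[k]] <- computeRVGC(meas[[k]]$map, iicf,
                             pointTable = meas[[k]]$pointTable)
    resC[[k]] <- computeRVGC(meas[[k]]$map, cicf,
                             pointTable = meas[[k]]$pointTable)
    log[[k]] <- list(image_id = ids[k], od_px = meas[[k]]$odPx,
                     iicf = icfValue(iicf),
                     flags = unique(c(rvgcFlags(resI[[k]]),
                                      rvgcFlags(resC[[k]]))))
  }
  rvgc <- rbind(
    do.call(rbind, Map(.rvgcRow, resI, ids)),
    do.call(rbind, Map(.rvgcRow, resC, ids)))
  agreement <- .agreementTable(.valuesMatrix(resI), .valuesMatrix(resC),
                               ids, cfg$alpha)
  icfTable <- data.frame(image_id = ids, od_px = odPx,
                         icf = cfg$referenceOdUm / odPx,
                         kind = "individual")
  icfTable <- rbind(icfTable,
                    data.frame(image_id = "cohort", od_px = mean(odPx),
                               icf = icfValue(cicf), kind = "constant"))
  .writeCsv(cfg$outDir, rvgc, "rvgc_icf.csv")
  .writeCsv(cfg$outDir, agreement, "agreement_icf.csv")
  .writeCsv(cfg$outDir, icfTable, "icf_table.csv")
  .writeLog(cfg$outDir, log, "log_icf.jsonl")
  list(rvgc = rvgc, agreement = agreement, constantIcf = cicf,
       icfTable = icfTable,
       threshold = bonferroniThreshold(cfg$alpha, length(RVGC_NAMES)),
       log = log)
}

#' Disc-centered vs macula-centered framing with individual factors
#'
#' Renders every eye in both centerings at the same resolution, measures
#' each render with its own individual conversion factor, excludes eyes
#' whose zone C annulus is clipped beyond `cfg$maxClipFrac` in either
#' view, and summarizes disc-centered minus macula-centered per
#' characteristic.
#'
#' @param cfg configuration from [experimentConfig()]; `views` must
#'   contain both `"ODC"` and `"MC"`.
#' @return list with `rvgc`, `agreement`, `excluded` (image ids),
#'   `threshold` and `log`; CSV/JSONL outputs under `cfg$outDir` when
#'   set.
#' @export
runCenteringComparison <- function(cfg = experimentConfig(views = c("ODC", "MC"))) {
  if (!all(c("ODC", "MC") %in% cfg$views))
    stop("centering comparison needs both ODC and MC views")
  eyes <- generateCohort(cfg$nEyes, cfg$seed, cfg$params)
  ids <- sprintf("eye%03d", seq_along(eyes))
  vODC <- viewSpec("ODC", fovDeg = cfg$fovDeg, scaleFactor = cfg$scaleFactor)
  vMC <- viewSpec("MC", fovDeg = cfg$fovDeg, scaleFactor = cfg$scaleFactor)
  resO <- resM <- vector("list", length(eyes))
  keep <- logical(length(eyes))
  log <- list()
  for (k in seq_along(eyes)) {
    mapO <- renderView(eyes[[k]], vODC)
    mapM <- renderView(eyes[[k]], vMC)
    clip <- c(ODC = mapO@meta$clipFracZoneC, MC = mapM@meta$clipFracZoneC)
    keep[k] <- all(clip <= cfg$maxClipFrac)
    entry <- list(image_id = ids[k], clip_frac = as.list(clip),
                  excluded = !keep[k])
    if (keep[k]) {
      ptO <- skeletonPointTable(mapO); ptM <- skeletonPointTable(mapM)
      odO <- opticDiscFromMap(mapO); odM <- opticDiscFromMap(mapM)
      mapO <- .mapLite(mapO); mapM <- .mapLite(mapM)
      resO[[k]] <- computeRVGC(mapO, individualICF(odO, cfg$referenceOdUm),
                               pointTable = ptO)
      resM[[k]] <- computeRVGC(mapM, individualICF(odM, cfg$referenceOdUm),
                               pointTable = ptM)
      entry$flags <- unique(c(rvgcFlags(resO[[k]]), rvgcFlags(resM[[k]])))
    }
    log[[k]] <- entry
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 eyes with acceptably complete zone C in both views")
  resO <- resO[keep]; resM <- resM[keep]; idsK <- ids[keep]
  rvgc <- rbind(
    cbind(view = "ODC", do.call(rbind, Map(.rvgcRow, resO, idsK))),
    cbind(view = "MC", do.call(rbind, Map(.rvgcRow, resM, idsK))))
  agreement <- .agreementTable(.valuesMatrix(resO), .valuesMatrix(resM),
                               idsK, cfg$alpha)
  .writeCsv(cfg$outDir, rvgc, "rvgc_centering.csv")
  .writeCsv(cfg$outDir, agreement, "agreement_centering.csv")
  .writeLog(cfg$outDir, log, "log_centering.jsonl")
  list(rvgc = rvgc, agreement = agreement, excluded = ids[!keep],
       threshold = bonferroniThreshold(cfg$alpha, length(RVGC_NAMES)),
       log = log)
}

#' Right vs left eye under the constant conversion factor
#'
#' Models the fellow eye of each patient as a horizontal mirror image
#' with independent caliber noise, measures both disc-centered renders
#' under the cohort constant factor (computed from all discs of both
#' sides), and reports the per-characteristic paired comparison.  Under
#' this null construction the comparisons are non-significant in
#' expectation.
#'
#' @param cfg configuration from [experimentConfig()]; `nEyes` is the
#'   number of patients (pairs).
#' @return list with `rvgc`, `comparison` (mean +/- SD per side with the
#'   paired p-value), `threshold` and `log`; CSV/JSONL outputs under
#'   `cfg$outDir` when set.
#' @export
runLateralityComparison <- function(cfg = experimentConfig()) {
  seeds <- .eyeSeeds(cfg$seed, 2L * cfg$nEyes)
  right <- lapply(seeds[seq_len(cfg$nEyes)],
                  function(s) generateEye(cfg$params, seed = s))
  left <- Map(function(eye, s) mirrorEye(eye, cfg$widthNoiseUm, seed = s),
              right, seeds[cfg$nEyes + seq_len(cfg$nEyes)])
  view <- viewSpec("ODC", scaleFactor = cfg$scaleFactor)
  mR <- lapply(right, .measureRender, view = view)
  mL <- lapply(left, .measureRender, view = view)
  cicf <- constantICF(c(vapply(mR, `[[`, 0, "odPx"),
                        vapply(mL, `[[`, 0, "odPx")), cfg$referenceOdUm)
  ids <- sprintf("patient%03d", seq_len(cfg$nEyes))
  resR <- Map(function(m) computeRVGC(m$map, cicf, pointTable = m$pointTable), mR)
  resL <- Map(function(m) computeRVGC(m$map, cicf, pointTable = m$pointTable), mL)
  xR <- .valuesMatrix(resR); xL <- .valuesMatrix(resL)
  rows <- lapply(RVGC_NAMES, function(v) {
    pc <- pairedCompare(pairedSeries(xL[, v], xR[, v], ids))
    data.frame(rvgc = v,
               right_mean = mean(xR[, v], na.rm = TRUE),
               right_sd = sd(xR[, v]),
               left_mean = mean(xL[, v], na.rm = TRUE),
               left_sd = sd(xL[, v]),
               p_value = pc$p, test = pc$test)
  })
  comparison <- do.call(rbind, rows)
  comparison$bonferroni_threshold <-
    bonferroniThreshold(cfg$alpha, length(RVGC_NAMES))
  rvgc <- rbind(
    cbind(side = "right", do.call(rbind, Map(.rvgcRow, resR, ids))),
    cbind(side = "left", do.call(rbind, Map(.rvgcRow, resL, ids))))
  log <- Map(function(id, r, l)
    list(image_id = id, flags = unique(c(rvgcFlags(r), rvgcFlags(l)))),
    ids, resR, resL)
  .writeCsv(cfg$outDir, rvgc, "rvgc_laterality.csv")
  .writeCsv(cfg$outDir, comparison, "comparison_laterality.csv")
  .writeLog(cfg$outDir, unname(log), "log_laterality.jsonl")
  list(rvgc = rvgc, comparison = comparison,
       threshold = bonferroniThreshold(cfg$alpha, length(RVGC_NAMES)),
       log = unname(log))
}
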