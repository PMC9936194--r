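# End-to-end orchestration: simulate (or load) -> register -> cycles ->
# EMG -> PCA -> stepwise regression -> reconstruction, with a manifest
# and per-stage log so a run is reproducible bit for bit.

.defaultThresholds <- function() {
  list(varianceThreshold = 0.95, pEnter = 0.05, pRemove = 0.10,
       cutoffHz = 250, qHi = 0.95, qLo = 0.05,
       cropDistance = 60, normDistance = 20)
}

.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config$thresholds <- utils::modifyList(.defaultThresholds(),
                                         config$thresholds %||% list())
  config$arms <- config$arms %||% c("kinematic", "emg")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full sprint-analysis pipeline
#'
#' Orchestrates every stage from a single declarative configuration,
#' writing all intermediate artifacts plus a manifest (file checksums,
#' seeds, parameters, package version) and a per-stage timing log to
#' \code{outDir}. Rerunning with the same configuration reproduces the
#' artifacts exactly.
#'
#' The configuration is a list (or a YAML/JSON file) with either a
#' \code{synthesis} block (arguments to \code{\link{cohortSpec}}) or a
#' \code{subjects} list (per subject: \code{marker} C3D path, optional
#' \code{emg} CSV path, \code{height}, \code{sex}, \code{age});
#' optional \code{thresholds} (variance retention 0.95, stepwise
#' 0.05/0.10, envelope cutoff 250 Hz, reconstruction percentiles
#' 0.05/0.95, crop 60 m, normalization window 20 m) and \code{arms}
#' (any of \code{"kinematic"}, \code{"emg"}).
#'
#' @param config list or path, see Details.
#' @param outDir output directory.
#' @param writeFeatures write the (large) per-arm feature matrices as
#'   CSV artifacts.
#' @return invisibly, a results bundle: per-arm \code{featureSet},
#'   \code{pca}, \code{retained}, \code{model}, \code{reconstruction},
#'   plus \code{outcome}, \code{manifest} path and \code{log} path.
#' @export
runPipeline <- function(config, outDir, writeFeatures = TRUE) {
  config <- .readConfig(config)
  th <- config$thresholds
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  cat("", file = logPath)
  t0 <- proc.time()[3]
  logLine <- function(...) {
    cat(sprintf("[%8.2fs] ", proc.time()[3] - t0), ..., "\n",
        sep = "", file = logPath, append = TRUE)
  }
  stage <- function(name, subjectId, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for subject ", subjectId, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  files <- character(0)
  addFile <- function(p) files <<- c(files, p)

  # ---- acquire trials ------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthesis)) {
    spec <- do.call(cohortSpec, config$synthesis)
    logLine("simulate: ", spec@nSubjects, " subjects, seed ", spec@seed)
    what <- if (all(c("kinematic", "emg") %in% config$arms)) "both"
            else config$arms[1]
    cohort <- generateCohort(spec, what = what)
    subjects <- lapply(seq_len(spec@nSubjects), function(i) {
      list(id = cohort$covariates$id[i],
           markerTrial = cohort$trials[[i]]$marker,
           emgTrial = cohort$trials[[i]]$emg,
           height = cohort$covariates$height[i],
           sex = cohort$covariates$sex[i],
           age = cohort$covariates$age[i])
    })
    truth <- cohort$truth
  } else if (!is.null(config$subjects)) {
    subjects <- lapply(seq_along(config$subjects), function(i) {
      s <- config$subjects[[i]]
      id <- s$id %||% sprintf("S%02d", i)
      if (is.null(s$height) || is.na(s$height))
        stop("config is missing height for subject ", id)
      mt <- stage("load", id, readMarkerTrial(
        s$marker, subject = list(id = id, height = s$height,
                                 sex = s$sex %||% NA_real_,
                                 age = s$age %||% NA_real_)))
      et <- if (!is.null(s$emg)) stage("load", id, readEmgTrial(s$emg))
      list(id = id, markerTrial = mt, emgTrial = et,
           height = s$height, sex = s$sex %||% NA_real_,
           age = s$age %||% NA_real_)
    })
  } else stop("config needs either a 'synthesis' block or a 'subjects' list")
  n <- length(subjects)

  # ---- register + cycles + per-subject features ----------------------
  kinF <- matrix(NA_real_, n, KIN_FEATURE_LENGTH)
  emgF <- if ("emg" %in% config$arms) matrix(NA_real_, n, EMG_FEATURE_LENGTH)
  outcome <- numeric(n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    reg <- stage("register", s$id,
                 registerSprint(s$markerTrial, th$cropDistance))
    kf <- stage("cycles", s$id,
                kinematicFeatures(reg$trial, height = s$height))
    kinF[i, ] <- kf$features
    outcome[i] <- kf$peakSpeed
    if (!is.null(emgF) && !is.null(s$emgTrial)) {
      ef <- stage("emg", s$id,
                  emgFeatures(s$emgTrial, reg$trial, kf$windows,
                              cutoffHz = th$cutoffHz,
                              normDistance = th$normDistance))
      emgF[i, ] <- ef$features
    }
    logLine("subject ", s$id, ": peak ", sprintf("%.2f", outcome[i]),
            " m/s, ", length(kf$events), " stride events")
  }
  if (!is.null(emgF) && anyNA(emgF)) emgF <- NULL  # no EMG data supplied

  covar <- data.frame(
    sex = vapply(subjects, `[[`, 0, "sex"),
    age = vapply(subjects, `[[`, 0, "age"),
    height = vapply(subjects, `[[`, 0, "height"))
  ids <- vapply(subjects, `[[`, "", "id")

  # ---- per-arm PCA, stepwise, reconstruction -------------------------
  results <- list()
  for (arm in intersect(config$arms, c("kinematic", "emg"))) {
    feats <- if (arm == "kinematic") kinF else emgF
    if (is.null(feats)) next
    fs <- featureSet(feats, outcome, covar$sex, covar$age, covar$height,
                     kind = arm, subjectIds = ids)
    pca <- fitWaveformPca(fs)
    ret <- retainComponents(pca, th$varianceThreshold)
    logLine(arm, ": retained ", length(ret$indices), " PCs (",
            sprintf("%.1f%%", 100 * ret$cumulative), " cumulative variance)")
    cand <- cbind(pca@scores[, ret$indices, drop = FALSE],
                  sex = covar$sex, age = covar$age, height = covar$height)
    model <- stepwiseRegress(cand, outcome,
                             pEnter = th$pEnter, pRemove = th$pRemove)
    logLine(arm, ": selected ", paste(model@selected, collapse = ", "),
            sprintf(" (R2 = %.3f)", model@r2))
    selPcs <- as.integer(sub("^PC", "",
      grep("^PC[0-9]+$", model@selected, value = TRUE)))
    recon <- if (length(selPcs))
      mcr(pca, selPcs, regression = model, qHi = th$qHi, qLo = th$qLo,
          alignToOutcome = TRUE)

    # artifacts
    if (writeFeatures) {
      p <- file.path(outDir, paste0("features_", arm, ".csv"))
      write.csv(data.frame(id = ids, feats, check.names = FALSE), p,
                row.names = FALSE)
      addFile(p)
    }
    p <- file.path(outDir, paste0("pca_", arm, "_summary.csv"))
    write.csv(data.frame(component = seq_along(pca@varExplained),
                         varianceFraction = pca@varExplained,
                         cumulative = cumsum(pca@varExplained)),
              p, row.names = FALSE)
    addFile(p)
    p <- file.path(outDir, paste0("scores_", arm, ".csv"))
    write.csv(data.frame(id = ids, pca@scores, check.names = FALSE), p,
              row.names = FALSE)
    addFile(p)
    p <- file.path(outDir, paste0("regression_", arm, ".csv"))
    writeModelReport(model, p)
    addFile(p)
    if (!is.null(recon)) {
      rp <- exportReconstruction(recon, file.path(outDir, "recon"),
                                 referenceHeight = mean(covar$height),
                                 prefix = paste0(arm, "_mcr"))
      for (q in rp) addFile(q)
    }
    results[[arm]] <- list(featureSet = fs, pca = pca, retained = ret,
                           model = model, reconstruction = recon)
  }

  # ---- outcome table + manifest --------------------------------------
  p <- file.path(outDir, "outcome.csv")
  write.csv(cbind(data.frame(id = ids, peakVelocity = outcome), covar), p,
            row.names = FALSE)
  addFile(p)
  manifest <- list(
    package = "sprintmodes",
    version = as.character(utils::packageVersion("sprintmodes")),
    thresholds = th,
    arms = config$arms,
    synthesis = config$synthesis,
    nSubjects = n,
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logLine("done: ", length(files), " artifacts")

  invisible(c(results, list(outcome = outcome, covariates = covar,
                            truth = truth, manifest = manifestPath,
                            log = logPath)))
}
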