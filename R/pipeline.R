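#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end run. Fully
#' determined by its values plus the master seed: a run is reproducible from
#' the config alone.
#'
#' @param sim a \linkS4class{SimConfig}.
#' @param features a \linkS4class{FeatureConfig}.
#' @param svm an \linkS4class{SVMConfig}.
#' @param split a \linkS4class{SplitSpec}.
#' @param tasks character vector of task names (subset of [painTasks()]).
#' @param emd logical, apply EMD denoising to EMG windows.
#' @param outDir output directory (created if missing).
#' @return object of class \code{PainPipelineConfig} (a validated list).
#' @export
pipelineConfig <- function(sim = simConfig(), features = featureConfig(),
                           svm = svmConfig(), split = splitSpec(),
                           tasks = painTasks(), emd = TRUE,
                           outDir = tempfile("painsig_run_")) {
  stopifnot(is(sim, "SimConfig"), is(features, "FeatureConfig"),
            is(svm, "SVMConfig"), is(split, "SplitSpec"))
  tasks <- match.arg(tasks, painTasks(), several.ok = TRUE)
  structure(list(sim = sim, features = features, svm = svm, split = split,
                 tasks = tasks, emd = emd, outDir = outDir),
            class = "PainPipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys \code{sim}, \code{features}, \code{svm}, \code{split} hold
#' the slot overrides of the respective config classes; \code{tasks},
#' \code{emd} and \code{out_dir} are optional scalars.
#'
#' @param path YAML file.
#' @return a \code{PainPipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(ctor, args) do.call(ctor, as.list(args))
  pipelineConfig(
    sim = mk(simConfig, y$sim), features = mk(featureConfig, y$features),
    svm = mk(svmConfig, y$svm), split = mk(splitSpec, y$split),
    tasks = if (is.null(y$tasks)) painTasks() else unlist(y$tasks),
    emd = if (is.null(y$emd)) TRUE else isTRUE(y$emd),
    outDir = if (is.null(y$out_dir)) tempfile("painsig_run_") else y$out_dir)
}

#' Simulate, preprocess and extract features for a whole cohort
#'
#' Streams subject by subject (simulate, filter, window, denoise, extract) so
#' raw recordings never accumulate in memory, and returns the combined
#' feature matrix before normalization.
#'
#' @param simCfg a \linkS4class{SimConfig}.
#' @param featCfg a \linkS4class{FeatureConfig}.
#' @param emd logical, EMD-denoise EMG windows (default TRUE).
#' @param verbose logical, log per-subject progress.
#' @return a \linkS4class{PainFeatureMatrix} with
#'   \code{nSubjects * (80 + nBaseline)} columns under the standard protocol.
#' @export
extractCohortFeatures <- function(simCfg = simConfig(),
                                  featCfg = featureConfig(), emd = TRUE,
                                  verbose = FALSE) {
  parts <- vector("list", simCfg@nSubjects)
  for (i in seq_len(simCfg@nSubjects)) {
    t0 <- Sys.time()
    sub <- simulateSubject(simCfg, i)
    ws <- preprocessRecording(sub$recording, sub$schedule,
                              windowS = simCfg@windowS, emd = emd)
    parts[[i]] <- extractFeatures(ws, featCfg)
    if (verbose)
      message(sprintf("subject %d/%d: %d windows in %.1f s", i,
                      simCfg@nSubjects, length(ws@labels),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  do.call(combineFeatureMatrices, parts)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> extract -> z-normalize per person -> per task:
#' prune, forward-select, grid-search, evaluate. Artifacts written to the run
#' directory: \code{features.tsv} (raw), \code{features_znorm.tsv},
#' \code{report_<task>.json} per task and \code{summary.json}.
#'
#' @param cfg a \code{PainPipelineConfig} from [pipelineConfig()].
#' @param verbose logical, stage logging via \code{message()}.
#' @return invisibly, a list with elements \code{features} (normalized
#'   \linkS4class{PainFeatureMatrix}), \code{reports} (named list of
#'   \linkS4class{EvalReport}), \code{summary} (data.frame) and \code{outDir}.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(sim = simConfig(nSubjects = 2, repsPerLevel = 2,
#'                                       nBaseline = 2, seed = 1),
#'                       tasks = "B_vs_T4")
#' }
#' @export
runPipeline <- function(cfg = pipelineConfig(), verbose = TRUE) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  fm <- extractCohortFeatures(cfg$sim, cfg$features, emd = cfg$emd,
                              verbose = verbose)
  log("extracted %d x %d feature matrix in %.1f s", nrow(fm), ncol(fm),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeFeatureMatrix(fm, file.path(cfg$outDir, "features.tsv"))
  fz <- znormPerPerson(fm)
  writeFeatureMatrix(fz, file.path(cfg$outDir, "features_znorm.tsv"))
  reports <- list()
  for (task in cfg$tasks) {
    t1 <- Sys.time()
    rep <- runTask(fz, task, svmCfg = cfg$svm, split = cfg$split,
                   seed = deriveSeed(cfg$sim@seed, "task", task))
    reports[[task]] <- rep
    writeEvalReport(rep, file.path(cfg$outDir,
                                   paste0("report_", task, ".json")))
    log("task %s: accuracy %.4f, V %.3f, %d features, %.1f s", task,
        rep@accuracy, rep@cramersV, length(rep@selectedFeatures),
        as.numeric(difftime(Sys.time(), t1, units = "secs")))
  }
  summary <- data.frame(
    task = names(reports),
    accuracy = vapply(reports, accuracy, numeric(1)),
    cramers_v = vapply(reports, function(r) r@cramersV, numeric(1)),
    n_selected = vapply(reports, function(r) length(r@selectedFeatures),
                        integer(1)),
    C = vapply(reports, function(r) unname(r@svmParams["C"]), numeric(1)),
    gamma = vapply(reports, function(r) unname(r@svmParams["gamma"]),
                   numeric(1)))
  rownames(summary) <- NULL
  jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = fz, reports = reports, summary = summary,
                 outDir = cfg$outDir))
}
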