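## End-to-end orchestration: simulate -> score -> map -> calibrate, with a
## single config, persisted intermediates and a reproducibility manifest.

#' Default run configuration
#'
#' Nested list mirroring the stage functions' arguments. Every default
#' matches the pipeline's canonical values: pre-selection filters at 10
#' reads / 10 cpm / WT 90th percentile, tolerance thresholds 0.5
#' (activity) and -0.4 (abundance), ASA classes at 20%/35%, interface
#' cutoff 5.0 Angstrom, hydrogen bonds at 3.4 Angstrom / 120 degrees, and
#' very-strong odds of pathogenicity 350.
#'
#' @param scenario \code{"activity"} or \code{"abundance"}.
#' @return named list.
#' @export
defaultRunConfig <- function(scenario = c("activity", "abundance")) {
  scenario <- match.arg(scenario)
  list(
    scenario = scenario,
    seed = 42L,
    stages = list(simulate = TRUE, score = TRUE, map = TRUE,
                  calibrate = TRUE),
    simulation = list(L = 153L, depth = 1.3e6, replicates = 2L,
                      cloneLambda = NULL, deleteriousFraction = NULL,
                      modeSd = 0.08, errorShape = 2, errorScale = 2.5e-6,
                      selectionFloor = 0.05, replicateNoiseSd = 0.5,
                      poolSize = 1e6, tiles = 5L),
    scoring = list(m = 2, minCount = 10, minCpm = 10, wtPercentile = 0.9,
                   minAnchors = 10L),
    map = list(threshold = if (scenario == "activity") 0.5 else -0.4,
               hyperSe = 2),
    calibration = list(nPos = 85L, nNeg = 100L, labelNoise = 0,
                       nBoot = 1000L, opVst = 350, gateCI = TRUE)
  )
}

checkConfigKeys <- function(config, reference = defaultRunConfig(),
                            path = "") {
  extra <- setdiff(names(config), names(reference))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (k in names(config)) {
    if (is.list(reference[[k]]) && !is.null(names(reference[[k]])) &&
        is.list(config[[k]]))
      checkConfigKeys(config[[k]], reference[[k]], paste0(path, ".", k))
  }
  invisible(TRUE)
}

mergeConfig <- function(defaults, overrides) {
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]))
      defaults[[k]] <- mergeConfig(defaults[[k]], overrides[[k]])
    else defaults[[k]] <- overrides[[k]]
  }
  defaults
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected before any stage runs; omitted keys fall back
#' to [defaultRunConfig()] values.
#'
#' @param file YAML path.
#' @return validated config list.
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  scenario <- cfg$scenario %||% "activity"
  ref <- defaultRunConfig(scenario)
  checkConfigKeys(cfg, ref)
  mergeConfig(ref, cfg)
}

simConfigFromRun <- function(config) {
  sim <- config$simulation
  preset <- if (config$scenario == "abundance") abundanceScenario
    else activityScenario
  args <- sim[!vapply(sim, is.null, logical(1))]
  args$seed <- config$seed
  do.call(preset, args)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order — simulate, score, map, calibrate —
#' persisting every intermediate under \code{outDir} along with a JSON
#' manifest (config hash, seed, package version, file list). Rerunning
#' with an identical config reproduces identical outputs. Any stage error
#' aborts the run naming the stage.
#'
#' @param config list from [defaultRunConfig()] / [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @param seed optional override of \code{config$seed}.
#' @return the run directory, invisibly; stage results in
#'   \code{attr(, "results")}.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir, seed = NULL) {
  checkConfigKeys(config, defaultRunConfig(config$scenario %||% "activity"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character()
  keep <- function(f) { files <<- c(files, basename(f)); f }

  scfg <- simConfigFromRun(config)
  if (isTRUE(config$stages$simulate)) {
    results$simulate <- run_stage("simulate", function() {
      orf <- randomOrf(scfg@L, seed = config$seed)
      variants <- enumerateVariantSpace(orf)
      truth <- simulateTruth(variants, scfg)
      counts <- simulateCountTables(truth, scfg)
      writeCountTables(counts, keep(file.path(outDir, "counts.tsv")))
      writeTruthTable(truth, keep(file.path(outDir, "truth.tsv")))
      writeLines(orf, keep(file.path(outDir, "reference_orf.txt")))
      list(orf = orf, truth = truth, counts = counts)
    })
  }
  if (isTRUE(config$stages$score)) {
    results$score <- run_stage("score", function() {
      counts <- results$simulate$counts %||%
        readCountTables(file.path(outDir, "counts.tsv"))
      sc <- config$scoring
      ss <- scoreTileseq(counts, m = sc$m, minCount = sc$minCount,
                         minCpm = sc$minCpm,
                         wtPercentile = sc$wtPercentile,
                         minAnchors = sc$minAnchors)
      writeScores(ss, keep(file.path(outDir, "scores.tsv")))
      writeMavedbScores(ss, keep(file.path(outDir, "scores_mavedb.csv")))
      ss
    })
  }
  if (isTRUE(config$stages$map)) {
    results$map <- run_stage("map", function() {
      ss <- results$score
      wt <- scoreTable(ss)
      wt_seq <- tapply(wt$from_aa, wt$position, `[`, 1L)
      em <- buildEffectMap(ss, as.vector(wt_seq),
                           threshold = config$map$threshold,
                           hyperSe = config$map$hyperSe)
      mat <- scoreMatrix(em)
      write.csv(mat, keep(file.path(outDir, "map_matrix.csv")))
      cons <- data.frame(position = seq_along(consensus(em)),
                         wt = wtSequence(em),
                         consensus = consensus(em))
      write.table(cons, keep(file.path(outDir, "consensus.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      em
    })
  }
  if (isTRUE(config$stages$calibrate)) {
    results$calibrate <- run_stage("calibrate", function() {
      cc <- config$calibration
      refsets <- simulateReferenceSets(results$simulate$truth,
                                       nPos = cc$nPos, nNeg = cc$nNeg,
                                       labelNoise = cc$labelNoise,
                                       seed = config$seed)
      report <- calibrateMap(results$score, refsets, nBoot = cc$nBoot,
                             seed = config$seed, opVst = cc$opVst,
                             gateCI = cc$gateCI)
      jsonlite::write_json(
        list(aubprc = aubprc(report), r90bp = r90bp(report),
             n_pos = report@params$n_pos, n_neg = report@params$n_neg,
             evidence_counts = as.list(table(llrTable(report)$evidence))),
        keep(file.path(outDir, "calibration.json")),
        auto_unbox = TRUE, digits = NA)
      write.table(llrTable(report), keep(file.path(outDir, "llr.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(curvePoints(report), keep(file.path(outDir, "curve.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report
    })
  }

  cfg_file <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    scenario = config$scenario,
    package_version = as.character(utils::packageVersion("mavemap")),
    files = sort(unique(c("config.yaml", "manifest.json", files))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(outDir, results = results))
}
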