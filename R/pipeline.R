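## End-to-end orchestration of the two analysis arms. Configs are plain
## lists (or JSON files with the same fields); every source of randomness is
## derived from the single config seed, so a rerun with the same config
## yields byte-identical outputs.

.readConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
    stopifnot(is.list(config))
    config
}

.writeManifest <- function(outDir, config, stage) {
    cfgPath <- file.path(outDir, "config.json")
    jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest <- list(
        stage = stage,
        seed = config$seed,
        config_md5 = unname(tools::md5sum(cfgPath)),
        package_version = as.character(utils::packageVersion("lightmask")),
        r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the behavior arm end-to-end
#'
#' Simulates (or tracks) one or more groups of larvae over a shared schedule,
#' then runs the full statistical battery: epoch metrics, occurrence rates,
#' inter-individual correlation matrices, and between-group comparisons
#' (Mann-Whitney on per-fish climbing and diving speeds and on correlation
#' coefficients, Jennrich's test on the correlation matrices, Kruskal-Wallis
#' when there are three or more groups). All artifacts (schedule JSON,
#' trajectory CSVs, metrics CSV, correlation CSVs, stats report JSON,
#' manifest) are written under \code{outDir}.
#'
#' @param config list or JSON path with fields: \code{outDir};
#'   \code{seed} (integer, default 1); \code{nCycles} (default 10);
#'   \code{rateHz} (default 5); \code{simulate} (default TRUE);
#'   \code{groups}: named list, each entry a list with either a
#'   \code{responsiveness} vector / \code{channel} / \code{nFish} for
#'   simulation, or \code{trajectoryCSV} pointing at a tracked trajectory
#'   file; optional \code{scheduleJSON} to load the schedule instead of
#'   generating it.
#' @return Invisibly, a list with the schedule, per-group
#'   \linkS4class{TrajectorySet}s, metrics, correlation matrices and the
#'   stats report (also written as JSON).
#' @examples
#' cfg <- list(outDir = tempfile(), seed = 1, nCycles = 2, rateHz = 2,
#'             groups = list(blue = list(nFish = 3),
#'                           none = list(nFish = 3,
#'                                       responsiveness = c(blue470 = 0))))
#' res <- runBehaviorPipeline(cfg)
#' names(res$report$comparisons)
#' @export
runBehaviorPipeline <- function(config) {
    config <- .readConfig(config)
    if (is.null(config$outDir)) stop("config needs an 'outDir'")
    if (is.null(config$seed)) config$seed <- 1L
    if (is.null(config$nCycles)) config$nCycles <- 10L
    if (is.null(config$rateHz)) config$rateHz <- 5
    if (is.null(config$simulate)) config$simulate <- TRUE
    if (is.null(config$groups) || !length(config$groups))
        stop("config needs at least one group")
    if (!is.null(config$scheduleJSON) && !file.exists(config$scheduleJSON))
        stop("schedule file not found: ", config$scheduleJSON)
    groups <- config$groups
    if (is.null(names(groups)))
        names(groups) <- sprintf("group%d", seq_along(groups))

    schedule <- if (!is.null(config$scheduleJSON))
        readScheduleJSON(config$scheduleJSON)
    else makeSchedule("behavior_cycles", nCycles = config$nCycles,
                      seed = config$seed,
                      channel = config$channel %||% "blue470")

    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeScheduleJSON(schedule, file.path(outDir, "schedule.json"))

    trajs <- list(); metrics <- list(); cors <- list()
    for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        gname <- names(groups)[gi]
        tr <- if (!is.null(g$trajectoryCSV)) {
            if (!config$simulate || file.exists(g$trajectoryCSV))
                readTrajectoriesCSV(g$trajectoryCSV)
            else stop("trajectory file not found: ", g$trajectoryCSV)
        } else {
            params <- behaviorParams(
                responsiveness = if (!is.null(g$responsiveness))
                    unlist(g$responsiveness)
                else eval(formals(behaviorParams)$responsiveness))
            simulateTrajectories(params, schedule,
                                 nFish = g$nFish %||% 12L,
                                 rateHz = config$rateHz,
                                 seed = .childSeed(config$seed, gi))
        }
        trajs[[gname]] <- tr
        writeTrajectoriesCSV(tr, file.path(outDir,
                                           paste0("trajectories_", gname,
                                                  ".csv")))
        m <- epochMetrics(tr, schedule)
        m$group <- gname
        metrics[[gname]] <- m
        cm <- pairwiseCorrelation(tr, group = gname)
        cors[[gname]] <- cm
        utils::write.csv(corMatrix(cm),
                         file.path(outDir, paste0("correlation_", gname,
                                                  ".csv")))
    }
    allMetrics <- do.call(rbind, metrics)
    utils::write.csv(allMetrics, file.path(outDir, "epoch_metrics.csv"),
                     row.names = FALSE)

    perFishSpeed <- function(m, dirn)
        tapply(m$initial_speed_cm_s[m$direction == dirn],
               m$fish[m$direction == dirn], mean)
    report <- list(occurrence = lapply(metrics, occurrenceRate),
                   comparisons = list())
    gn <- names(groups)
    if (length(gn) >= 2L) {
        for (a in seq_along(gn)) for (b in seq_along(gn)) {
            if (b <= a) next
            key <- paste(gn[a], "vs", gn[b])
            cmp <- list()
            for (dirn in c("climb", "dive")) {
                mw <- mannWhitneyU(perFishSpeed(metrics[[a]], dirn),
                                   perFishSpeed(metrics[[b]], dirn))
                cmp[[paste0(dirn, "_speed")]] <-
                    mw[c("U", "p", "tail", "rank_biserial")]
            }
            mwc <- mannWhitneyU(upperTriValues(cors[[a]]),
                                upperTriValues(cors[[b]]))
            cmp$correlation <- mwc[c("U", "p", "tail", "rank_biserial")]
            jt <- tryCatch(jennrichTest(cors[[a]], cors[[b]]),
                           error = function(e) list(error = conditionMessage(e)))
            cmp$jennrich <- jt
            report$comparisons[[key]] <- cmp
        }
    }
    if (length(gn) >= 3L) {
        for (dirn in c("climb", "dive"))
            report$kruskal[[paste0(dirn, "_speed")]] <-
                kruskalWallisTest(lapply(metrics, perFishSpeed, dirn = dirn))
        report$bonferroni_alpha <-
            bonferroniAlpha(0.05, choose(length(gn), 2L))
    }
    report$normality <- lapply(metrics, function(m)
        tryCatch(normalityCheck(perFishSpeed(m, "climb")),
                 error = function(e) list(error = conditionMessage(e))))
    jsonlite::write_json(report, file.path(outDir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .writeManifest(outDir, config, "behavior")
    invisible(list(schedule = schedule, trajectories = trajs,
                   metrics = allMetrics, correlations = cors,
                   report = report))
}

#' Run the imaging arm end-to-end
#'
#' For each simulated fish: generate a randomized blue/red schedule movie
#' with planted sources, PCA-reduce, run spatial ICA, segment ROIs, extract
#' z-scored traces, build that fish's template bank and classify the ICA
#' temporal signals; finally collect the classified spatial maps across fish
#' and register/average them per category. All randomness derives from the
#' config seed (schedule order, per-fish source jitter, movie noise), so
#' reruns are byte-identical.
#'
#' @param config list or JSON path with fields (all optional but
#'   \code{outDir}): \code{seed} (default 1), \code{nFish} (default 7),
#'   \code{nPulses} (default 6 colored pulses), \code{dim} (default
#'   c(40, 60)), \code{rateHz} (default 1), \code{amplitude} (default 1),
#'   \code{noiseSd} (default 0.1), \code{jitterPx} (default 2),
#'   \code{k} (retained PCs, default 10), \code{mu} (default 0),
#'   \code{tau} (sawtooth decay, default 2), \code{threshold} (default 0.5).
#' @return Invisibly, a list with per-fish results (decomposition,
#'   classification table) and the \linkS4class{ClassifiedMaps} integration.
#' @examples
#' \donttest{
#' res <- runImagingPipeline(list(outDir = tempfile(), seed = 1, nFish = 2,
#'                                dim = c(24, 36), nPulses = 4))
#' names(categoryAverages(res$integrated))
#' }
#' @export
runImagingPipeline <- function(config) {
    config <- .readConfig(config)
    if (is.null(config$outDir)) stop("config needs an 'outDir'")
    defaults <- list(seed = 1L, nFish = 7L, nPulses = 10L, dim = c(28L, 40L),
                     rateHz = 1, amplitude = 1, noiseSd = 0.1, jitterPx = 2L,
                     k = 10L, mu = 0, tau = 2, threshold = 0.5)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    perFish <- list()
    catMaps <- stats::setNames(vector("list", length(.TEMPLATE_KEYS)),
                               .TEMPLATE_KEYS)
    classRows <- list()
    for (f in seq_len(config$nFish)) {
        fid <- sprintf("fish%02d", f)
        fseed <- .childSeed(config$seed, f)
        schedule <- makeSchedule("imaging_random", nCycles = config$nPulses,
                                 seed = fseed)
        sources <- defaultSources(dim = config$dim,
                                  amplitude = config$amplitude,
                                  jitterPx = config$jitterPx, seed = fseed)
        sim <- simulateCalciumMovie(schedule, sources, dim = config$dim,
                                    rateHz = config$rateHz,
                                    noiseSd = config$noiseSd, seed = fseed)
        pca <- pcaReduce(sim$movie, config$k)
        ica <- spatialICA(pca, mu = config$mu)
        rois <- suppressWarnings(segmentROIs(ica))
        traces <- if (length(rois)) roiTraces(sim$movie, rois) else NULL
        bank <- buildTemplates(schedule, rateHz = config$rateHz,
                               tau = config$tau)
        cls <- classifyComponents(ica, bank, threshold = config$threshold)
        cls$fish <- fid
        classRows[[f]] <- cls
        for (i in which(cls$category != "unclassified")) {
            mp <- componentImage(ica, cls$component[i])
            attr(mp, "maxCorr") <- cls$max_corr[i]
            attr(mp, "component") <- cls$component[i]
            cat <- cls$category[i]
            ## one map per fish per category: keep the best-correlated
            if (is.null(catMaps[[cat]][[fid]]) ||
                attr(catMaps[[cat]][[fid]], "maxCorr") < cls$max_corr[i])
                catMaps[[cat]][[fid]] <- mp
        }
        perFish[[fid]] <- list(schedule = schedule, decomposition = ica,
                               rois = rois, traces = traces,
                               classification = cls,
                               centers = attr(sources, "centers"))
    }
    allCls <- do.call(rbind, classRows)
    utils::write.csv(allCls, file.path(outDir, "classification.csv"),
                     row.names = FALSE)
    catMaps <- Filter(function(x) length(x) > 0L, catMaps)
    integrated <- if (length(catMaps))
        registerAndAverage(catMaps, reference = "fish01") else NULL
    if (!is.null(integrated)) {
        avg <- categoryAverages(integrated)
        pages <- lapply(avg, function(m) { m[is.na(m)] <- 0; m })
        writeMovieTIFF(pages, file.path(outDir, "category_averages.tif"))
        jsonlite::write_json(
            list(categories = names(avg),
                 offsets = memberMaps(integrated)),
            file.path(outDir, "offsets.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    .writeManifest(outDir, config, "imaging")
    invisible(list(perFish = perFish, classification = allCls,
                   integrated = integrated))
}
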