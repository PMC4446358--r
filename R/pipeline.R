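#' Run the segmentation pipeline from a configuration
#'
#' Executes the requested stages in order -- `scene` (synthetic scene
#' generation), `oversegment`, `train`, `segment` (standard / delayed /
#' two-phase context-aware) and `evaluate` -- writing every intermediate
#' artifact (superpixels, model, segmentation, JSON reports) into `outDir`
#' together with a provenance record embedding the full configuration and
#' the package version. All randomness flows from the single `seed` entry,
#' so rerunning the same configuration reproduces the outputs.
#'
#' Configuration (YAML file or list): a top-level `seed`, a `stages` vector,
#' and one optional section per stage with that stage's parameters
#' (defaults: `scene` accepts [sceneSpec()] fields; `oversegment` accepts
#' [watershedOversegment()] fields; `train` accepts regime/kIters/
#' numTrees/maxDepth/delta; `segment` accepts method/delta/deltaM/
#' mitoProbThreshold; `evaluate` needs no fields).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param outDir output directory (created if missing).
#' @return named list of artifact paths (invisibly).
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$seed)) stop("config must declare a root seed")
    seed <- as.integer(config$seed)
    stages <- config$stages %||%
        c("scene", "oversegment", "train", "segment", "evaluate")
    bad <- setdiff(stages,
                   c("scene", "oversegment", "train", "segment",
                     "evaluate"))
    if (length(bad) > 0)
        stop("unknown stage(s): ", paste(bad, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    art <- list()
    scene <- NULL; labels <- NULL; probs <- NULL; gt <- NULL
    predictor <- NULL; segmentation <- NULL

    writeReport <- function(name, payload) {
        p <- file.path(outDir, paste0(name, ".json"))
        jsonlite::write_json(
            c(list(stage = name,
                   provenance = list(
                       config = config,
                       package = as.character(
                           utils::packageVersion("cadaSeg")),
                       timestamp = format(Sys.time(), tz = "UTC"))),
              payload),
            p, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
        art[[name]] <<- p
    }

    for (stage in stages) {
        prm <- config[[stage]] %||% list()
        if (stage == "scene") {
            spec <- do.call(sceneSpec, c(prm, list(seed = seed)))
            scene <- generateScene(spec)
            labels <- scene@superpixels
            probs <- scene@probs
            gt <- scene@gtCells
            p <- file.path(outDir, "gt.tif")
            writeLabelVolume(gt, p); art$gt <- p
            p <- file.path(outDir, "superpixels.tif")
            writeLabelVolume(labels, p); art$superpixels <- p
            art$probs <- writeProbabilityMaps(probs,
                                              file.path(outDir, "probs"))
            writeReport("scene", list(spec = spec))
        } else if (stage == "oversegment") {
            if (is.null(probs)) {
                probs <- readProbabilityMaps(prm$probs %||%
                                             stop("oversegment: no probs"))
            }
            labels <- do.call(watershedOversegment,
                              c(list(probs = probs),
                                prm[intersect(names(prm),
                                              c("seedThreshold",
                                                "minSeedSize",
                                                "smoothingSigma"))]))
            p <- file.path(outDir, "superpixels.tif")
            writeLabelVolume(labels, p); art$superpixels <- p
            writeReport("oversegment",
                        list(nSuperpixels = length(labelIds(labels))))
        } else if (stage == "train") {
            if (is.null(labels) || is.null(probs) || is.null(gt))
                stop("train: needs labels, probs and ground truth ",
                     "(run the scene stage or point the config at files)")
            ts <- buildTrainingSet(
                labels, probs, gt,
                regime = prm$regime %||% "single",
                kIters = prm$kIters %||% 2L,
                delta = prm$delta %||% 0.14,
                mitoProbThreshold = prm$mitoProbThreshold %||% 0.5,
                seed = seed)
            predictor <- trainBoundaryClassifier(
                ts$features, ts$labels,
                numTrees = prm$numTrees %||% 100L,
                maxDepth = prm$maxDepth %||% 20L, seed = seed)
            p <- file.path(outDir, "predictor.rds")
            savePredictor(predictor, p); art$predictor <- p
            writeReport("train",
                        list(nRows = length(ts$labels),
                             classBalance = as.list(table(ts$labels))))
        } else if (stage == "segment") {
            if (is.null(predictor) && !is.null(prm$predictor))
                predictor <- loadPredictor(prm$predictor)
            method <- prm$method %||% "cada"
            hc <- predictor %||% meanProbPredictor()
            if (method == "cada") {
                res <- cadaSegment(labels, probs, hc,
                                   deltaC = prm$delta %||% 0.14,
                                   deltaM = prm$deltaM %||% 0.5,
                                   mitoProbThreshold =
                                       prm$mitoProbThreshold %||% 0.5)
                segmentation <- res$labels
                writeReport("segment",
                            list(method = method, phase1 = res$phase1,
                                 phase2 = res$phase2,
                                 unabsorbedMito = res$unabsorbedMito))
            } else {
                graph <- buildRAG(labels, probs)
                graph <- if (method == "standard")
                    standardAgglomerate(graph, hc, prm$delta %||% 0.14)
                else delayedAgglomerate(graph, hc, prm$delta %||% 0.14)
                segmentation <- exportLabels(graph, labels)
                writeReport("segment", list(method = method,
                                            report = runReport(graph)))
            }
            p <- file.path(outDir, "segmentation.tif")
            writeLabelVolume(segmentation, p); art$segmentation <- p
        } else if (stage == "evaluate") {
            seg <- segmentation %||% labels
            if (is.null(gt) || is.null(seg))
                stop("evaluate: needs ground truth and a segmentation")
            sm <- splitMetrics(gt, seg)
            writeReport("evaluate",
                        list(viOE = sm@viOE, viUE = sm@viUE,
                             reOE = sm@reOE, reUE = sm@reUE))
        }
    }
    invisible(art)
}
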