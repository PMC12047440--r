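# Umbrella runner binding the stages into a reproducible run with a
# manifest (config hash, input digests, seed, per-stage outputs).

.pipelineConfigKeys <- c("stages", "simulate", "massphot", "report")

#' Run a multi-stage analysis with a reproducible manifest
#'
#' Executes the requested stages in dependency order. The supported flow
#' is \code{simulate} (mass-photometry generator, writing an event TSV,
#' a standards TSV and a ground-truth YAML side-car), \code{massphot}
#' (calibration from the standards, 100-bin/8-kDa histogram, oligomer
#' peak fit; writes histogram CSV and fit JSON) and \code{report}
#' (writes the manifest). Identical config and seed reproduce
#' byte-identical stage outputs; a stage failure is recorded in the
#' manifest as partial completion.
#'
#' @param config nested list; allowed top-level keys: \code{stages}
#'   (character vector), \code{simulate} (arguments of
#'   \code{\link{simMassEvents}}), \code{massphot} (\code{lower_edge},
#'   \code{monomer_mass}), \code{report}. Unknown keys are an error
#'   before any stage runs.
#' @param out output directory (created if needed).
#' @param seed integer master seed.
#' @return the manifest (list), invisibly written to
#'   \code{manifest.yaml} when the report stage runs.
#' @export
runPipeline <- function(config, out = tempfile("run"), seed = 1) {
    bad <- setdiff(names(config), .pipelineConfigKeys)
    if (length(bad))
        stop("invalid config key(s): ", paste(bad, collapse = ", "))
    stages <- config$stages
    if (is.null(stages)) stages <- c("simulate", "massphot", "report")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)

    cfgFile <- file.path(out, "config.yaml")
    yaml::write_yaml(config, cfgFile)
    manifest <- list(tool = "rnpquant",
                     version = as.character(utils::packageVersion("rnpquant")),
                     config_hash = unname(tools::md5sum(cfgFile)),
                     seed = seed,
                     started = format(Sys.time(), tz = "UTC"),
                     stages = list(), inputs = list(), outputs = list())

    paths <- list(events = file.path(out, "events.tsv"),
                  standards = file.path(out, "standards.tsv"),
                  truth = file.path(out, "ground_truth.yaml"),
                  histogram = file.path(out, "histogram.csv"),
                  fit = file.path(out, "oligomer_fit.json"))

    for (st in stages) {
        status <- tryCatch({
            switch(st,
                simulate = {
                    sc <- config$simulate
                    if (is.null(sc$species))
                        sc$species <- data.frame(mass = c(120, 240),
                                                 fraction = c(0.3, 0.7))
                    sim <- simMassEvents(
                        species = sc$species,
                        n_events = sc$n_events %||% 20000,
                        mass_noise_sd = sc$mass_noise_sd %||% 12,
                        calibration = sc$calibration %||%
                            c(slope = 1000, intercept = 0),
                        seed = seed)
                    write.table(data.frame(contrast = sim$events@contrast),
                                paths$events, sep = "\t",
                                row.names = FALSE, quote = FALSE)
                    std <- do.call(rbind, lapply(names(sim$standards),
                        function(nm) data.frame(species = nm,
                            contrast = sim$standards[[nm]]@contrast)))
                    write.table(std, paths$standards, sep = "\t",
                                row.names = FALSE, quote = FALSE)
                    tr <- groundTruth(sim$events)
                    tr$component <- NULL
                    tr$species <- as.list(as.data.frame(tr$species))
                    writeGroundTruth(tr, paths$truth)
                    manifest$outputs$simulate <-
                        unname(unlist(paths[c("events", "standards",
                                              "truth")]))
                    "ok"
                },
                massphot = {
                    ev <- read.delim(paths$events)
                    std <- read.delim(paths$standards)
                    manifest$inputs$massphot <- as.list(
                        tools::md5sum(c(paths$events, paths$standards)))
                    sets <- lapply(split(std$contrast, std$species),
                                   function(ct) new("MassEventSet",
                                                    contrast = ct))
                    cal <- calibrateMass(sets, massStandards()[names(sets)])
                    mes <- applyCalibration(
                        new("MassEventSet", contrast = ev$contrast), cal)
                    mc <- config$massphot
                    h <- buildMassHistogram(mes,
                                            lower_edge = mc$lower_edge %||% 0)
                    h <- smoothMassHistogram(h)
                    writeHistogramCsv(h, paths$histogram)
                    fit <- fitOligomerPeaks(h,
                        monomer_mass = mc$monomer_mass %||% 40)
                    jsonlite::write_json(fit@table, paths$fit,
                                         dataframe = "rows", digits = NA,
                                         na = "null")
                    manifest$outputs$massphot <-
                        unname(unlist(paths[c("histogram", "fit")]))
                    "ok"
                },
                report = {
                    "ok"
                },
                stop("unknown stage: ", st))
        }, error = function(e) paste("failed:", conditionMessage(e)))
        manifest$stages[[st]] <- status
        if (!identical(status, "ok")) break
    }
    manifest$finished <- format(Sys.time(), tz = "UTC")
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    manifest$out <- out
    invisible(manifest)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
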