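## End-to-end orchestration: filter -> ruminotype -> DA/PA -> sPLS-DA +
## sPLS regression -> biomarker intersection -> variance components.

#' Pipeline configuration
#'
#' Declarative configuration for [runPipeline()]: either paths to the
#' three input files or a [scenarioConfig()] to simulate them, stage
#' toggles, per-stage parameters, and a single global seed from which
#' every stage derives its own named substream. Round-trips to JSON.
#'
#' @param scenario a [scenarioConfig()] (used when `paths` is NULL).
#' @param paths optional list with `counts`, `genotypes`, `phenotypes`.
#' @param stages character vector of stages to run, a subset of
#'   `c("filter", "ruminotype", "differential", "spls", "varcomp")`.
#' @param trait trait to analyse (`"CH4y"` or `"CH4"`).
#' @param kRange candidate cluster numbers.
#' @param nBoot Jaccard bootstrap repetitions.
#' @param keepX sPLS-DA keepX per component.
#' @param keepXReg sPLS regression keepX (component 1).
#' @param folds,repeats cross-validation layout.
#' @param mcmc an [mcmcConfig()].
#' @param seed global seed.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(scenario = scenarioConfig(), paths = NULL,
                           stages = c("filter", "ruminotype",
                                      "differential", "spls", "varcomp"),
                           trait = "CH4y", kRange = 2:8, nBoot = 100,
                           keepX = c(200, 31), keepXReg = 200, folds = 5,
                           repeats = 50, mcmc = mcmcConfig(), seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Save / load a pipeline configuration
#'
#' @param cfg a [pipelineConfig()].
#' @param path JSON file path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` the configuration.
#' @export
writePipelineConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$scenario <- do.call(scenarioConfig, raw$scenario[names(raw$scenario) %in%
    names(formals(scenarioConfig))])
  raw$mcmc <- do.call(mcmcConfig, raw$mcmc[names(raw$mcmc) %in%
    names(formals(mcmcConfig))])
  cfg <- do.call(pipelineConfig, raw[names(raw) %in%
    names(formals(pipelineConfig))])
  cfg
}

# per-stage substream seeds derived from the global seed (kept < 2^31)
.stageSeed <- function(seed, stage) {
  offs <- c(simulate = 0L, ruminotype = 101L, differential = 202L,
            spls = 303L, varcomp = 404L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full analytical pipeline
#'
#' Stage order: load/simulate inputs, OTU filtering, genus aggregation,
#' ruminotype discovery (sqrt-JSD + PAM, CH model selection, bootstrap
#' stability, phenotype association), differential abundance (ZIG) and
#' presence-absence tests on genera, sPLS-DA on clusters and sPLS
#' regression on the adjusted trait at OTU level, biomarker intersection,
#' and the two-kernel variance-component model on the whole and selected
#' OTU sets. Per-stage TSV/JSON outputs and a manifest (parameters, seeds,
#' stage-by-stage feature counts) are written to `outDir` when given.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir optional output directory.
#' @return list with the per-stage results and the manifest.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir = NULL) {
  stages <- cfg$stages
  manifest <- list(package_version = as.character(utils::packageVersion("ruminotyper")),
                   seed = cfg$seed, stages = stages, counts = list())
  res <- list(config = cfg)

  ## inputs
  if (is.null(cfg$paths)) {
    cfg$scenario$seed <- .stageSeed(cfg$seed, "simulate")
    study <- simulateStudy(cfg$scenario)
  } else {
    study <- list(counts = readCountTable(cfg$paths$counts),
                  genotypes = readGenotypes(cfg$paths$genotypes),
                  phenotypes = readPhenotypes(cfg$paths$phenotypes),
                  truth = NULL)
  }
  res$truth <- study$truth
  manifest$counts$input_features <- nrow(study$counts)

  pheno <- preparePhenotypes(study$phenotypes, trait = cfg$trait)
  adjCol <- paste0("adj_", cfg$trait)
  traitByAnimal <- perAnimalTrait(pheno, adjCol)
  res$phenotypes <- pheno

  counts <- study$counts
  if ("filter" %in% stages) {
    counts <- filterOtus(counts)
    manifest$counts$after_filter <- nrow(counts)
  }
  genera <- aggregateTaxon(counts, "genus")
  manifest$counts$genera <- nrow(genera)
  res$counts <- counts

  sampleIds <- colnames(otuCounts(counts))
  traitVec <- traitByAnimal[sampleIds]

  labels <- NULL
  if ("ruminotype" %in% stages) {
    d <- jsdDistance(toRelative(genera))
    sel <- selectK(d, kRange = cfg$kRange)
    boot <- jaccardBootstrap(d, sel$chosenK, nBoot = cfg$nBoot,
                             seed = .stageSeed(cfg$seed, "ruminotype"))
    labels <- clusterLabels(sel$solution)
    assoc <- clusterPhenotypeAssoc(labels, traitVec)
    res$ruminotype <- list(quality = sel$table, chosenK = sel$chosenK,
                           labels = labels,
                           stability = boot$clusterJaccard, assoc = assoc)
    manifest$counts$chosen_k <- sel$chosenK
  }

  if ("differential" %in% stages && !is.null(labels)) {
    grp <- factor(paste0("R", labels))
    res$differential <- list(
      zig = differentialAbundance(genera, grp),
      pa = presenceAbsence(genera, grp))
  }

  if ("spls" %in% stages && !is.null(labels)) {
    clrX <- clrTransform(counts)
    grp <- factor(paste0("R", labels))
    ncompDa <- min(length(cfg$keepX), nlevels(grp) - 1L + 1L)
    daFit <- splsdaFit(clrX, grp, ncomp = length(cfg$keepX),
                       keepX = pmin(cfg$keepX, nrow(counts)))
    regFit <- splsFit(clrX, traitVec, ncomp = 1,
                      keepX = min(cfg$keepXReg, nrow(counts)))
    set.seed(.stageSeed(cfg$seed, "spls"))
    auc <- suppressWarnings(aurocScores(daFit, t(abundanceValues(clrX)), grp))
    bio <- intersectBiomarkers(daFit, regFit)
    res$spls <- list(da = daFit, reg = regFit, auroc = auc,
                     biomarkers = bio)
    manifest$counts$biomarkers_common <- sum(bio$source == "common")
  }

  if ("varcomp" %in% stages) {
    qc <- genotypeQC(study$genotypes)
    biom <- if (!is.null(res$spls))
      res$spls$biomarkers$feature_id[res$spls$biomarkers$source == "common"]
    else NULL
    cfg$mcmc$seed <- .stageSeed(cfg$seed, "varcomp")
    res$varcomp <- varianceReport(traitVec, qc, counts,
                                  biomarkers = biom, config = cfg$mcmc)
  }

  res$manifest <- manifest
  if (!is.null(outDir)) .writePipelineOutputs(res, outDir)
  res
}

.writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) write.table(df, file.path(outDir, name),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  if (!is.null(res$ruminotype)) {
    wtsv(data.frame(sample = names(res$ruminotype$labels),
                    cluster = paste0("R", res$ruminotype$labels)),
         "ruminotype_labels.tsv")
    wtsv(res$ruminotype$quality, "cluster_quality.tsv")
    wtsv(data.frame(cluster = paste0("R", seq_along(res$ruminotype$stability)),
                    jaccard = res$ruminotype$stability),
         "cluster_stability.tsv")
    wtsv(res$ruminotype$assoc$contrasts, "cluster_phenotype_contrasts.tsv")
  }
  if (!is.null(res$differential)) {
    wtsv(res$differential$zig, "differential_abundance.tsv")
    wtsv(res$differential$pa, "presence_absence.tsv")
  }
  if (!is.null(res$spls)) {
    wtsv(res$spls$biomarkers, "biomarkers.tsv")
    wtsv(data.frame(class = names(res$spls$auroc), auc = res$spls$auroc),
         "auroc.tsv")
  }
  if (!is.null(res$varcomp)) wtsv(res$varcomp, "variance_components.tsv")
  jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outDir)
}
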