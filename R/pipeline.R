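#' Pipeline configuration
#'
#' Assembles a validated configuration for \code{\link{runPipeline}}. All
#' thresholds default to the study's stated values: completeness strictly
#' above 0.80, family presence in at least 80\% of species, a maximum count of
#' at least 3 in some species, BH q < 0.05, 1000 enrichment resamples, GO
#' terms on at least 50 families (family level) or 200 genes (gene level).
#'
#' @param inputDir directory holding the input bundle (as written by
#'   \code{\link{simulateBundle}}); individual paths below override its
#'   defaults.
#' @param tree,counts,traits,completeness,annotations,membership,genelistsDir,expression
#'   input file paths.
#' @param outDir output directory.
#' @param completenessThreshold,presenceFraction,minMaxCount,alpha,nSamples,minTermFamilies,minTermGenes,seed
#'   analysis parameters.
#' @param ... named overrides applied last (the config analogue of a
#'   \code{--set key=value} switch).
#' @return a named list of class \code{pfsConfig}.
#' @export
pipelineConfig <- function(inputDir = NULL,
                           tree = NULL, counts = NULL, traits = NULL,
                           completeness = NULL, annotations = NULL,
                           membership = NULL, genelistsDir = NULL,
                           expression = NULL, outDir = "pfs_out",
                           completenessThreshold = 0.80,
                           presenceFraction = 0.80, minMaxCount = 3L,
                           alpha = 0.05, nSamples = 1000L,
                           minTermFamilies = 50L, minTermGenes = 200L,
                           seed = 1L, ...) {
  pth <- function(given, name) {
    if (!is.null(given)) given
    else if (!is.null(inputDir)) file.path(inputDir, name)
    else NULL
  }
  cfg <- list(
    tree = pth(tree, "tree.nwk"), counts = pth(counts, "counts.tsv"),
    traits = pth(traits, "traits.tsv"),
    completeness = pth(completeness, "completeness.tsv"),
    annotations = pth(annotations, "annotations.tsv"),
    membership = pth(membership, "membership.tsv"),
    genelistsDir = pth(genelistsDir, "genelists"),
    expression = pth(expression, "expression.tsv"),
    outDir = outDir,
    completenessThreshold = completenessThreshold,
    presenceFraction = presenceFraction, minMaxCount = minMaxCount,
    alpha = alpha, nSamples = nSamples, minTermFamilies = minTermFamilies,
    minTermGenes = minTermGenes, seed = seed)
  ov <- list(...)
  cfg[names(ov)] <- ov
  stopifnot(cfg$completenessThreshold > 0, cfg$completenessThreshold < 1,
            cfg$presenceFraction >= 0, cfg$presenceFraction <= 1,
            cfg$alpha > 0, cfg$alpha <= 1, cfg$nSamples >= 2)
  class(cfg) <- "pfsConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys are the arguments of \code{\link{pipelineConfig}} (snake_case keys
#' are accepted and converted).
#'
#' @param file YAML path.
#' @param ... overrides applied after the file.
#' @return a \code{pfsConfig}.
#' @export
readPipelineConfig <- function(file, ...) {
  y <- read_yaml(file)
  names(y) <- gsub("_(\\w)", "\\U\\1", names(y), perl = TRUE)
  do.call(pipelineConfig, c(y, list(...)))
}

#' Overlap of two scans' significant family sets
#'
#' Set algebra on the significant calls of two scan results (or two
#' predictors of one result) over the same family universe.
#'
#' @param scanA,scanB \linkS4class{ScanResult} objects.
#' @param predictorA,predictorB predictors to compare (defaults: first of
#'   each).
#' @param direction "any", "expanding" or "contracting".
#' @return list with counts \code{shared}, \code{a_only}, \code{b_only} and
#'   the corresponding family id vectors.
#' @export
summarizeOverlapOfScans <- function(scanA, scanB,
                                    predictorA = scanA@predictors[1L],
                                    predictorB = scanB@predictors[1L],
                                    direction = "any") {
  uniA <- unique(scanTable(scanA)$family_id)
  uniB <- unique(scanTable(scanB)$family_id)
  if (!setequal(uniA, uniB))
    stop("scans cover different family universes")
  a <- significantFamilies(scanA, predictorA, direction)
  b <- significantFamilies(scanB, predictorB, direction)
  list(shared = length(intersect(a, b)),
       a_only = length(setdiff(a, b)),
       b_only = length(setdiff(b, a)),
       shared_ids = sort(intersect(a, b)),
       a_only_ids = sort(setdiff(a, b)),
       b_only_ids = sort(setdiff(b, a)))
}

.stage <- function(name, report, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full comparative pipeline
#'
#' Executes, in order: completeness filtering; family filter cascade; trait
#' log10 transforms and allometric brain-size residuals; single-predictor
#' PGLS scans for log10 MLSP, log10 body mass, relative brain size, log10
#' gestation time and log10 age at sexual maturity; the two-predictor scan
#' (log10 MLSP + relative brain size); the total-gene-count control
#' regression; family-level resampling GO enrichment of the MLSP-expanding
#' families (two-predictor model); gene-level GO enrichment of their member
#' genes; chi-square overlaps against every curated gene list; leave-one-out
#' sensitivity analysis of the two-predictor scan; and the expression /
#' transcript-count comparison. All tabular outputs are written as TSV under
#' \code{config$outDir} together with a machine-readable \code{report.json};
#' the run is deterministic for fixed inputs and seed.
#'
#' @param config a \code{pfsConfig} from \code{\link{pipelineConfig}} (or a
#'   YAML path, read via \code{\link{readPipelineConfig}}).
#' @return invisibly, the report list (also written as JSON).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pfsConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), stages = list())
  t0 <- proc.time()[["elapsed"]]

  tree <- .stage("read_tree", report, readNewick(file = config$tree))
  counts <- .stage("read_counts", report, readCountMatrix(config$counts))
  traits <- .stage("read_traits", report, readTraitTable(config$traits))
  scores <- .stage("read_completeness", report,
                   readCompletenessTable(config$completeness))

  retained <- .stage("completeness_filter", report,
                     filterSpeciesByCompleteness(scores, config$completenessThreshold))
  retained <- intersect(retained, intersect(colnames(counts), tree$tip.label))
  report$stages$completeness <- list(n_scored = length(scores),
                                     n_retained = length(retained))

  countsR <- counts[, retained, drop = FALSE]
  filtered <- .stage("family_filters", report,
                     filterFamilies(countsR, config$presenceFraction,
                                    config$minMaxCount))
  report$stages$family_filters <- list(n_input = nrow(counts),
                                       n_retained = nrow(filtered))

  traits <- .stage("trait_prep", report,
                   relativeBrainSize(log10Traits(traits)))
  fce <- .stage("assemble", report, suppressWarnings(
    FamilyCountExperiment(filtered, traits, pruneTo(tree, retained))))

  singlePredictors <- c("log10_mlsp", "log10_body_mass", "relative_brain_size",
                        "log10_gestation_time", "log10_age_sexual_maturity")
  singlePredictors <- intersect(singlePredictors, names(colData(fce)))
  scans <- list()
  for (pr in singlePredictors) {
    scans[[pr]] <- .stage(paste0("scan_", pr), report, suppressWarnings(
      scanFamilies(fce, pr, alpha = config$alpha)))
    writeScanTsv(scans[[pr]], file.path(config$outDir,
                                        paste0("scan_", pr, ".tsv")))
  }
  report$stages$single_scans <- lapply(scans, function(s) {
    tab <- scanTable(s)
    list(n_families = length(unique(tab$family_id)), n_species = s@nSpecies,
         expanding = sum(tab$call == "expanding"),
         contracting = sum(tab$call == "contracting"))
  })

  twoScan <- .stage("scan_two_predictor", report, suppressWarnings(
    scanFamilies(fce, c("log10_mlsp", "relative_brain_size"),
                 alpha = config$alpha)))
  writeScanTsv(twoScan, file.path(config$outDir, "scan_two_predictor.tsv"))
  tt <- scanTable(twoScan)
  report$stages$two_predictor <- lapply(
    split(as.data.frame(tt), tt$predictor), function(d)
      list(expanding = sum(d$call == "expanding"),
           contracting = sum(d$call == "contracting")))

  ov <- summarizeOverlapOfScans(twoScan, twoScan, "log10_mlsp",
                                "relative_brain_size", "expanding")
  report$stages$scan_overlap <- ov[c("shared", "a_only", "b_only")]

  control <- .stage("total_count_control", report,
                    totalCountRegression(fce, "log10_mlsp"))
  report$stages$total_count_control <- list(
    beta = unname(control@coefficients[2L]), t = unname(control@t[2L]),
    p = unname(control@p[2L]))

  mlspFamilies <- significantFamilies(twoScan, "log10_mlsp", "expanding")
  membership <- read.delim(config$membership, stringsAsFactors = FALSE)
  membership <- membership[membership$family_id %in% rownames(fce), ]
  geneTerms <- .stage("read_annotations", report, readAnnotationMap(
    config$annotations, background = membership$gene_id, restrict = TRUE))
  famTerms <- .stage("lift_go", report,
                     liftGoToFamilies(geneTerms, membership))
  famTerms@background <- rownames(fce)

  enrFam <- if (length(mlspFamilies)) .stage("enrichment_families", report, {
    ft <- filterTerms(famTerms, config$minTermFamilies)
    samplingEnrichment(mlspFamilies, ft, nSamples = config$nSamples,
                       seed = config$seed)
  }) else NULL
  if (!is.null(enrFam))
    writeEnrichmentTsv(enrFam, file.path(config$outDir,
                                         "enrichment_families.tsv"))

  mlspGenes <- membership$gene_id[membership$family_id %in% mlspFamilies]
  enrGene <- if (length(mlspGenes)) .stage("enrichment_genes", report, {
    gt <- filterTerms(geneTerms, config$minTermGenes)
    if (length(gt@map))
      samplingEnrichment(mlspGenes, gt, nSamples = config$nSamples,
                         seed = config$seed + 1L)
    else NULL
  }) else NULL
  if (!is.null(enrGene))
    writeEnrichmentTsv(enrGene, file.path(config$outDir,
                                          "enrichment_genes.tsv"))
  report$stages$enrichment <- list(
    n_focal_families = length(mlspFamilies),
    family_terms_hit = if (is.null(enrFam)) 0L
                       else sum(enrichmentTable(enrFam)$q < config$alpha),
    gene_terms_hit = if (is.null(enrGene)) 0L
                     else sum(enrichmentTable(enrGene)$q < config$alpha))

  overlaps <- NULL
  if (!is.null(config$genelistsDir) && dir.exists(config$genelistsDir)) {
    files <- list.files(config$genelistsDir, pattern = "\\.txt$",
                        full.names = TRUE)
    studyBg <- membership$gene_id
    overlaps <- .stage("genelist_overlaps", report, do.call(rbind, lapply(
      files, function(f) {
        gl <- readGeneList(f)
        res <- chiSquareOverlap(gl, attr(gl, "background"),
                                intersect(mlspGenes, studyBg), studyBg)
        data.frame(list = sub("\\.txt$", "", basename(f)),
                   statistic = res$statistic, p = res$p,
                   direction = res$direction, log2_fold = res$log2_fold,
                   n_background = res$n_background,
                   unreliable = res$unreliable)
      })))
    .writeTsv(overlaps, file.path(config$outDir, "overlaps.tsv"))
    report$stages$overlaps <- list(
      n_lists = nrow(overlaps),
      significant = sum(overlaps$p < config$alpha))
  }

  if (length(mlspFamilies) >= 2L) {
    loo <- .stage("leave_one_out", report,
                  suppressMessages(looScan(fce, twoScan, alpha = config$alpha)))
    .writeTsv(as.data.frame(looTable(loo)), file.path(config$outDir, "loo.tsv"))
    report$stages$loo <- list(
      n_species = nrow(looTable(loo)),
      influential = as.character(
        looTable(loo)$species_dropped[looTable(loo)$influential]),
      max_abs_d = max(abs(looTable(loo)$cohens_d)))
  } else {
    message("[leave_one_out] skipped: fewer than 2 significant families")
    report$stages$loo <- list(n_species = 0L, influential = character(),
                              max_abs_d = NA_real_)
  }

  if (!is.null(config$expression) && file.exists(config$expression)) {
    expr <- read.delim(config$expression, stringsAsFactors = FALSE)
    cmp <- .stage("expression_comparison", report,
                  compareExpression(expr, intersect(mlspGenes, expr$gene_id)))
    .writeTsv(cmp, file.path(config$outDir, "expression_comparison.tsv"))
    report$stages$expression <- setNames(as.list(cmp$p), cmp$measure)
  }

  report$wallclock_seconds <- proc.time()[["elapsed"]] - t0
  write_json(report, file.path(config$outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(report)
}
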