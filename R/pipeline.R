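#' Pipeline configuration
#'
#' Assembles the thresholds and inputs of a full run.  Inputs may be given
#' as file paths (read with [readExpressionTable()] / [readTargetScan()])
#' or as in-memory objects; the default thresholds are the selection rules
#' of the method: component selection at t-test p < 0.05, outlier features
#' at BH-adjusted chi-squared p < 0.01, regulation calls at BH-adjusted
#' t-test p < 0.05, q-value significance at q < 0.01.
#'
#' @param mrna,mirna [ExpressionMatrix-class] objects or TSV paths.
#' @param mrnaLabels,mirnaLabels label vectors or two-column TSV paths
#'   (ignored when the matrices are in-memory objects).
#' @param targets a [TargetMap-class] or a conserved-target TSV path.
#' @param species taxon filter used when \code{targets} is a path.
#' @param alphaPC,outlierThreshold,regulationAlpha,qvalueThreshold the
#'   stage thresholds, all in (0,1).
#' @param L named list or vector with elements \code{mrna} and
#'   \code{mirna}: number of PC loadings per discriminant; \code{NULL}
#'   entries are chosen by the accuracy scan in [discriminate()].
#' @param unlog2Mrna,unlog2Mirna de-log the respective matrix before
#'   normalization (for profiles distributed on the log2 scale).
#' @param probeToGene optional named probe-to-gene map for the mRNA side.
#' @param seed RNG seed recorded with the run.
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(mrna, mirna, mrnaLabels = NULL,
                           mirnaLabels = NULL, targets,
                           species = "9606", alphaPC = 0.05,
                           outlierThreshold = 0.01, regulationAlpha = 0.05,
                           qvalueThreshold = 0.01,
                           L = list(mrna = NULL, mirna = NULL),
                           unlog2Mrna = FALSE, unlog2Mirna = FALSE,
                           probeToGene = NULL, seed = 1) {
  thr <- c(alphaPC, outlierThreshold, regulationAlpha, qvalueThreshold)
  if (any(thr <= 0 | thr >= 1))
    stop("all thresholds must lie in (0,1)")
  for (x in list(mrna, mirna, targets))
    if (is.character(x) && length(x) == 1 && !file.exists(x))
      stop("input path does not exist: ", x)
  structure(list(mrna = mrna, mirna = mirna, mrnaLabels = mrnaLabels,
                 mirnaLabels = mirnaLabels, targets = targets,
                 species = species, alphaPC = alphaPC,
                 outlierThreshold = outlierThreshold,
                 regulationAlpha = regulationAlpha,
                 qvalueThreshold = qvalueThreshold, L = as.list(L),
                 unlog2Mrna = unlog2Mrna, unlog2Mirna = unlog2Mirna,
                 probeToGene = probeToGene, seed = as.integer(seed)),
            class = "pipelineConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full miRNA-mRNA interaction pipeline
#'
#' Executes ingestion and normalization, PCA-based unsupervised feature
#' extraction on each matrix, regulation calls and reciprocal-pair
#' intersection with the conserved target map, leave-one-out LDA
#' discrimination per matrix with Fisher scoring, and the q-value
#' cross-check — writing every stage table, a machine-readable summary and
#' a log into \code{outDir}.  A stage failure aborts with the stage name;
#' tables already written are retained.
#'
#' @param cfg a [pipelineConfig()] list.
#' @param outDir run directory (created; reused if present).
#' @return invisibly, a list with all stage results and the summary.
#' @export
runPipeline <- function(cfg, outDir) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log_path <- file.path(outDir, "log.txt")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pcaUFE %s | R %s | seed %d",
       as.character(utils::packageVersion("pcaUFE")),
       paste(R.version$major, R.version$minor, sep = "."), cfg$seed)
  logf("thresholds: alphaPC=%g outlier=%g regulation=%g qvalue=%g",
       cfg$alphaPC, cfg$outlierThreshold, cfg$regulationAlpha,
       cfg$qvalueThreshold)

  load_matrix <- function(x, labels, delog, what) {
    m <- if (methods::is(x, "ExpressionMatrix")) x
         else readExpressionTable(x, labels)
    if (delog) m <- unlog2(m)
    m <- normalizeSamples(m)
    logf("%s: %d features x %d samples%s", what, nrow(m), ncol(m),
         if (delog) " (de-logged)" else "")
    m
  }
  mrna <- stage("data_io", load_matrix(cfg$mrna, cfg$mrnaLabels,
                                       cfg$unlog2Mrna, "mRNA"))
  mirna <- stage("data_io", load_matrix(cfg$mirna, cfg$mirnaLabels,
                                        cfg$unlog2Mirna, "miRNA"))
  targets <- stage("data_io",
    if (methods::is(cfg$targets, "TargetMap")) cfg$targets
    else readTargetScan(cfg$targets, species = cfg$species,
                        mirnaToFamily = stats::setNames(rownames(mirna),
                                                        rownames(mirna))))

  fe <- stage("pca_fe", lapply(
    list(mrna = mrna, mirna = mirna), function(m) {
      res <- selectFeatures(m, alphaPC = cfg$alphaPC,
                            threshold = cfg$outlierThreshold)
      res
    }))
  for (side in names(fe)) {
    writeFeatureReport(fe[[side]],
                       file.path(outDir, paste0("features_", side, ".tsv")))
    logf("pca_fe %s: df=%d, %d selected", side, fe[[side]]@nOmega,
         sum(fe[[side]]@selected))
  }

  calls <- stage("regulation_pairs", list(
    mrna = callRegulation(mrna, selectedFeatures(fe$mrna),
                          alpha = cfg$regulationAlpha),
    mirna = callRegulation(mirna, selectedFeatures(fe$mirna),
                           alpha = cfg$regulationAlpha)))
  pairs <- stage("regulation_pairs",
    findReciprocalPairs(calls$mirna, calls$mrna, targets,
                        probeToGene = cfg$probeToGene))
  utils::write.table(pairs, file.path(outDir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("regulation_pairs: %d mRNA calls, %d miRNA calls, %d pairs",
       nrow(calls$mrna), nrow(calls$mirna), nrow(pairs))

  mats <- list(mrna = mrna, mirna = mirna)
  disc <- stage("discrimination", stats::setNames(lapply(
    names(mats), function(side)
      discriminate(mats[[side]], selectedFeatures(fe[[side]]),
                   L = cfg$L[[side]])), names(mats)))
  disc_tab <- do.call(rbind, lapply(names(disc), function(side) {
    r <- disc[[side]]
    data.frame(matrix_ = side, L = r@L,
               tp = r@confusion[1, 1], fp = r@confusion[1, 2],
               fn = r@confusion[2, 1], tn = r@confusion[2, 2],
               p_value = r@pValue, odds_ratio = r@oddsRatio)
  }))
  utils::write.table(disc_tab, file.path(outDir, "discrimination.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  qv <- stage("fdr_qvalue", lapply(fe, function(res)
    computeQvalues(rawP(res), threshold = cfg$qvalueThreshold)))
  for (side in names(qv))
    utils::write.table(
      data.frame(feature_id = names(rawP(fe[[side]])),
                 p = rawP(fe[[side]]), q = qValues(qv[[side]]),
                 significant = qv[[side]]@significant),
      file.path(outDir, paste0("qvalues_", side, ".tsv")), sep = "\t",
      quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = cfg$seed,
    n_selected = lapply(fe, function(x) sum(x@selected)),
    n_omega = lapply(fe, function(x) x@nOmega),
    n_calls = lapply(calls, nrow),
    n_pairs = nrow(pairs),
    discrimination = lapply(disc, function(r)
      list(L = r@L, confusion = as.vector(r@confusion),
           p_value = r@pValue, odds_ratio = r@oddsRatio)),
    n_qvalue_significant = lapply(qv, function(x) sum(x@significant)))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done: %d pairs", nrow(pairs))
  invisible(list(mrna = mrna, mirna = mirna, targets = targets, fe = fe,
                 calls = calls, pairs = pairs, discrimination = disc,
                 qvalues = qv, summary = summary))
}
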