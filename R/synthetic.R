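#' Synthetic study configuration
#'
#' Constructor for [SyntheticConfig-class] with the default study
#' conditions: 2000 mRNAs and 300 miRNAs measured on 20 case and 20
#' control samples each, 50 planted outlier mRNAs and 10 planted outlier
#' miRNAs shifted by 2 pre-normalization units between classes over unit
#' Gaussian noise, 20 conserved targets per miRNA family of which 80% of a
#' planted miRNA's targets are planted opposite-direction mRNAs.
#'
#' @param nMrna,nMirna feature counts.
#' @param nCase,nControl mRNA cohort sizes.
#' @param nCaseMirna,nControlMirna miRNA cohort sizes (default: same as the
#'   mRNA cohort; the two cohorts are unmatched and may differ).
#' @param nOutlierMrna,nOutlierMirna planted outlier counts.
#' @param effect class shift in pre-normalization units.
#' @param noiseSd Gaussian noise standard deviation.
#' @param targetsPerMirna conserved-target out-degree per miRNA family.
#' @param reciprocalFraction fraction of each planted miRNA's targets drawn
#'   from planted opposite-direction mRNAs.
#' @param seed RNG seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nMrna = 2000, nMirna = 300,
                            nCase = 20, nControl = 20,
                            nCaseMirna = nCase, nControlMirna = nControl,
                            nOutlierMrna = 50, nOutlierMirna = 10,
                            effect = 2, noiseSd = 1,
                            targetsPerMirna = 20,
                            reciprocalFraction = 0.8, seed = 1) {
  methods::new("SyntheticConfig",
    nMrna = as.integer(nMrna), nMirna = as.integer(nMirna),
    nCase = as.integer(nCase), nControl = as.integer(nControl),
    nCaseMirna = as.integer(nCaseMirna),
    nControlMirna = as.integer(nControlMirna),
    nOutlierMrna = as.integer(nOutlierMrna),
    nOutlierMirna = as.integer(nOutlierMirna),
    effect = as.numeric(effect), noiseSd = as.numeric(noiseSd),
    targetsPerMirna = as.integer(targetsPerMirna),
    reciprocalFraction = as.numeric(reciprocalFraction),
    seed = as.integer(seed))
}

#' Generate paired synthetic mRNA/miRNA matrices with planted structure
#'
#' Emulates the data model of an unmatched two-cohort case/control study:
#' baseline expression is i.i.d. Gaussian(0, noiseSd); planted outlier
#' features receive a class shift of +/- \code{effect} in the case samples
#' (directions alternate so both regulation directions occur); and the
#' conserved target map contains, for each planted miRNA, a fraction of
#' targets drawn from planted mRNAs of the opposite direction (the planted
#' reciprocal pairs, recorded as ground truth) with the remainder, and all
#' targets of non-planted miRNAs, drawn as decoys from non-planted mRNAs.
#' Matrices are returned standardized with [normalizeSamples()].  The same
#' seed reproduces the output exactly.
#'
#' @param cfg a [SyntheticConfig-class], e.g. from [syntheticConfig()].
#' @return list with elements \code{mrna} and \code{mirna}
#'   ([ExpressionMatrix-class]), \code{targets} ([TargetMap-class]), and
#'   \code{truth}: a list with data.frames \code{outlierMrna},
#'   \code{outlierMirna} (id, direction) and \code{truePairs}
#'   (mirna_id, gene_id).
#' @export
generateSynthetic <- function(cfg = syntheticConfig()) {
  stopifnot(methods::is(cfg, "SyntheticConfig"))
  methods::validObject(cfg)
  set.seed(cfg@seed)
  gene_ids <- sprintf("GENE%05d", seq_len(cfg@nMrna))
  mir_ids <- sprintf("hsa-miR-%d", seq_len(cfg@nMirna))

  plant <- function(n_feat, ids, n_case, n_ctrl, n_out, prefix) {
    x <- matrix(stats::rnorm(n_feat * (n_case + n_ctrl), sd = cfg@noiseSd),
                n_feat, n_case + n_ctrl,
                dimnames = list(ids, sprintf("%s%03d", prefix,
                                             seq_len(n_case + n_ctrl))))
    labels <- rep(c("case", "control"), c(n_case, n_ctrl))
    idx <- sort(sample.int(n_feat, n_out))
    dirs <- rep(c("up", "down"), length.out = n_out)
    if (n_out > 1) dirs <- sample(dirs)
    shift <- ifelse(dirs == "up", cfg@effect, -cfg@effect)
    x[idx, labels == "case"] <- x[idx, labels == "case"] + shift
    list(m = ExpressionMatrix(x, labels),
         truth = data.frame(id = ids[idx], direction = dirs))
  }
  mr <- plant(cfg@nMrna, gene_ids, cfg@nCase, cfg@nControl,
              cfg@nOutlierMrna, "MR")
  mi <- plant(cfg@nMirna, mir_ids, cfg@nCaseMirna, cfg@nControlMirna,
              cfg@nOutlierMirna, "MI")

  decoy_pool <- setdiff(gene_ids, mr$truth$id)
  n_true <- round(cfg@reciprocalFraction * cfg@targetsPerMirna)
  fam_keys <- normalizeMirnaName(mir_ids)
  f2g <- vector("list", cfg@nMirna)
  names(f2g) <- fam_keys
  pairs <- list()
  for (i in seq_len(cfg@nMirna)) {
    planted_i <- match(mir_ids[i], mi$truth$id)
    tg <- character()
    if (!is.na(planted_i) && n_true > 0) {
      opp <- mr$truth$id[mr$truth$direction != mi$truth$direction[planted_i]]
      tg <- sample(opp, min(n_true, length(opp)))
      if (length(tg))
        pairs[[length(pairs) + 1L]] <-
          data.frame(mirna_id = mir_ids[i], gene_id = tg)
    }
    n_decoy <- cfg@targetsPerMirna - length(tg)
    if (n_decoy > 0 && length(decoy_pool))
      tg <- c(tg, sample(decoy_pool, min(n_decoy, length(decoy_pool))))
    f2g[[i]] <- sort(unique(toupper(tg)))
  }
  f2g <- f2g[lengths(f2g) > 0]
  targets <- methods::new("TargetMap", familyToGenes = f2g,
                          mirnaToFamily = stats::setNames(fam_keys, fam_keys),
                          species = "synthetic")
  true_pairs <- if (length(pairs)) {
    tp <- do.call(rbind, pairs)
    tp <- tp[order(tp$mirna_id, tp$gene_id), , drop = FALSE]
    rownames(tp) <- NULL
    tp
  } else data.frame(mirna_id = character(), gene_id = character())

  list(mrna = normalizeSamples(mr$m), mirna = normalizeSamples(mi$m),
       targets = targets,
       truth = list(outlierMrna = mr$truth, outlierMirna = mi$truth,
                    truePairs = true_pairs))
}

#' Write a synthetic dataset to disk
#'
#' Writes the matrices and label files in the TSV layout consumed by
#' [readExpressionTable()], the target map as a conserved-family-info
#' style TSV for [readTargetScan()], and the ground truth as JSON.
#'
#' @param sim output of [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSynthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionTable(sim$mrna, file.path(dir, "mrna.tsv"),
                       file.path(dir, "mrna_labels.tsv"))
  writeExpressionTable(sim$mirna, file.path(dir, "mirna.tsv"),
                       file.path(dir, "mirna_labels.tsv"))
  f2g <- sim$targets@familyToGenes
  utils::write.table(
    data.frame(`miR family` = rep(names(f2g), lengths(f2g)),
               `Gene Symbol` = unlist(f2g, use.names = FALSE),
               `Species ID` = "9606", check.names = FALSE),
    file.path(dir, "targets.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns")
  invisible(dir)
}
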