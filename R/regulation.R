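#' Call up/down regulation for selected features
#'
#' Welch t test per selected feature between case and control samples, with
#' Benjamini-Hochberg adjustment computed over the selected set only (the
#' outlier features are the hypotheses of interest; correcting over all
#' features instead is available via \code{universe = "all"}).  Calls with
#' adjusted p below \code{alpha} are retained; the direction is the sign of
#' the case-minus-control mean difference, and the measure-zero case of an
#' exactly zero difference is excluded.
#'
#' @param m a normalized [ExpressionMatrix-class].
#' @param selected character vector of feature identifiers to test (e.g.
#'   \code{selectedFeatures(selectFeatures(m))}).
#' @param alpha adjusted-p cutoff, default 0.05.
#' @param universe BH universe: the selected set (default) or all features.
#' @return data.frame with columns feature_id, direction ("up"/"down"),
#'   raw_p, adjusted_p, mean_case, mean_control; zero rows if nothing is
#'   significant.
#' @export
callRegulation <- function(m, selected, alpha = 0.05,
                           universe = c("selected", "all")) {
  universe <- match.arg(universe)
  empty <- data.frame(feature_id = character(), direction = character(),
                      raw_p = numeric(), adjusted_p = numeric(),
                      mean_case = numeric(), mean_control = numeric())
  if (length(selected) == 0) {
    warning("empty selected set: no regulation calls")
    return(empty)
  }
  missing <- setdiff(selected, rownames(m))
  if (length(missing))
    stop("selected features absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  test_set <- if (universe == "all") rownames(m) else selected
  x <- exprsValues(m)[test_set, , drop = FALSE]
  case <- classLabels(m) == "case"
  if (sum(case) < 2 || sum(!case) < 2)
    stop("both classes need at least 2 samples")
  p <- vapply(seq_len(nrow(x)), function(i)
    stats::t.test(x[i, case], x[i, !case])$p.value, numeric(1))
  adj <- bhAdjust(p)
  mc <- rowMeans(x[, case, drop = FALSE])
  mn <- rowMeans(x[, !case, drop = FALSE])
  out <- data.frame(feature_id = test_set,
                    direction = ifelse(mc > mn, "up", "down"),
                    raw_p = p, adjusted_p = adj,
                    mean_case = mc, mean_control = mn,
                    row.names = NULL)
  out <- out[out$feature_id %in% selected & out$adjusted_p < alpha &
               out$mean_case != out$mean_control, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) return(empty)
  out
}

#' Read a conserved miRNA-family target table
#'
#' Parses a conserved-family-info style TSV with (at least) a miRNA family
#' column, a target gene symbol column and a species/taxon column, filters
#' to the requested taxon, and builds the family-to-target-set map with
#' set semantics (duplicate rows collapse).  Family keys are normalized
#' with [normalizeMirnaName()].
#'
#' @param path TSV path (plain or gzipped).
#' @param species taxon identifier to keep, default \code{"9606"} (human).
#' @param mirnaToFamily optional named character vector mapping mature
#'   miRNA names to family names (both sides are normalized).
#' @return a [TargetMap-class].
#' @export
readTargetScan <- function(path, species = "9606", mirnaToFamily = character()) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  pick <- function(cands, what) {
    hit <- which(tolower(gsub("[. _]", "", names(tab))) %in% cands)
    if (!length(hit))
      stop("missing required column for ", what, " (looked for: ",
           paste(cands, collapse = ", "), ")")
    hit[1]
  }
  fam_c <- pick(c("mirfamily", "family", "mirnafamily"), "miRNA family")
  gene_c <- pick(c("genesymbol", "gene", "symbol"), "gene symbol")
  sp_c <- pick(c("speciesid", "species", "taxon", "taxonid"), "species")
  tab <- tab[tab[[sp_c]] == as.character(species), , drop = FALSE]
  fam <- normalizeMirnaName(tab[[fam_c]])
  gene <- toupper(trimws(tab[[gene_c]]))
  keep <- nzchar(fam) & nzchar(gene)
  f2g <- lapply(split(gene[keep], fam[keep]), function(g) sort(unique(g)))
  f2g <- f2g[lengths(f2g) > 0]
  m2f <- character()
  if (length(mirnaToFamily))
    m2f <- stats::setNames(normalizeMirnaName(unname(mirnaToFamily)),
                           normalizeMirnaName(names(mirnaToFamily)))
  methods::new("TargetMap", familyToGenes = f2g, mirnaToFamily = m2f,
               species = as.character(species))
}

#' Normalize a miRNA name to a family lookup key
#'
#' Strips the three-letter species prefix (e.g. \code{"hsa-"}), folds case,
#' and keeps the arm suffix (-3p/-5p), so that mature names and family
#' strings meet on a common key.
#'
#' @param name character vector of miRNA or family names.
#' @return character vector of lookup keys.
#' @examples
#' normalizeMirnaName("hsa-miR-30a")      # "mir-30a"
#' normalizeMirnaName("hsa-miR-143-3p")   # "mir-143-3p"
#' @export
normalizeMirnaName <- function(name) {
  key <- tolower(trimws(as.character(name)))
  sub("^[a-z]{3}-(?=(mir|let|lin))", "", key, perl = TRUE)
}

#' Reciprocally regulated miRNA-mRNA pairs
#'
#' Emits every (miRNA, gene) combination in which the gene belongs to the
#' conserved target set of the miRNA's family and the two regulation calls
#' have opposite directions (miRNA up with target down, or miRNA down with
#' target up).  miRNA identifiers are resolved to families by exact mature
#' name first, then by family-string match; unresolved names are excluded
#' with a message.  Output is deduplicated and sorted by (mirna_id,
#' gene_id).
#'
#' @param mirnaCalls,mrnaCalls regulation-call data.frames from
#'   [callRegulation()].
#' @param targets a [TargetMap-class].
#' @param probeToGene optional named character vector mapping mRNA feature
#'   identifiers to gene symbols; by default identifiers are used as
#'   symbols directly.
#' @return data.frame with columns mirna_id, gene_id, mirna_direction,
#'   gene_direction, family.
#' @export
findReciprocalPairs <- function(mirnaCalls, mrnaCalls, targets,
                                probeToGene = NULL) {
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      mirna_direction = character(),
                      gene_direction = character(), family = character())
  if (nrow(mirnaCalls) == 0 || nrow(mrnaCalls) == 0) return(empty)
  genes <- if (is.null(probeToGene)) {
    stats::setNames(mrnaCalls$feature_id, mrnaCalls$feature_id)
  } else {
    stats::setNames(probeToGene[mrnaCalls$feature_id], mrnaCalls$feature_id)
  }
  gene_dir <- stats::setNames(mrnaCalls$direction, toupper(genes))
  unresolved <- 0L
  rows <- vector("list", nrow(mirnaCalls))
  for (i in seq_len(nrow(mirnaCalls))) {
    key <- normalizeMirnaName(mirnaCalls$feature_id[i])
    fam <- if (key %in% names(targets@mirnaToFamily)) {
      targets@mirnaToFamily[[key]]
    } else if (key %in% names(targets@familyToGenes)) {
      key
    } else NA_character_
    if (is.na(fam) || !fam %in% names(targets@familyToGenes)) {
      unresolved <- unresolved + 1L
      next
    }
    tg <- intersect(targets@familyToGenes[[fam]], names(gene_dir))
    tg <- tg[gene_dir[tg] != mirnaCalls$direction[i]]
    if (length(tg))
      rows[[i]] <- data.frame(mirna_id = mirnaCalls$feature_id[i],
                              gene_id = tg,
                              mirna_direction = mirnaCalls$direction[i],
                              gene_direction = unname(gene_dir[tg]),
                              family = fam)
  }
  if (unresolved)
    message(unresolved, " miRNA name(s) could not be resolved to a family")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- unique(out)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
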