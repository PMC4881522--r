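test_that("regulation calls carry the planted direction and drop nulls", {
  set.seed(51)
  x <- matrix(rnorm(100 * 40), 100,
              dimnames = list(sprintf("f%03d", 1:100), sprintf("s%02d", 1:40)))
  x[1, 1:20] <- x[1, 1:20] + 3    # planted up in cases
  x[2, 1:20] <- x[2, 1:20] - 3    # planted down
  em <- ExpressionMatrix(x, rep(c("case", "control"), each = 20))
  calls <- callRegulation(em, c("f001", "f002", "f003"))
  expect_setequal(calls$feature_id, c("f001", "f002"))
  expect_identical(calls$direction[calls$feature_id == "f001"], "up")
  expect_identical(calls$direction[calls$feature_id == "f002"], "down")
  expect_true(all(calls$adjusted_p < 0.05))
  expect_warning(empty <- callRegulation(em, character()), "empty selected")
  expect_identical(nrow(empty), 0L)
})

test_that("BH universe is the selected set: outside features change nothing", {
  em <- rand_em(200, 10, 10, seed = 53)
  sel <- sprintf("f%04d", 1:30)
  full <- callRegulation(em, sel)
  small <- callRegulation(em[1:30, ], sel)
  expect_equal(full, small)
})

test_that("strong planted shifts are recovered with correct signs", {
  ok <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 200
    x <- matrix(rnorm(n * 40), n, dimnames = list(sprintf("f%03d", 1:n),
                                                  sprintf("s%02d", 1:40)))
    dirs <- rep(c(1, -1), 25)
    x[1:50, 1:20] <- x[1:50, 1:20] + 3 * dirs
    em <- ExpressionMatrix(x, rep(c("case", "control"), each = 20))
    calls <- callRegulation(em, sprintf("f%03d", 1:50))
    want <- ifelse(dirs > 0, "up", "down")
    got <- calls$direction[match(sprintf("f%03d", 1:50), calls$feature_id)]
    identical(got, want)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("conserved target tables filter by species with set semantics", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "targets.tsv")
  writeLines(c("miR family\tGene Symbol\tSpecies ID",
               "miR-30-5p\tBCL11A\t9606",
               "miR-30-5p\tSOX4\t9606",
               "miR-30-5p\tSox4\t10090",
               "miR-30-5p\tBCL11A\t9606"), path)
  tm <- readTargetScan(path, species = "9606")
  expect_identical(names(tm@familyToGenes), "mir-30-5p")
  expect_identical(tm@familyToGenes[["mir-30-5p"]], c("BCL11A", "SOX4"))
  bad <- file.path(tmp, "bad.tsv")
  writeLines(c("miR family\tSpecies ID", "miR-1\t9606"), bad)
  expect_error(readTargetScan(bad), "gene symbol")
})

test_that("per-family target counts match independent line counts", {
  set.seed(57)
  fams <- sprintf("miR-%d", 1:15)
  rows <- data.frame(fam = sample(fams, 400, replace = TRUE),
                     gene = sprintf("G%03d", sample(120, 400, replace = TRUE)),
                     sp = sample(c("9606", "10090"), 400, replace = TRUE,
                                 prob = c(.8, .2)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miR family\tGene Symbol\tSpecies ID",
               sprintf("%s\t%s\t%s", rows$fam, rows$gene, rows$sp)), tmp)
  tm <- readTargetScan(tmp, species = "9606")
  human <- unique(rows[rows$sp == "9606", c("fam", "gene")])
  want <- table(tolower(human$fam))
  got <- lengths(tm@familyToGenes)
  expect_equal(unname(got[names(want)]), as.vector(want))
})

test_that("miRNA names normalize to family keys with arm preserved", {
  expect_identical(normalizeMirnaName("hsa-miR-30a"), "mir-30a")
  expect_identical(normalizeMirnaName("hsa-miR-143-3p"), "mir-143-3p")
  expect_identical(normalizeMirnaName("mmu-let-7a-5p"), "let-7a-5p")
  # a fixture of names with hand-assigned families resolves completely
  names20 <- c(sprintf("hsa-miR-%d", 1:10), sprintf("hsa-miR-%d-5p", 11:15),
               sprintf("hsa-let-7%s", letters[1:5]))
  want <- c(sprintf("mir-%d", 1:10), sprintf("mir-%d-5p", 11:15),
            sprintf("let-7%s", letters[1:5]))
  expect_identical(normalizeMirnaName(names20), want)
})

test_that("reciprocal pairs require both target membership and opposition", {
  tm <- new("TargetMap",
            familyToGenes = list("mir-1" = c("GENEA", "GENEB"),
                                 "mir-2" = "GENEA"),
            mirnaToFamily = c("mir-1" = "mir-1", "mir-2" = "mir-2"),
            species = "9606")
  mir <- data.frame(feature_id = c("hsa-miR-1", "hsa-miR-2"),
                    direction = c("up", "down"))
  mr <- data.frame(feature_id = c("GENEA", "GENEB"),
                   direction = c("down", "up"))
  pairs <- findReciprocalPairs(mir, mr, tm)
  # miR-1 up / GENEA down -> pair; miR-1 up / GENEB up -> no pair;
  # miR-2 down / GENEA down -> no pair
  expect_identical(pairs$mirna_id, "hsa-miR-1")
  expect_identical(pairs$gene_id, "GENEA")
  expect_true(all(pairs$mirna_direction != pairs$gene_direction))
})

test_that("pair discovery equals a brute-force cross-product oracle", {
  set.seed(59)
  genes <- sprintf("G%03d", 1:200)
  mirs <- sprintf("hsa-miR-%d", 1:30)
  fams <- normalizeMirnaName(mirs)
  f2g <- setNames(lapply(seq_along(mirs), function(i)
    sort(sample(genes, sample(5:30, 1)))), fams)
  tm <- new("TargetMap", familyToGenes = f2g,
            mirnaToFamily = setNames(fams, fams), species = "9606")
  mir_calls <- data.frame(feature_id = sample(mirs, 12),
                          direction = sample(c("up", "down"), 12, TRUE))
  mr_calls <- data.frame(feature_id = sample(genes, 80),
                         direction = sample(c("up", "down"), 80, TRUE))
  got <- findReciprocalPairs(mir_calls, mr_calls, tm)
  # naive double loop over all combinations
  want <- list()
  for (i in seq_len(nrow(mir_calls))) for (j in seq_len(nrow(mr_calls))) {
    fam <- normalizeMirnaName(mir_calls$feature_id[i])
    if (mr_calls$feature_id[j] %in% f2g[[fam]] &&
        mir_calls$direction[i] != mr_calls$direction[j])
      want[[length(want) + 1]] <- paste(mir_calls$feature_id[i],
                                        mr_calls$feature_id[j])
  }
  expect_setequal(pair_key(got), unlist(want))
  expect_lte(nrow(got), nrow(mir_calls) * nrow(mr_calls))
  # every emitted pair satisfies membership and reciprocity exhaustively
  for (r in seq_len(nrow(got))) {
    expect_true(got$gene_id[r] %in% f2g[[got$family[r]]])
    expect_true(got$mirna_direction[r] != got$gene_direction[r])
  }
})
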