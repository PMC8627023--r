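test_that("the queried base count follows the closed form for every kind", {
  set.seed(7)
  for (i in 1:25) {
    nW <- sample(0:4, 1)
    len <- sample(seq(3L, 30L, 3L), 1)
    start <- sample(50:500, 1)
    del <- MicroindelCatalog(chrom = "chr1", start = start,
                             kind = "deletion", indelLength = len)
    ins <- MicroindelCatalog(chrom = "chr1", start = start,
                             kind = "insertion", indelLength = len)
    mex <- MicroexonCatalog(chrom = "chr1", start = start,
                            end = start + len)
    expect_length(conservationPositions(del, nW)[[1]], len + 2 * nW)
    expect_length(conservationPositions(ins, nW)[[1]], 2 + 2 * nW)
    expect_length(conservationPositions(mex, nW)[[1]], len + 2 * nW)
  }
  # windows overhanging the chromosome origin are truncated, not padded
  nearEdge <- MicroindelCatalog(chrom = "chr1", start = 1,
                                kind = "deletion", indelLength = 3L)
  expect_identical(conservationPositions(nearEdge, 2)[[1]], 0:5)
})

test_that("insertion windows cover the two flanking bases plus the flank", {
  ins <- MicroindelCatalog(chrom = "chr1", start = 200, kind = "insertion",
                           indelLength = 6L)
  expect_identical(conservationPositions(ins, 2)[[1]], 197:202)
})

test_that("a constant track aggregates to a constant triple", {
  mex <- MicroexonCatalog(chrom = "chr1", start = 100, end = 109)
  w <- conservationWindow(mex, constantProvider(0.7))
  expect_equal(unlist(w), c(cons_max = 0.7, cons_min = 0.7, cons_mean = 0.7))
})

test_that("window aggregation equals brute-force recomputation on a track", {
  set.seed(13)
  prov <- hashProvider()
  for (i in 1:50) {
    len <- sample(seq(3L, 30L, 3L), 1)
    start <- sample(20:4000, 1)
    kind <- sample(c("deletion", "insertion", "exon"), 1)
    cat <- if (kind == "exon")
      MicroexonCatalog(chrom = "chrS1", start = start, end = start + len)
    else
      MicroindelCatalog(chrom = "chrS1", start = start, kind = kind,
                        indelLength = len)
    got <- conservationWindow(cat, prov, 2)
    pos <- conservationPositions(cat, 2)[[1]]
    v <- prov("chrS1", pos)
    expect_equal(unname(unlist(got)), c(max(v), min(v), mean(v)))
  }
})

test_that("all-missing windows propagate NA instead of failing", {
  mex <- MicroexonCatalog(chrom = "chrUn", start = 100, end = 109)
  none <- function(chrom, positions) rep(NA_real_, length(positions))
  expect_true(all(is.na(unlist(conservationWindow(mex, none)))))
})

test_that("residue windows add flanks and truncate at protein boundaries", {
  expect_identical(residueWindow(10, 12, 100), 8:14)
  expect_identical(residueWindow(1, 3, 100), 1:5)          # left truncation
  expect_identical(residueWindow(99, 100, 100), 97:100)    # right truncation
  expect_identical(residueWindow(10, 9, 100), 7:12)        # insertion point
  expect_error(residueWindow(90, 120, 100), "outside protein")
})

test_that("feature vectors carry 25 canonical fields with exact aggregates", {
  residues <- data.frame(
    proteinId = "p1", idx = 1:20,
    probC = rep(0.5, 20), probH = c(rep(0.3, 7), 0.1, 0.2, 0.9, 0.8, 0.1,
                                    rep(0.3, 8)),
    probE = rep(0.2, 20),
    disorder = seq(0, 0.95, length.out = 20),
    asa = seq(5, 100, length.out = 20))
  # 9-nt exon -> residues 10..12; window with flank 2 is residues 8..14
  mex <- MicroexonCatalog(chrom = "chr1", start = 100, end = 109,
                          proteinId = "p1", proteinLength = 20L,
                          residueStart = 10L, residueEnd = 12L)
  fv <- extractFeatures(mex, constantProvider(1), residues)
  expect_identical(colnames(fv), microFeatureNames())
  expect_identical(ncol(fv), 25L)
  winH <- residues$probH[8:14]
  expect_equal(unname(fv[1, c("ss_prob_max_H", "ss_prob_min_H",
                              "ss_prob_mean_H")]),
               c(max(winH), min(winH), mean(winH)))
  # probC = 0.5 beats probH and probE at residues 8,9,13,14 and 12;
  # argmax is H at 10 (0.9) and 11 (0.8)
  expect_equal(unname(fv[1, c("ss_pred_frac_C", "ss_pred_frac_H",
                              "ss_pred_frac_E")]),
               c(5 / 7, 2 / 7, 0))
  expect_equal(unname(fv[1, "record_length"]), 9)
  expect_equal(unname(fv[1, "protein_length"]), 20)
  expect_equal(unname(fv[1, "dist_to_start"]), 9)   # 0-based first residue
  expect_equal(unname(fv[1, "dist_to_end"]), 8)     # residues past the last
})

test_that("extractor equals an independent recomputation on synthetic tracks", {
  trk <- generateTracks(seed = 5, nExons = 10, nIndels = 10)
  prov <- trackProvider(trk$conservation)
  for (cat in list(trk$microexons, trk$microindels)) {
    fv <- extractFeatures(cat, prov, trk$residues)
    expect_false(any(is.na(fv)))
    mc <- mcols(cat)
    for (i in seq_along(cat)) {
      pos <- conservationPositions(cat[i], 2)[[1]]
      v <- prov(as.character(seqnames(cat[i])), pos)
      expect_equal(unname(fv[i, c("cons_max", "cons_min", "cons_mean")]),
                   c(max(v), min(v), mean(v)))
      ann <- trk$residues[trk$residues$proteinId == mc$proteinId[i], ]
      win <- ann[ann$idx %in% residueWindow(mc$residueStart[i],
                                            mc$residueEnd[i],
                                            mc$proteinLength[i]), ]
      cls <- c("C", "H", "E")[apply(win[, c("probC", "probH", "probE")],
                                    1, which.max)]
      expect_equal(unname(fv[i, c("dis_max", "dis_min", "dis_mean")]),
                   c(max(win$disorder), min(win$disorder),
                     mean(win$disorder)))
      expect_equal(unname(fv[i, c("asa_max", "asa_min", "asa_mean")]),
                   c(max(win$asa), min(win$asa), mean(win$asa)))
      expect_equal(unname(fv[i, "ss_pred_frac_H"]), mean(cls == "H"))
    }
    # aggregation sanity: min <= mean <= max on every triple
    for (stem in c("cons", "dis", "asa"))
      expect_true(all(fv[, paste0(stem, "_min")] <=
                        fv[, paste0(stem, "_mean")] &
                      fv[, paste0(stem, "_mean")] <=
                        fv[, paste0(stem, "_max")]))
    expect_equal(unname(rowSums(fv[, c("ss_pred_frac_C", "ss_pred_frac_H",
                                       "ss_pred_frac_E")])),
                 rep(1, nrow(fv)))
  }
})

test_that("feature tables round-trip and reject a wrong layout", {
  trk <- generateTracks(seed = 3, nExons = 6, nIndels = 6)
  fv <- extractFeatures(trk$microexons, trackProvider(trk$conservation),
                        trk$residues)
  fv[2, "cons_mean"] <- NA   # sentinel round trip
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(fv, path, labels = rep(c(0L, 1L), 3))
  back <- readFeatureTable(path, domain = "target")
  expect_s4_class(back, "DomainDataset")
  expect_equal(featureMatrix(back), fv, ignore_attr = TRUE)
  expect_identical(domainLabels(back), rep(c(0L, 1L), 3))

  bad <- utils::read.delim(path, check.names = FALSE)
  bad$cons_max <- NULL
  badPath <- tempfile(fileext = ".tsv")
  write.table(bad, badPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFeatureTable(badPath), "expected 25")
  expect_error(writeFeatureTable(fv[, 1:24], tempfile()), "25 canonical")
})

test_that("the scaler imputes source medians and standardizes both domains", {
  x <- matrix(c(1, 2, 3, NA, 10, 20, 30, 40), 4,
              dimnames = list(NULL, NULL))
  colnames(x) <- c("a", "b")
  sc <- featureScaler(x)
  expect_equal(sc$medians[["a"]], 2)         # median of 1,2,3
  xs <- scaleFeatures(x, sc)
  expect_false(any(is.na(xs)))
  expect_equal(unname(colMeans(xs)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1), tolerance = 1e-12)
  # constant feature: scale guard keeps values finite
  const <- cbind(x, c = rep(5, 4))
  expect_true(all(is.finite(scaleFeatures(const, featureScaler(const)))))
})
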