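test_that("VCF indels are resolved from allele lengths with 0-based starts", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\td1\tACCCT\tA\t.\tPASS\t.",
    "chr1\t200\ti1\tG\tGATGATG\t.\tPASS\t."))
  cat <- readMicroindels(vcf, label = "functional")
  expect_s4_class(cat, "MicroindelCatalog")
  expect_length(cat, 2L)

  del <- cat[mcols(cat)$kind == "deletion"]
  expect_identical(GenomicRanges::start(del) - 1L, 100L)  # 0-based
  expect_identical(mcols(del)$indelLength, 4L)
  expect_identical(GenomicRanges::width(del), 4L)

  ins <- cat[mcols(cat)$kind == "insertion"]
  expect_identical(mcols(ins)$indelLength, 6L)
  expect_identical(GenomicRanges::width(ins), 0L)
  expect_identical(GenomicRanges::start(ins) - 1L, 200L)
  expect_true(all(mcols(cat)$label == "functional"))
})

test_that("multi-allelic rows are split and substitutions skipped per record", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "chr1\t300\tm1\tC\tCAAA,T\t.\tPASS\t.",
    "chr1\t400\ts1\tA\tG\t.\tPASS\t."))
  expect_warning(cat <- readMicroindels(vcf), "skipped 2")
  expect_length(cat, 1L)          # CAAA insertion survives; C>T and A>G do not
  expect_identical(mcols(cat)$kind, "insertion")
  expect_identical(mcols(cat)$indelLength, 3L)
  expect_identical(S4Vectors::metadata(cat)$skipped, 2L)
})

test_that("TSV reader yields one record per data row", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr2", start = c(10, 50, 90),
                   kind = c("deletion", "insertion", "deletion"),
                   length = c(6L, 9L, 4L))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cat <- readMicroindels(tsv, label = "neutral")
  expect_length(cat, nrow(df))
  expect_identical(mcols(cat)$indelLength, df$length)
  expect_error(readMicroindels(tempfile()), "no such file")
})

test_that("NFS microindel filter keeps 3..30 nt multiples of three, in order", {
  cat <- MicroindelCatalog(chrom = "chr1", start = c(0, 100, 200, 300, 400),
                           kind = "deletion",
                           indelLength = c(3L, 4L, 6L, 30L, 33L))
  kept <- filterNFSMicroindels(cat)
  expect_identical(mcols(kept)$indelLength, c(3L, 6L, 30L))
  expect_identical(filterNFSMicroindels(kept), kept)   # idempotent
  expect_length(filterNFSMicroindels(cat[0]), 0L)
})

test_that("NFS filters agree with a brute-force per-record rule check", {
  set.seed(41)
  n <- 100L
  len <- sample.int(40L, n, replace = TRUE)
  cat <- MicroindelCatalog(chrom = "chr1",
                           start = cumsum(len + 5L), kind = "deletion",
                           indelLength = len)
  oracle <- vapply(len, function(l) l >= 3 && l <= 30 && l %% 3 == 0,
                   logical(1))
  expect_identical(names(filterNFSMicroindels(cat)), names(cat)[oracle])

  elen <- sample(seq(3L, 33L, 1L), n, replace = TRUE)
  inCds <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.8, .2))
  stops <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.1, .9))
  mex <- MicroexonCatalog(chrom = "chr1", start = cumsum(elen + 10L),
                          end = cumsum(elen + 10L) + elen,
                          inCDS = inCds, containsStop = stops)
  oracleEx <- vapply(seq_len(n), function(i)
    elen[i] >= 3 && elen[i] <= 30 && elen[i] %% 3 == 0 &&
      inCds[i] && !stops[i], logical(1))
  expect_identical(names(filterNFSMicroexons(mex)), names(mex)[oracleEx])
})

test_that("microexon eligibility cases behave as annotated", {
  mex <- MicroexonCatalog(
    chrom = "chr3",
    start = c(78696778, 1000, 2000), end = c(78696805, 1028, 2009),
    gene = c("ROBO1", "x", "y"),
    containsStop = c(FALSE, FALSE, TRUE))
  kept <- filterNFSMicroexons(mex)
  expect_identical(mcols(kept)$gene, "ROBO1")       # 27 nt coding, no stop
  # 28 nt is frameshift, 9 nt with a stop codon is dropped
})

test_that("BED output is 0-based half-open and round-trips", {
  lit <- literatureMicroexons()
  mex <- MicroexonCatalog(chrom = lit$chrom, start = lit$start,
                          end = lit$start + lit$length, gene = lit$gene)
  bed <- tempfile(fileext = ".bed")
  writeBed(mex, bed, probability = lit$probability)
  lines <- readLines(bed)
  expect_length(lines, 19L)
  robo <- strsplit(grep("ROBO1", lines, value = TRUE), "\t")[[1]]
  expect_identical(robo[1:4], c("chr3", "78696778", "78696805", "ROBO1"))
  expect_identical(robo[5], "739")                   # probability x 1000

  back <- readMicroexonBed(bed)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(mex))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(mex))
})

test_that("a VCF locus survives the 1-based to 0-based to BED round trip", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"),
                     "chr1\t100\td1\tACCCTA\tA\t.\tPASS\t.")
  cat <- readMicroindels(vcf)
  bed <- tempfile(fileext = ".bed")
  writeBed(cat, bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  # REF ACCCTA at POS 100 deletes 1-based 101..105 = 0-based [100, 105)
  expect_identical(f[2:3], c("100", "105"))
})

test_that("catalog validity rejects inconsistent records", {
  expect_error(MicroindelCatalog(chrom = "chr1", start = 5,
                                 kind = "inversion", indelLength = 3L),
               "deletion|insertion")
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  expect_error(validObject(as(gr, "MicroindelCatalog")), "missing metadata")
})
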