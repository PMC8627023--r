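# Fixtures are built in code at test time; nothing binary ships with the
# package.

suppressPackageStartupMessages(library(GenomicRanges))  # mcols, start, width

writeToyVcf <- function(path, rows) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t")),
    rows), path)
  path
}

# provider returning a constant everywhere
constantProvider <- function(value) {
  function(chrom, positions) rep(value, length(positions))
}

# deterministic pseudo-track provider: score is a fixed function of
# (chrom, position), defined for every position >= 0
hashProvider <- function() {
  function(chrom, positions) {
    h <- as.integer(chartr("chrS", "1234", substr(chrom, 4, 4)))
    if (is.na(h)) h <- 1L
    sin(positions * 0.37 + h) + 0.1 * positions %% 1
  }
}

# standardized default-scenario pipeline used by several tests
runDefaultTransfer <- function(scenario) {
  dom <- generateDomains(scenario)
  scl <- featureScaler(featureMatrix(dom$source))
  Xs <- scaleFeatures(featureMatrix(dom$source), scl)
  Xt <- scaleFeatures(featureMatrix(dom$target), scl)
  proj <- fitTCA(Xs, Xt, m = 8)
  fit <- trainClassifier(sourceEmbedding(proj), domainLabels(dom$source))
  pred <- predictTarget(fit, targetEmbedding(proj))
  list(domains = dom, Xs = Xs, Xt = Xt, projection = proj,
       predictions = pred,
       accuracy = mean(as.integer(pred$label == "functional") ==
                         dom$targetLabels))
}
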