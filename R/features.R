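# Features module: the fixed 25-feature vector computed per record from a
# per-base conservation provider and per-residue structure annotations.
#
# Aggregation windows follow one rule at both levels: the record's own span
# plus nWindow positions of flank on each side; a zero-length insertion
# contributes its two flanking positions instead of a span.

.FEATURE_NAMES <- c(
  "record_length",
  "cons_max", "cons_min", "cons_mean",
  "ss_prob_max_C", "ss_prob_min_C", "ss_prob_mean_C",
  "ss_prob_max_H", "ss_prob_min_H", "ss_prob_mean_H",
  "ss_prob_max_E", "ss_prob_min_E", "ss_prob_mean_E",
  "ss_pred_frac_C", "ss_pred_frac_H", "ss_pred_frac_E",
  "dis_max", "dis_min", "dis_mean",
  "asa_max", "asa_min", "asa_mean",
  "protein_length", "dist_to_start", "dist_to_end")

#' Canonical feature layout
#'
#' The 25 feature names, in the fixed column order shared by every producer
#' and consumer in the package: record length (nt); max/min/mean DNA
#' conservation; max/min/mean secondary-structure probability for coil (C),
#' helix (H) and sheet (E); the fraction of window residues predicted as
#' each class; max/min/mean disorder; max/min/mean accessible surface area;
#' and three length-geometry features (protein length and the residue
#' distances from the encoded peptide to the N- and C-terminus).
#'
#' @return character vector of length 25.
#' @export
microFeatureNames <- function() .FEATURE_NAMES

#' Build a conservation provider from a flat track
#'
#' A conservation provider is a deterministic function
#' `f(chrom, positions)` mapping 0-based genomic positions to per-base
#' scores (phyloP-like), with `NA` for positions the track does not cover.
#' This constructor adapts a flat data.frame track — the plain-text stand-in
#' for a bigWig query — with columns `chrom`, `pos` (0-based) and `score`.
#'
#' @param track data.frame with columns `chrom`, `pos`, `score`.
#' @return a provider function.
#' @examples
#' p <- trackProvider(data.frame(chrom = "chr1", pos = 0:9, score = 0.7))
#' p("chr1", c(2, 5, 100))  # 0.7 0.7 NA
#' @export
trackProvider <- function(track) {
  stopifnot(all(c("chrom", "pos", "score") %in% colnames(track)))
  key <- paste(track$chrom, track$pos)
  score <- track$score
  function(chrom, positions) {
    score[match(paste(chrom, positions), key)]
  }
}

# 0-based positions queried for one record; the closed-form counts are
# len + 2*nWindow for deletions/exons and 2 + 2*nWindow for insertions
# (before truncation at the chromosome origin).
.consPositions1 <- function(start0, end0, zeroWidth, nWindow) {
  if (zeroWidth) {
    lo <- start0 - 1L - nWindow
    hi <- start0 + nWindow
  } else {
    lo <- start0 - nWindow
    hi <- end0 - 1L + nWindow
  }
  pos <- seq.int(lo, hi)
  pos[pos >= 0L]
}

#' Genomic positions queried for the conservation features
#'
#' @param x a [MicroindelCatalog-class] or [MicroexonCatalog-class].
#' @param nWindow flank size in bases on each side (default 2).
#' @return list of 0-based position vectors, one per record.
#' @export
conservationPositions <- function(x, nWindow = 2L) {
  stopifnot(is(x, "GRanges"), nWindow >= 0L)
  start0 <- GenomicRanges::start(x) - 1L
  end0 <- GenomicRanges::end(x)
  zw <- GenomicRanges::width(x) == 0L
  lapply(seq_along(x), function(i)
    .consPositions1(start0[i], end0[i], zw[i], as.integer(nWindow)))
}

#' Windowed DNA conservation features
#'
#' Queries the provider over the record span plus `nWindow` flanking bases
#' on each side (for insertions: the two bases flanking the insertion point
#' plus `nWindow` further on each side) and aggregates the non-missing
#' values.
#'
#' @inheritParams conservationPositions
#' @param provider a conservation provider function, e.g. from
#'   [trackProvider()].
#' @return data.frame with columns `cons_max`, `cons_min`, `cons_mean`
#'   (`NA` when every queried value is missing).
#' @export
conservationWindow <- function(x, provider, nWindow = 2L) {
  stopifnot(is.function(provider))
  pos <- conservationPositions(x, nWindow)
  chrom <- as.character(GenomeInfoDb::seqnames(x))
  out <- t(vapply(seq_along(pos), function(i) {
    v <- provider(chrom[i], pos[[i]])
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    c(max(v), min(v), mean(v))
  }, numeric(3)))
  stats::setNames(as.data.frame(out), c("cons_max", "cons_min", "cons_mean"))
}

#' Residue indices of the protein-level aggregation window
#'
#' The encoded residues plus `nWindow` residues of flank on each side,
#' truncated at the protein boundaries.  An insertion encodes no residues
#' (`residueEnd = residueStart - 1`); its window is the two residues
#' flanking the insertion point plus `nWindow` on each side, mirroring the
#' DNA-level rule.
#'
#' @param residueStart,residueEnd 1-based inclusive residue indices of the
#'   encoded peptide within the protein.
#' @param proteinLength protein length in residues.
#' @param nWindow flank size in residues on each side (default 2).
#' @return integer vector of 1-based residue indices.
#' @export
residueWindow <- function(residueStart, residueEnd, proteinLength,
                          nWindow = 2L) {
  if (residueStart < 1L || residueEnd > proteinLength ||
      residueEnd < residueStart - 1L)
    .stopf("residue indices [%d, %d] fall outside protein of length %d",
           residueStart, residueEnd, proteinLength)
  if (residueEnd < residueStart) {        # zero-length insertion point
    lo <- residueStart - 1L - nWindow
    hi <- residueStart + nWindow
  } else {
    lo <- residueStart - nWindow
    hi <- residueEnd + nWindow
  }
  seq.int(max(1L, lo), min(proteinLength, hi))
}

.aggTriple <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) c(NA_real_, NA_real_, NA_real_) else c(max(v), min(v), mean(v))
}

#' Extract the 25-feature vector for every record
#'
#' Fills the canonical feature layout of [microFeatureNames()]: the record
#' length from the catalog; the conservation triple from
#' [conservationWindow()]; per-class max/min/mean secondary-structure
#' probabilities, predicted-class fractions, disorder and ASA triples over
#' the [residueWindow()]; and the protein length-geometry features
#' (`dist_to_start` = 0-based index of the first encoded residue,
#' `dist_to_end` = residues between the last encoded residue and the
#' C-terminus).
#'
#' Records lacking a protein mapping, or whose providers return nothing,
#' get `NA` in the affected fields and are flagged in the `incomplete`
#' attribute; downstream modeling imputes them (see [featureScaler()]).
#'
#' @param x a [MicroindelCatalog-class] or [MicroexonCatalog-class] whose
#'   metadata carries the protein mapping columns `proteinId`,
#'   `proteinLength`, `residueStart`, `residueEnd`.
#' @param conservation a conservation provider function ([trackProvider()]).
#' @param residues data.frame of per-residue structure annotations with
#'   columns `proteinId`, `idx` (1-based residue index), `probC`, `probH`,
#'   `probE`, `disorder`, `asa` and optionally `predClass` (derived by
#'   argmax, ties broken in C, H, E order, when absent).
#' @param nWindow flank size (bases and residues) on each side; default 2.
#' @return numeric matrix, one row per record, 25 named columns; attribute
#'   `incomplete` is a logical vector flagging records with missing fields.
#' @export
extractFeatures <- function(x, conservation, residues, nWindow = 2L) {
  stopifnot(is(x, "GRanges"))
  mc <- mcols(x)
  recLen <- if (!is.null(mc$indelLength)) mc$indelLength else mc$exonLength
  if (is.null(recLen)) .stopf("catalog has neither indelLength nor exonLength")
  cons <- conservationWindow(x, conservation, nWindow)

  need <- c("probC", "probH", "probE", "disorder", "asa", "proteinId", "idx")
  miss <- setdiff(need, colnames(residues))
  if (length(miss))
    .stopf("residue table is missing column(s): %s",
           paste(miss, collapse = ", "))
  if (is.null(residues$predClass)) {
    p <- as.matrix(residues[, c("probC", "probH", "probE")])
    residues$predClass <- c("C", "H", "E")[max.col(p, ties.method = "first")]
  }
  byProt <- split(residues, residues$proteinId)

  n <- length(x)
  out <- matrix(NA_real_, n, length(.FEATURE_NAMES),
                dimnames = list(names(x), .FEATURE_NAMES))
  out[, "record_length"] <- recLen
  out[, c("cons_max", "cons_min", "cons_mean")] <- as.matrix(cons)

  hasMap <- all(.MAPPING_COLS %in% colnames(mc))
  for (i in seq_len(n)) {
    if (!hasMap || is.na(mc$proteinId[i])) next
    ann <- byProt[[as.character(mc$proteinId[i])]]
    if (is.null(ann)) next
    L <- as.integer(mc$proteinLength[i])
    rs <- as.integer(mc$residueStart[i]); re <- as.integer(mc$residueEnd[i])
    win <- tryCatch(residueWindow(rs, re, L, nWindow), error = function(e) {
      .warnf("record %s: %s", names(x)[i] %||% i, conditionMessage(e))
      NULL
    })
    if (is.null(win)) next
    ann <- ann[match(win, ann$idx), , drop = FALSE]
    ann <- ann[!is.na(ann$idx), , drop = FALSE]
    if (!nrow(ann)) next
    out[i, c("ss_prob_max_C", "ss_prob_min_C", "ss_prob_mean_C")] <-
      .aggTriple(ann$probC)
    out[i, c("ss_prob_max_H", "ss_prob_min_H", "ss_prob_mean_H")] <-
      .aggTriple(ann$probH)
    out[i, c("ss_prob_max_E", "ss_prob_min_E", "ss_prob_mean_E")] <-
      .aggTriple(ann$probE)
    out[i, c("ss_pred_frac_C", "ss_pred_frac_H", "ss_pred_frac_E")] <-
      c(mean(ann$predClass == "C"), mean(ann$predClass == "H"),
        mean(ann$predClass == "E"))
    out[i, c("dis_max", "dis_min", "dis_mean")] <- .aggTriple(ann$disorder)
    out[i, c("asa_max", "asa_min", "asa_mean")] <- .aggTriple(ann$asa)
    out[i, "protein_length"] <- L
    out[i, "dist_to_start"] <- rs - 1L
    out[i, "dist_to_end"] <- L - max(re, rs - 1L)
  }
  attr(out, "incomplete") <- apply(out, 1L, anyNA)
  out
}

#' Fit a median-imputing z-score scaler on the source domain
#'
#' Missing values are imputed with per-feature medians and every feature is
#' standardized to zero mean, unit variance.  Fitting on the source domain
#' only, then applying the frozen parameters to both domains, avoids target
#' leakage ahead of the kernel computation.  Zero-variance features get
#' scale 1 so standardization never divides by zero.
#'
#' @param x numeric matrix of source-domain feature vectors.
#' @return list with elements `medians`, `center`, `scale`.
#' @seealso [scaleFeatures()]
#' @export
featureScaler <- function(x) {
  x <- .assertMatrix(x)
  medians <- apply(x, 2L, stats::median, na.rm = TRUE)
  medians[is.na(medians)] <- 0
  xi <- x
  for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- medians[j]
  center <- colMeans(xi)
  scale <- apply(xi, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(medians = medians, center = center, scale = scale)
}

#' Apply a fitted scaler
#'
#' @param x numeric matrix with the scaler's feature dimension.
#' @param scaler output of [featureScaler()].
#' @return imputed, standardized matrix.
#' @export
scaleFeatures <- function(x, scaler) {
  x <- .assertMatrix(x)
  if (ncol(x) != length(scaler$center))
    .stopf("feature dimension %d does not match scaler (%d)",
           ncol(x), length(scaler$center))
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- scaler$medians[j]
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Write / read the 25-feature interchange table
#'
#' Tab-separated with one header row naming all 25 features in canonical
#' order, plus an `id` column (from rownames) and an optional `label`
#' column.  Missing values are serialized as `NA`.  `readFeatureTable()` is
#' the exact inverse on finite values and rejects any table whose feature
#' columns deviate from the canonical 25.
#'
#' @param x numeric matrix with the 25 canonical columns.
#' @param path file to write / read.
#' @param labels optional 0/1 labels written alongside.
#' @return `writeFeatureTable()`: `path` invisibly; `readFeatureTable()`:
#'   a [DomainDataset-class].
#' @export
writeFeatureTable <- function(x, path, labels = NULL) {
  x <- .assertMatrix(x)
  if (!identical(colnames(x), .FEATURE_NAMES))
    .stopf("feature table must have the 25 canonical columns; got %d",
           ncol(x))
  df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE)
  if (!is.null(labels)) df$label <- as.integer(labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @param domain domain tag given to the dataset read back.
#' @export
readFeatureTable <- function(path, domain = c("source", "target")) {
  domain <- match.arg(domain)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  featCols <- setdiff(colnames(df), c("id", "label"))
  if (length(featCols) != length(.FEATURE_NAMES))
    .stopf("expected 25 feature columns, found %d", length(featCols))
  bad <- which(featCols != .FEATURE_NAMES)
  if (length(bad))
    .stopf("feature column %d is '%s', expected '%s'",
           bad[1], featCols[bad[1]], .FEATURE_NAMES[bad[1]])
  m <- as.matrix(df[, featCols])
  rownames(m) <- if ("id" %in% colnames(df)) df$id else NULL
  DomainDataset(m, labels = if ("label" %in% colnames(df)) df$label else NULL,
                domain = domain)
}
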