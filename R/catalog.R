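# Catalog module: microindel / microexon record containers, non-frameshift
# eligibility filters, and the VCF / TSV / BED interchange surface.
#
# External files use the field's conventions (VCF POS is 1-based, BED and
# the flat TSV dialects are 0-based half-open); internally everything is a
# GRanges (1-based closed).  Insertions are zero-width anchor ranges at the
# position immediately after the VCF anchor base.

.MAPPING_COLS <- c("proteinId", "proteinLength", "residueStart", "residueEnd")

#' Build a microindel catalog from vectors
#'
#' @param chrom chromosome names.
#' @param start 0-based start of the deleted span, or the 0-based insertion
#'   point (the position immediately after the VCF anchor base).
#' @param kind `"deletion"` or `"insertion"` per record.
#' @param indelLength indel length in nt.  For deletions it must equal the
#'   span length; for insertions it is the inserted-sequence length.
#' @param label functional label per record (recycled).
#' @param strand strand per record (recycled; `"*"` for unknown).
#' @param id record identifiers (default `indel_1 ...`).
#' @param ... further metadata columns (e.g. the protein mapping columns
#'   `proteinId`, `proteinLength`, `residueStart`, `residueEnd`).
#' @return a [MicroindelCatalog-class].
#' @examples
#' MicroindelCatalog(chrom = "chr1", start = 100, kind = "deletion",
#'                   indelLength = 6, label = "functional")
#' @export
MicroindelCatalog <- function(chrom, start, kind, indelLength,
                              label = "unknown", strand = "*", id = NULL,
                              ...) {
  n <- length(start)
  kind <- rep_len(as.character(kind), n)
  indelLength <- rep_len(as.integer(indelLength), n)
  width <- ifelse(kind == "deletion", indelLength, 0L)
  gr <- GRanges(rep_len(chrom, n),
                IRanges(start = as.integer(start) + 1L,
                        width = as.integer(width)),
                strand = rep_len(strand, n))
  mcols(gr) <- DataFrame(kind = kind, indelLength = indelLength,
                         label = rep_len(as.character(label), n), ...)
  names(gr) <- id %||% paste0("indel_", seq_len(n))
  out <- as(gr, "MicroindelCatalog")
  validObject(out)
  out
}

#' Build a microexon catalog from vectors
#'
#' @param chrom,start,strand,id as in [MicroindelCatalog()]; `start` and
#'   `end` are 0-based half-open.
#' @param end 0-based exclusive end.
#' @param gene gene symbol per record (recycled; optional).
#' @param inCDS,containsStop logical eligibility flags (recycled); these are
#'   annotation inputs, not computed here.
#' @param ... further metadata columns, e.g. the protein mapping columns.
#' @return a [MicroexonCatalog-class].
#' @examples
#' MicroexonCatalog(chrom = "chr3", start = 78696778, end = 78696805,
#'                  gene = "ROBO1")
#' @export
MicroexonCatalog <- function(chrom, start, end, gene = NA_character_,
                             inCDS = TRUE, containsStop = FALSE,
                             strand = "*", id = NULL, ...) {
  n <- length(start)
  gr <- GRanges(rep_len(chrom, n),
                IRanges(start = as.integer(start) + 1L,
                        end = as.integer(end)),
                strand = rep_len(strand, n))
  mcols(gr) <- DataFrame(gene = rep_len(as.character(gene), n),
                         exonLength = as.integer(end) - as.integer(start),
                         inCDS = rep_len(as.logical(inCDS), n),
                         containsStop = rep_len(as.logical(containsStop), n),
                         ...)
  names(gr) <- id %||% paste0("mex_", seq_len(n))
  out <- as(gr, "MicroexonCatalog")
  validObject(out)
  out
}

#' Read microindels from a VCF or flat TSV file
#'
#' VCF rows are resolved to pure insertions or deletions from the REF/ALT
#' allele lengths; multi-allelic rows are split into biallelic records
#' first.  Records whose alleles do not describe a simple indel (SNVs,
#' complex substitutions) are skipped per record with one summary warning.
#' The TSV dialect has columns `chrom`, `start` (0-based), `kind`, `length`
#' and optionally `end`, `label`, `id`, `strand` plus the protein mapping
#' columns.
#'
#' @param path file to read.
#' @param label label assigned to every record (VCF carries no functional
#'   label); a TSV `label` column wins over this argument.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @return a [MicroindelCatalog-class]; the number of skipped VCF records is
#'   available as `metadata(x)$skipped`.
#' @export
readMicroindels <- function(path, label = "unknown",
                            format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("cannot read '%s': no such file", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") .readIndelVcf(path, label) else
    .readIndelTsv(path, label)
}

.readIndelVcf <- function(path, label) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  out <- list(chrom = character(), start = integer(), kind = character(),
              len = integer(), id = character())
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"] %||% NA_character_, ",", fixed = TRUE)[[1]]
    if (is.na(pos) || is.na(ref) || !length(alts) || anyNA(alts)) {
      skipped <- skipped + 1L
      next
    }
    rid <- fix[i, "ID"]
    for (j in seq_along(alts)) {
      alt <- alts[[j]]
      aid <- if (is.na(rid) || rid == ".")
        sprintf("%s_%d%s", fix[i, "CHROM"], pos,
                if (length(alts) > 1) paste0("_", j) else "")
      else if (length(alts) > 1) paste0(rid, "_", j) else rid
      if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) {
        # deletion: bases after the retained prefix are removed
        out$chrom <- c(out$chrom, fix[i, "CHROM"])
        out$start <- c(out$start, pos - 1L + nchar(alt))  # 0-based
        out$kind  <- c(out$kind, "deletion")
        out$len   <- c(out$len, nchar(ref) - nchar(alt))
        out$id    <- c(out$id, aid)
      } else if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) {
        out$chrom <- c(out$chrom, fix[i, "CHROM"])
        out$start <- c(out$start, pos - 1L + nchar(ref))
        out$kind  <- c(out$kind, "insertion")
        out$len   <- c(out$len, nchar(alt) - nchar(ref))
        out$id    <- c(out$id, aid)
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  if (skipped > 0L)
    .warnf("skipped %d VCF record(s) that are not simple indels", skipped)
  cat <- MicroindelCatalog(chrom = out$chrom, start = out$start,
                           kind = out$kind, indelLength = out$len,
                           label = label, id = out$id)
  S4Vectors::metadata(cat)$skipped <- skipped
  cat
}

.readIndelTsv <- function(path, label) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "kind", "length")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .stopf("TSV is missing required column(s): %s",
           paste(miss, collapse = ", "))
  extra <- df[intersect(.MAPPING_COLS, colnames(df))]
  do.call(MicroindelCatalog, c(
    list(chrom = df$chrom, start = df$start, kind = df$kind,
         indelLength = df$length,
         label = if ("label" %in% colnames(df)) df$label else label,
         strand = if ("strand" %in% colnames(df)) df$strand else "*",
         id = if ("id" %in% colnames(df)) df$id else NULL),
    as.list(extra)))
}

#' Read microexons from a flat TSV file
#'
#' Required columns: `chrom`, `start` (0-based), `end` (exclusive).
#' Optional: `gene`, `inCDS`, `containsStop`, `strand`, `id` and the protein
#' mapping columns `proteinId`, `proteinLength`, `residueStart`,
#' `residueEnd`.
#'
#' @param path file to read.
#' @return a [MicroexonCatalog-class].
#' @export
readMicroexons <- function(path) {
  if (!file.exists(path)) .stopf("cannot read '%s': no such file", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "start", "end"), colnames(df))
  if (length(miss))
    .stopf("TSV is missing required column(s): %s",
           paste(miss, collapse = ", "))
  extra <- df[intersect(.MAPPING_COLS, colnames(df))]
  do.call(MicroexonCatalog, c(
    list(chrom = df$chrom, start = df$start, end = df$end,
         gene = if ("gene" %in% colnames(df)) df$gene else NA_character_,
         inCDS = if ("inCDS" %in% colnames(df)) df$inCDS else TRUE,
         containsStop = if ("containsStop" %in% colnames(df))
           df$containsStop else FALSE,
         strand = if ("strand" %in% colnames(df)) df$strand else "*",
         id = if ("id" %in% colnames(df)) df$id else NULL),
    as.list(extra)))
}

#' Non-frameshift eligibility filter for microindels
#'
#' Retains records whose indel length is between 3 and 30 nt inclusive and a
#' multiple of 3 — the class whose insertion or removal preserves the
#' reading frame.  Record order is preserved and the filter is idempotent.
#'
#' @param x a [MicroindelCatalog-class].
#' @return the eligible subset of `x`.
#' @export
filterNFSMicroindels <- function(x) {
  stopifnot(is(x, "MicroindelCatalog"))
  len <- mcols(x)$indelLength
  x[len >= 3L & len <= 30L & len %% 3L == 0L]
}

#' Non-frameshift eligibility filter for microexons
#'
#' Retains coding microexons of 3-30 nt whose length is a multiple of 3
#' (frame preserving) and whose encoded peptide contains no stop codon.
#' The `inCDS` and `containsStop` flags are annotation inputs populated
#' upstream.
#'
#' @param x a [MicroexonCatalog-class].
#' @return the eligible subset of `x`.
#' @export
filterNFSMicroexons <- function(x) {
  stopifnot(is(x, "MicroexonCatalog"))
  mc <- mcols(x)
  len <- mc$exonLength
  x[len >= 3L & len <= 30L & len %% 3L == 0L & mc$inCDS & !mc$containsStop]
}

#' Write a catalog as 6-column BED
#'
#' Emits standard 0-based half-open BED6.  The name column is the gene
#' symbol when present, else the record id; the score column is
#' `probability * 1000` (rounded, capped at 1000) when a `probability`
#' metadata column or argument is available, else 0.
#'
#' @param x a [MicroindelCatalog-class] or [MicroexonCatalog-class].
#' @param path output file.
#' @param probability optional per-record functional probability used for
#'   the BED score column.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path, probability = NULL) {
  stopifnot(is(x, "GRanges"))
  gr <- granges(x)
  mc <- mcols(x)
  nm <- if (!is.null(mc$gene) && !all(is.na(mc$gene))) {
    ifelse(is.na(mc$gene), names(x) %||% as.character(seq_along(x)), mc$gene)
  } else names(x) %||% as.character(seq_along(x))
  prob <- probability %||% mc$probability
  score <- if (is.null(prob)) rep(0L, length(x)) else
    pmin(1000L, as.integer(round(prob * 1000)))
  names(gr) <- nm
  mcols(gr)$score <- score
  dir <- dirname(path)
  if (!dir.exists(dir)) .stopf("cannot write '%s': no such directory", path)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file of microexon intervals
#'
#' Convenience inverse of [writeBed()] for microexon catalogs; eligibility
#' flags default to `TRUE`/`FALSE` and must be refined from annotation.
#'
#' @param path BED file.
#' @return a [MicroexonCatalog-class].
#' @export
readMicroexonBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  MicroexonCatalog(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   gene = mcols(gr)$name %||% NA_character_,
                   strand = as.character(GenomicRanges::strand(gr)),
                   id = mcols(gr)$name)
}
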