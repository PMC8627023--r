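#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

.INDEL_KINDS  <- c("deletion", "insertion")
.LABEL_LEVELS <- c("functional", "neutral", "unknown")
.DOMAIN_TAGS  <- c("source", "target")

#' Catalog of microindel loci
#'
#' A [GenomicRanges::GRanges] subclass holding one record per microindel.
#' Coordinates follow the usual GRanges 1-based closed convention; insertions
#' are zero-width ranges anchored at the position immediately after the VCF
#' anchor base, so that external 0-based half-open interchange (VCF in, BED
#' out) round-trips exactly.  Required metadata columns:
#' \describe{
#'   \item{kind}{`"deletion"` or `"insertion"`.}
#'   \item{indelLength}{indel length in nt: deleted span width for deletions,
#'     inserted-sequence length for insertions.}
#'   \item{label}{`"functional"`, `"neutral"` or `"unknown"`.}
#' }
#' Optional columns `proteinId`, `proteinLength`, `residueStart`,
#' `residueEnd` carry the protein-level mapping used by [extractFeatures()].
#'
#' @seealso [MicroindelCatalog()], [readMicroindels()], [filterNFSMicroindels()]
#' @export
setClass("MicroindelCatalog", contains = "GRanges")

#' Catalog of microexon loci
#'
#' A [GenomicRanges::GRanges] subclass with one record per microexon.
#' Required metadata columns:
#' \describe{
#'   \item{exonLength}{exon length in nt, always equal to the range width.}
#'   \item{inCDS}{logical; exon lies inside an annotated coding sequence.}
#'   \item{containsStop}{logical; the encoded peptide contains a stop codon.}
#' }
#' A `gene` column plus the optional protein-mapping columns of
#' [MicroindelCatalog] are carried through when present.
#'
#' @seealso [MicroexonCatalog()], [readMicroexons()], [filterNFSMicroexons()]
#' @export
setClass("MicroexonCatalog", contains = "GRanges")

setValidity("MicroindelCatalog", function(object) {
  mc <- mcols(object)
  need <- c("kind", "indelLength", "label")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (!all(mc$kind %in% .INDEL_KINDS))
    return("'kind' must be 'deletion' or 'insertion'")
  if (!all(mc$label %in% .LABEL_LEVELS))
    return("'label' must be 'functional', 'neutral' or 'unknown'")
  if (any(mc$indelLength < 1L))
    return("'indelLength' must be >= 1")
  del <- mc$kind == "deletion"
  if (any(GenomicRanges::width(object)[del] != mc$indelLength[del]))
    return("deletion width must equal indelLength")
  if (any(GenomicRanges::width(object)[!del] != 0L))
    return("insertions must be zero-width anchor ranges")
  TRUE
})

setValidity("MicroexonCatalog", function(object) {
  mc <- mcols(object)
  need <- c("exonLength", "inCDS", "containsStop")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (any(GenomicRanges::width(object) != mc$exonLength))
    return("exonLength must equal the range width")
  if (!is.logical(mc$inCDS) || !is.logical(mc$containsStop))
    return("'inCDS' and 'containsStop' must be logical")
  TRUE
})

#' Two-domain feature dataset
#'
#' Holds an n-record-by-p-feature matrix for one domain of a transfer-learning
#' problem, tagged `"source"` (labeled microindels) or `"target"` (unlabeled
#' microexons).  Labels, when present, are binary with 1 = functional and
#' 0 = neutral.
#'
#' @slot matrix numeric matrix, records in rows, features in columns.
#' @slot labels integer vector of 0/1 labels, or empty when the domain is
#'   unlabeled.
#' @slot domain `"source"` or `"target"`.
#'
#' @seealso [DomainDataset()], [fitTCA()], [generateDomains()]
#' @export
setClass("DomainDataset",
  representation(matrix = "matrix", labels = "integer", domain = "character"))

setValidity("DomainDataset", function(object) {
  if (!is.numeric(object@matrix)) return("'matrix' must be numeric")
  if (length(object@domain) != 1L || !object@domain %in% .DOMAIN_TAGS)
    return("'domain' must be 'source' or 'target'")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@matrix))
    return("'labels' length must match the number of rows")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("'labels' must be 0 (neutral) or 1 (functional)")
  TRUE
})

#' Fitted Transfer Component Analysis projection
#'
#' State of a fitted TCA mapping: the stacked source+target training matrix,
#' the kernel specification (with any data-derived bandwidth frozen at fit
#' time), and the leading eigenvectors of the regularized transfer-component
#' eigenproblem.  Projecting data through the object ([tcaTransform()])
#' yields latent components in which the maximum mean discrepancy between
#' the two domains is minimized while embedded variance is preserved.
#'
#' @slot kernel list; resolved kernel specification (see [kernelSpec()]).
#' @slot trainMatrix the stacked (n1+n2) x p fit-time feature matrix.
#' @slot eigvecs (n1+n2) x m matrix of retained eigenvectors.
#' @slot eigvals the m retained eigenvalues, non-increasing.
#' @slot m number of retained components.
#' @slot mu ridge regularizer of the transfer eigenproblem.
#' @slot nSource,nTarget row counts of the two stacked domains.
#' @slot embedding cached (n1+n2) x m fit-time embedding `K %*% eigvecs`.
#'
#' @seealso [fitTCA()], [tcaTransform()], [mmdDistance()]
#' @export
setClass("TCAProjection",
  representation(kernel = "list", trainMatrix = "matrix", eigvecs = "matrix",
                 eigvals = "numeric", m = "integer", mu = "numeric",
                 nSource = "integer", nTarget = "integer",
                 embedding = "matrix"))

setValidity("TCAProjection", function(object) {
  n <- object@nSource + object@nTarget
  if (nrow(object@eigvecs) != n) return("eigvecs rows must equal n1+n2")
  if (ncol(object@eigvecs) != object@m) return("eigvecs cols must equal m")
  if (length(object@eigvals) != object@m) return("one eigenvalue per component")
  if (is.unsorted(rev(object@eigvals), strictly = FALSE))
    return("eigenvalues must be non-increasing")
  if (!all(is.finite(object@embedding)))
    return("training embedding must be finite")
  TRUE
})

#' Cross-validation evaluation report
#'
#' Pooled metrics of a stratified k-fold cross-validation of the margin
#' classifier: precision, accuracy, Matthews correlation coefficient, recall
#' and the rank-statistic AUC, together with the fold assignment that
#' produced them.
#'
#' @slot precision,accuracy,mcc,recall,auc pooled metrics; all in [0,1]
#'   except `mcc` in [-1,1].
#' @slot nFolds number of folds.
#' @slot folds integer fold id per record.
#' @slot seed RNG seed used for fold assignment.
#'
#' @seealso [crossValidate()]
#' @export
setClass("EvaluationReport",
  representation(precision = "numeric", accuracy = "numeric", mcc = "numeric",
                 recall = "numeric", auc = "numeric", nFolds = "integer",
                 folds = "integer", seed = "integer"))

setValidity("EvaluationReport", function(object) {
  ok01 <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!ok01(object@precision)) return("precision must be in [0,1]")
  if (!ok01(object@accuracy)) return("accuracy must be in [0,1]")
  if (!ok01(object@recall)) return("recall must be in [0,1]")
  if (!ok01(object@auc)) return("auc must be in [0,1]")
  if (abs(object@mcc) > 1 + 1e-12) return("mcc must be in [-1,1]")
  if (length(object@folds) &&
      !setequal(unique(object@folds), seq_len(object@nFolds)))
    return("every fold id in 1..nFolds must occur")
  TRUE
})

#' Reference catalog for nearest-neighbor prediction
#'
#' Already-scored microexons kept in the original standardized 25-feature
#' space.  A novel record that cannot go through the two-sample TCA mapping
#' is labeled by the mean stored probability of its k nearest reference
#' records ([knnPredict()]).
#'
#' @slot features n x p matrix of reference feature vectors (raw scale).
#' @slot probabilities functional probability per reference record.
#' @slot labels 0/1 labels at the catalog's threshold (may be empty).
#' @slot scaler feature scaler (medians/center/scale) applied to queries so
#'   that distances are computed in the standardized space; see
#'   [featureScaler()].
#'
#' @seealso [referenceCatalog()], [knnPredict()]
#' @export
setClass("ReferenceCatalog",
  representation(features = "matrix", probabilities = "numeric",
                 labels = "integer", scaler = "list"))

setValidity("ReferenceCatalog", function(object) {
  if (nrow(object@features) != length(object@probabilities))
    return("one probability per reference row")
  if (any(object@probabilities < 0 | object@probabilities > 1))
    return("probabilities must be in [0,1]")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@features))
    return("'labels' length must match the number of rows")
  TRUE
})
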