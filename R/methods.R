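# Constructors, accessors and show() methods for the core S4 classes.

#' Construct a DomainDataset
#'
#' @param matrix numeric matrix (records x features); a data.frame is
#'   coerced.
#' @param labels optional 0/1 vector (1 = functional); logical and factor
#'   inputs are coerced.
#' @param domain `"source"` or `"target"`.
#' @return a [DomainDataset-class] object.
#' @examples
#' d <- DomainDataset(matrix(rnorm(20), 4), labels = c(1, 0, 1, 0))
#' featureMatrix(d); domainLabels(d); domainTag(d)
#' @export
DomainDataset <- function(matrix, labels = NULL,
                          domain = c("source", "target")) {
  domain <- match.arg(domain)
  matrix <- .assertMatrix(matrix, "matrix")
  labels <- if (is.null(labels)) integer(0) else as.integer(labels)
  new("DomainDataset", matrix = matrix, labels = labels, domain = domain)
}

#' @rdname DomainDataset-class
#' @export
setMethod("featureMatrix", "DomainDataset", function(x) x@matrix)

#' @rdname DomainDataset-class
#' @export
setMethod("domainLabels", "DomainDataset",
          function(x) if (length(x@labels)) x@labels else NULL)

#' @rdname DomainDataset-class
#' @export
setMethod("domainTag", "DomainDataset", function(x) x@domain)

#' @rdname DomainDataset-class
#' @export
setMethod("nrow", "DomainDataset", function(x) nrow(x@matrix))

#' @rdname DomainDataset-class
#' @export
setMethod("ncol", "DomainDataset", function(x) ncol(x@matrix))

setMethod("show", "DomainDataset", function(object) {
  cat(sprintf("DomainDataset [%s]: %d records x %d features, %s\n",
              object@domain, nrow(object@matrix), ncol(object@matrix),
              if (length(object@labels))
                sprintf("%d functional / %d neutral",
                        sum(object@labels == 1L), sum(object@labels == 0L))
              else "unlabeled"))
})

#' @rdname TCAProjection-class
#' @export
setMethod("nComponents", "TCAProjection", function(x) x@m)

#' @rdname TCAProjection-class
#' @export
setMethod("sourceEmbedding", "TCAProjection",
          function(x) x@embedding[seq_len(x@nSource), , drop = FALSE])

#' @rdname TCAProjection-class
#' @export
setMethod("targetEmbedding", "TCAProjection",
          function(x) x@embedding[x@nSource + seq_len(x@nTarget), ,
                                  drop = FALSE])

setMethod("show", "TCAProjection", function(object) {
  cat(sprintf(
    "TCAProjection: %d components, %s kernel, mu = %g\n",
    object@m, object@kernel$kernel, object@mu))
  cat(sprintf("  fitted on %d source + %d target records (%d features)\n",
              object@nSource, object@nTarget, ncol(object@trainMatrix)))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(object@eigvals, 5), 4), collapse = ", "),
      if (object@m > 5) "..." else "", "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%d-fold CV, seed %d)\n",
              object@nFolds, object@seed))
  cat(sprintf(
    "  precision %.3f | accuracy %.3f | MCC %.3f | recall %.3f | AUC %.3f\n",
    object@precision, object@accuracy, object@mcc, object@recall,
    object@auc))
})

#' Coerce an EvaluationReport to a one-row data.frame
#'
#' @param x an [EvaluationReport-class] object.
#' @param ... ignored.
#' @export
#' @method as.data.frame EvaluationReport
as.data.frame.EvaluationReport <- function(x, ...) {
  data.frame(precision = x@precision, accuracy = x@accuracy, mcc = x@mcc,
             recall = x@recall, auc = x@auc, n_folds = x@nFolds,
             seed = x@seed)
}

#' Construct a ReferenceCatalog
#'
#' @param features matrix of reference feature vectors on the raw feature
#'   scale (one row per already-scored microexon).
#' @param probabilities functional probability per row.
#' @param labels optional 0/1 labels.
#' @param scaler optional [featureScaler()] output; when `NULL` a scaler is
#'   fitted on `features` so queries and references share one standardized
#'   space.
#' @return a [ReferenceCatalog-class] object.
#' @export
referenceCatalog <- function(features, probabilities, labels = NULL,
                             scaler = NULL) {
  features <- .assertMatrix(features, "features")
  if (is.null(scaler)) scaler <- featureScaler(features)
  new("ReferenceCatalog", features = features,
      probabilities = as.numeric(probabilities),
      labels = if (is.null(labels)) integer(0) else as.integer(labels),
      scaler = scaler)
}

setMethod("show", "ReferenceCatalog", function(object) {
  cat(sprintf("ReferenceCatalog: %d records x %d features\n",
              nrow(object@features), ncol(object@features)))
  if (length(object@labels))
    cat(sprintf("  %d functional / %d neutral at the stored threshold\n",
                sum(object@labels == 1L), sum(object@labels == 0L)))
})
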