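#' @rdname DomainDataset-class
#' @param object,x a package object
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname DomainDataset-class
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname DomainDataset-class
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))

#' @rdname TCAProjection-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname TCAProjection-class
#' @export
setGeneric("sourceEmbedding", function(x) standardGeneric("sourceEmbedding"))

#' @rdname TCAProjection-class
#' @export
setGeneric("targetEmbedding", function(x) standardGeneric("targetEmbedding"))

#' Project feature vectors into the fitted latent space
#'
#' Rows identical to fit-time training rows reproduce the cached training
#' embedding; any other row is mapped with the kernel out-of-sample
#' extension: its kernel row against the training stack is multiplied by the
#' stored eigenvectors.
#'
#' @param x a [TCAProjection-class] object.
#' @param data numeric matrix with the training feature dimension.
#' @return numeric matrix with `nComponents(x)` columns.
#' @export
setGeneric("tcaTransform", function(x, data) standardGeneric("tcaTransform"))
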