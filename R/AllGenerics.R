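#' @rdname AssociationSet-class
#' @param object,x an object.
#' @export
setGeneric("traitId", function(object) standardGeneric("traitId"))

#' @rdname AssociationSet-class
#' @export
setGeneric("traitType", function(object) standardGeneric("traitType"))

#' @rdname AssociationSet-class
#' @export
setGeneric("assocData", function(object) standardGeneric("assocData"))

#' @rdname AssociationSet-class
#' @export
setGeneric("variantIds", function(object) standardGeneric("variantIds"))

#' @rdname AssociationSet-class
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))

#' @rdname HarmonizedSet-class
#' @param object an object.
#' @export
setGeneric("exposureId", function(object) standardGeneric("exposureId"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("outcomeId", function(object) standardGeneric("outcomeId"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("harmonizedData", function(object) standardGeneric("harmonizedData"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("droppedCounts", function(object) standardGeneric("droppedCounts"))

#' @rdname InstrumentSet-class
#' @param object an object.
#' @export
setGeneric("fStatistics", function(object) standardGeneric("fStatistics"))

#' @rdname InstrumentSet-class
#' @export
setGeneric("auditCounts", function(object) standardGeneric("auditCounts"))

#' Pairwise linkage-disequilibrium lookup
#'
#' Returns the r-squared between one variant and each of a vector of other
#' variants.  Pairs unknown to the source are in linkage equilibrium (0).
#'
#' @param source an [LDSource].
#' @param id a single variant id.
#' @param ids character vector of variant ids to query against \code{id}.
#' @return numeric vector of r-squared values, one per element of \code{ids}.
#' @export
setGeneric("ldR2", function(source, id, ids) standardGeneric("ldR2"))
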