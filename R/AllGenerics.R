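# Generics for the package's accessors.

#' @rdname GeneModels-class
#' @param x,object An object.
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' @rdname GeneModels-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname GeneModels-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels-class
#' @export
setGeneric("isTranslatable", function(x) standardGeneric("isTranslatable"))

#' @rdname VariantPanel-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname VariantPanel-class
#' @param pool \code{"mut"} or \code{"wt"}.
#' @export
setGeneric("poolCounts", function(x, pool) standardGeneric("poolCounts"))

#' @rdname VariantPanel-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname EDProfile-class
#' @export
setGeneric("edValues", function(x) standardGeneric("edValues"))

#' @rdname EDProfile-class
#' @export
setGeneric("edThreshold", function(x) standardGeneric("edThreshold"))

#' @rdname F2Cohort-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname F2Cohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname F2Cohort-class
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname F2Cohort-class
#' @export
setGeneric("causalLocus", function(x) standardGeneric("causalLocus"))
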