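#' @rdname TCRRepertoire-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname TCRRepertoire-accessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))

#' @rdname TCRRepertoire-accessors
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))

#' @rdname TCRRepertoire-accessors
#' @export
setGeneric("totalTemplates", function(x) standardGeneric("totalTemplates"))

#' @rdname TCRRepertoire-accessors
#' @export
setGeneric("productiveTemplates",
           function(x) standardGeneric("productiveTemplates"))

#' @rdname productiveSubset
#' @export
setGeneric("productiveSubset", function(x) standardGeneric("productiveSubset"))

#' @rdname TCRCohort-accessors
#' @export
setGeneric("repertoires", function(x) standardGeneric("repertoires"))

#' @rdname TCRCohort-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname TCRCohort-accessors
#' @export
setGeneric("clinical", function(x) standardGeneric("clinical"))

#' @rdname EpitopeDB-accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
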