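#' Accessors for TCRRepertoire
#'
#' `sampleId`, `tissue` and `clones` return the slots; `totalTemplates` and
#' `productiveTemplates` are computed from the clone table (the sum of
#' template counts over all, respectively in-frame, rearrangements).
#'
#' @param x a [TCRRepertoire-class] object.
#' @return `sampleId`/`tissue`: character scalar; `clones`: data.frame;
#'   `totalTemplates`/`productiveTemplates`: numeric scalar.
#' @name TCRRepertoire-accessors
NULL

#' @rdname TCRRepertoire-accessors
#' @export
setMethod("sampleId", "TCRRepertoire", function(x) x@sampleId)

#' @rdname TCRRepertoire-accessors
#' @export
setMethod("tissue", "TCRRepertoire", function(x) x@tissue)

#' @rdname TCRRepertoire-accessors
#' @export
setMethod("clones", "TCRRepertoire", function(x) x@clones)

#' @rdname TCRRepertoire-accessors
#' @export
setMethod("totalTemplates", "TCRRepertoire",
          function(x) sum(x@clones$templates))

#' @rdname TCRRepertoire-accessors
#' @export
setMethod("productiveTemplates", "TCRRepertoire", function(x)
    sum(x@clones$templates[x@clones$frame_type == "in_frame"]))

#' Restrict a repertoire to productive rearrangements
#'
#' Keeps exactly the in-frame, stop-codon-free clones; template totals are
#' recomputed from the retained rows. Idempotent.
#'
#' @param x a [TCRRepertoire-class] object.
#' @return a [TCRRepertoire-class] with only productive clones.
#' @export
setMethod("productiveSubset", "TCRRepertoire", function(x) {
    keep <- x@clones$frame_type == "in_frame"
    initialize(x, clones = {
        cl <- x@clones[keep, , drop = FALSE]; rownames(cl) <- NULL; cl
    })
})

setMethod("show", "TCRRepertoire", function(object) {
    cl <- object@clones
    nprod <- sum(cl$frame_type == "in_frame")
    cat(sprintf(paste0("TCRRepertoire '%s' (%s)\n",
                       "  %d rearrangements (%d productive)\n",
                       "  %d templates (%d productive)\n"),
                object@sampleId, object@tissue, nrow(cl), nprod,
                totalTemplates(object), productiveTemplates(object)))
})

#' Accessors for TCRCohort
#'
#' @param x a [TCRCohort-class] object.
#' @return `repertoires`: named list of [TCRRepertoire-class];
#'   `manifest`/`clinical`: data.frame.
#' @name TCRCohort-accessors
NULL

#' @rdname TCRCohort-accessors
#' @export
setMethod("repertoires", "TCRCohort", function(x) x@repertoires)

#' @rdname TCRCohort-accessors
#' @export
setMethod("manifest", "TCRCohort", function(x) x@manifest)

#' @rdname TCRCohort-accessors
#' @export
setMethod("clinical", "TCRCohort", function(x) x@clinical)

setMethod("show", "TCRCohort", function(object) {
    man <- object@manifest
    cat(sprintf("TCRCohort: %d repertoires (%d tumor, %d blood), %d patients\n",
                length(object@repertoires), sum(man$tissue == "tumor"),
                sum(man$tissue == "blood"), length(unique(man$patient_id))))
    if (nrow(man))
        print(table(group = man$group, tissue = man$tissue))
})

#' Accessor for EpitopeDB
#' @param x an [EpitopeDB-class] object.
#' @return data.frame of (cdr3_aa, species, epitope, mhc_class) entries.
#' @name EpitopeDB-accessors
NULL

#' @rdname EpitopeDB-accessors
#' @export
setMethod("entries", "EpitopeDB", function(x) x@entries)

setMethod("show", "EpitopeDB", function(object) {
    e <- object@entries
    cat(sprintf("EpitopeDB: %d entries, %d distinct CDR3s, %d species\n",
                nrow(e), length(unique(e$cdr3_aa)),
                length(unique(e$species))))
})

#' @export
setMethod("length", "TCRCohort", function(x) length(x@repertoires))

#' @export
setMethod("[[", "TCRCohort", function(x, i) x@repertoires[[i]])
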