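#' Number of spacer segments
#' @param x a [CassetteDesign-class] or [CassetteState-class].
#' @return An integer scalar.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' loxP site orientations
#' @param x a [CassetteDesign-class] or [CassetteState-class].
#' @return A character vector of `"+"`/`"-"`.
#' @export
setGeneric("siteOrientations", function(x) standardGeneric("siteOrientations"))

#' Oriented segments of a cassette state
#' @param x a [CassetteState-class].
#' @return A data.frame with columns `id` and `orientation`.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname nSegments
setMethod("nSegments", "CassetteDesign", function(x) x@nSegments)

#' @rdname nSegments
setMethod("nSegments", "CassetteState", function(x) length(x@segmentIds))

#' @rdname siteOrientations
setMethod("siteOrientations", "CassetteDesign", function(x) x@siteOrientations)

#' @rdname siteOrientations
setMethod("siteOrientations", "CassetteState", function(x) x@siteOrientations)

#' @rdname segmentTable
setMethod("segmentTable", "CassetteState", function(x) {
    data.frame(id = x@segmentIds, orientation = x@segmentOrientations,
               stringsAsFactors = FALSE)
})
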