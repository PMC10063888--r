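#' @rdname accessors
#' @export
setGeneric("icfValue", function(object) standardGeneric("icfValue"))

#' @rdname accessors
#' @export
setGeneric("icfKind", function(object) standardGeneric("icfKind"))

#' @rdname accessors
#' @export
setGeneric("odCenter", function(object) standardGeneric("odCenter"))

#' @rdname accessors
#' @export
setGeneric("meanODDiameter", function(object) standardGeneric("meanODDiameter"))

#' @rdname accessors
#' @export
setGeneric("vesselLabels", function(object) standardGeneric("vesselLabels"))

#' @rdname accessors
#' @export
setGeneric("mapMeta", function(object) standardGeneric("mapMeta"))

#' @rdname accessors
#' @export
setGeneric("rvgcValues", function(object) standardGeneric("rvgcValues"))

#' @rdname accessors
#' @export
setGeneric("rvgcFlags", function(object) standardGeneric("rvgcFlags"))

#' @rdname accessors
#' @export
setGeneric("vessels", function(object) standardGeneric("vessels"))
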