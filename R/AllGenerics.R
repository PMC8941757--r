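#' @rdname fold
#' @export
setGeneric("fold", function(x) standardGeneric("fold"))

#' @rdname projectSFS
#' @export
setGeneric("projectSFS", function(x, m) standardGeneric("projectSFS"))

#' @rdname normalizeSFS
#' @export
setGeneric("normalizeSFS", function(x) standardGeneric("normalizeSFS"))

#' @rdname sfs-accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @rdname sfs-accessors
#' @export
setGeneric("nHaploid", function(x) standardGeneric("nHaploid"))

#' @rdname sfs-accessors
#' @export
setGeneric("isFolded", function(x) standardGeneric("isFolded"))

#' @rdname sfs-accessors
#' @export
setGeneric("isPolarized", function(x) standardGeneric("isPolarized"))

#' @rdname sfs-accessors
#' @export
setGeneric("segregatingSites", function(x) standardGeneric("segregatingSites"))

#' @rdname asfs-accessors
#' @export
setGeneric("asfsValues", function(x) standardGeneric("asfsValues"))

#' @rdname asfs-accessors
#' @export
setGeneric("taxaCount", function(x) standardGeneric("taxaCount"))

#' @rdname asfs-accessors
#' @export
setGeneric("binLayout", function(x) standardGeneric("binLayout"))

#' @rdname epoch-accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname epoch-accessors
#' @export
setGeneric("popSizeAt", function(x, t) standardGeneric("popSizeAt"))

#' @rdname xiGrid
#' @export
setGeneric("xiGrid", function(x) standardGeneric("xiGrid"))
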