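#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))
#' @rdname accessors
#' @export
setGeneric("genus", function(x) standardGeneric("genus"))
#' @rdname accessors
#' @export
setGeneric("dnaSequence", function(x) standardGeneric("dnaSequence"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("isPlasmid", function(x) standardGeneric("isPlasmid"))
#' @rdname accessors
#' @export
setGeneric("cdsTable", function(x) standardGeneric("cdsTable"))
#' @rdname accessors
#' @export
setGeneric("skippedFeatures", function(x) standardGeneric("skippedFeatures"))

#' @rdname genomeSize
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))
#' @rdname gcContent
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))
#' @rdname windowedGcSkew
#' @export
setGeneric("windowedGcSkew", function(x, nWindows = 4096L)
  standardGeneric("windowedGcSkew"))
#' @rdname gcsi
#' @export
setGeneric("gcsi", function(x, nWindows = 4096L, srNorm = 6000, distNorm = 600)
  standardGeneric("gcsi"))

#' @rdname accessors
#' @export
setGeneric("windowSkews", function(x) standardGeneric("windowSkews"))
#' @rdname accessors
#' @export
setGeneric("cumulativeSkew", function(x) standardGeneric("cumulativeSkew"))

#' @rdname accessors
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))
#' @rdname accessors
#' @export
setGeneric("genusLabels", function(x) standardGeneric("genusLabels"))
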