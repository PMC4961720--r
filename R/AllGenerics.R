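#' @include AllClasses.R
NULL

#' @export
setGeneric("bomanIndex", function(x, ...) standardGeneric("bomanIndex"))

#' @export
setGeneric("gravy", function(x, ...) standardGeneric("gravy"))

#' @export
setGeneric("wwInterface", function(x, ...) standardGeneric("wwInterface"))

#' @export
setGeneric("netCharge", function(x, ...) standardGeneric("netCharge"))

#' @export
setGeneric("hydrophobicRatio",
           function(x, ...) standardGeneric("hydrophobicRatio"))

#' @export
setGeneric("molecularWeight",
           function(x, ...) standardGeneric("molecularWeight"))

#' @export
setGeneric("descriptorProfile",
           function(x, ...) standardGeneric("descriptorProfile"))

#' @export
setGeneric("applyMutations",
           function(x, mutations, ...) standardGeneric("applyMutations"))

#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @export
setGeneric("peptideId", function(x) standardGeneric("peptideId"))

#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))

#' @export
setGeneric("scanRows", function(x) standardGeneric("scanRows"))

#' @export
setGeneric("csdData", function(x) standardGeneric("csdData"))

#' @export
setGeneric("restraintCounts", function(x) standardGeneric("restraintCounts"))
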