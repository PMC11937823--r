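#' Re-exported generics
#'
#' `counts` is re-exported from \pkg{BiocGenerics} so that
#' `counts(x)` works without attaching that package.
#'
#' @importFrom BiocGenerics counts
#' @export counts
#' @name reexports
#' @keywords internal
NULL

#' @rdname AmpliconExperiment-class
#' @export
setGeneric("molecule", function(object) standardGeneric("molecule"))
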