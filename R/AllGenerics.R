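# Generics shared across modules (defined first in collation order).

#' @rdname predictProbability
#' @export
setGeneric("predictProbability",
           function(object, table) standardGeneric("predictProbability"))
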