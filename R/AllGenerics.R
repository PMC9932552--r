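#' @export
setGeneric("nTemplates", function(object) standardGeneric("nTemplates"))

#' @export
setGeneric("templateHeadings", function(object) standardGeneric("templateHeadings"))

#' @export
setGeneric("degPerPixel", function(object) standardGeneric("degPerPixel"))

#' @export
setGeneric("flowArray", function(object) standardGeneric("flowArray"))

#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @export
setGeneric("trialSpec", function(object) standardGeneric("trialSpec"))

#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @export
setGeneric("sceneConfig", function(object) standardGeneric("sceneConfig"))

#' @export
setGeneric("activations", function(object) standardGeneric("activations"))

#' @export
setGeneric("inputTrace", function(object) standardGeneric("inputTrace"))

#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
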