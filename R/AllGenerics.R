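#' @include AllClasses.R
NULL

#' @export
setGeneric("cellArea", function(mesh, cells = NULL) standardGeneric("cellArea"))

#' @export
setGeneric("cellPerimeter",
           function(mesh, cells = NULL) standardGeneric("cellPerimeter"))

#' @export
setGeneric("cellCentroid",
           function(mesh, cells = NULL) standardGeneric("cellCentroid"))

#' @export
setGeneric("neighbourCount",
           function(mesh, cells = NULL) standardGeneric("neighbourCount"))

#' @export
setGeneric("validateMesh", function(mesh, ...) standardGeneric("validateMesh"))

#' @export
setGeneric("tissueEnergy",
           function(mesh, params) standardGeneric("tissueEnergy"))

#' @export
setGeneric("vertexForces",
           function(mesh, params) standardGeneric("vertexForces"))

#' @export
setGeneric("cellPressure",
           function(mesh, params, cells = NULL) standardGeneric("cellPressure"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @export
setGeneric("nJunctions", function(x) standardGeneric("nJunctions"))

#' @export
setGeneric("boxSize", function(x) standardGeneric("boxSize"))

#' @export
setGeneric("patchSize", function(x) standardGeneric("patchSize"))

#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' @export
setGeneric("cellKind", function(x, cells = NULL) standardGeneric("cellKind"))

#' @export
setGeneric("activeCells", function(x) standardGeneric("activeCells"))

#' @export
setGeneric("passiveCells", function(x) standardGeneric("passiveCells"))

#' @export
setGeneric("aliveCells", function(x) standardGeneric("aliveCells"))
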