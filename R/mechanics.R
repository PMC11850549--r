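#' @include mesh-core.R params.R
NULL

#' Tissue shape energy
#'
#' Sum over live cells of the quadratic area and perimeter penalties,
#' `E = sum_c [ K_A/2 (A_c - A_c0)^2 + K_P/2 (P_c - P_c0)^2 ]`.
#' Non-negative, and zero exactly when every cell sits at both targets.
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @return scalar energy in simulation units
#' @examples
#' sq <- makeSingleCellMesh(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
#'                          targetArea = 0.5, targetPerimeter = 3)
#' tissueEnergy(sq, modelParams())  # 3/2 * 0.25 + 1/2 * 1 = 0.875
#' @export
setMethod("tissueEnergy", signature("TissueMesh", "ModelParams"),
  function(mesh, params) {
    cpp_tissue_energy(.meshToList(mesh), .paramsToList(params))
  })

#' Analytic vertex forces
#'
#' Negative gradient of the shape energy with respect to each vertex
#' position: the area term contributes the shoelace gradient
#' (perpendicular of the diagonal between the vertex's cell neighbours),
#' the perimeter term unit vectors along the incident junctions, summed
#' over the cells meeting at the vertex. Clamped vertices report exactly
#' zero force; a zero-length junction's perimeter contribution is
#' dropped (its unit vector is undefined).
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @return matrix with one row per vertex slot and columns `fx`, `fy`
#'   (dead vertices report zero)
#' @export
setMethod("vertexForces", signature("TissueMesh", "ModelParams"),
  function(mesh, params) {
    f <- cpp_vertex_forces(.meshToList(mesh), .paramsToList(params))
    colnames(f) <- c("fx", "fy")
    f
  })

#' Homeostatic cell pressure
#'
#' `P_r^c = -K_A (A_c - A_c0)`: positive for compressed cells (actual
#' area below target), negative for stretched ones.
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @param cells cell ids, or NULL for every live cell
#' @return named numeric vector of pressures
#' @export
setMethod("cellPressure", signature("TissueMesh", "ModelParams"),
  function(mesh, params, cells = NULL) {
    cells <- .checkCells(mesh, cells)
    p <- cpp_cell_pressures(.meshToList(mesh), .paramsToList(params))
    structure(p[cells], names = cells)
  })

# finite-difference gradient of the energy; retained as an independent
# test oracle for the analytic forces (never used by the dynamics)
.numericalForces <- function(mesh, params, h = 1e-6, vertices = NULL) {
  v <- mesh@vertices
  if (is.null(vertices)) vertices <- which(v$alive)
  out <- matrix(0, nrow(v), 2)
  for (i in vertices) {
    if (v$clamped[i]) next
    for (d in 1:2) {
      m1 <- mesh; m2 <- mesh
      if (d == 1) {
        m1@vertices$x[i] <- v$x[i] + h
        m2@vertices$x[i] <- v$x[i] - h
      } else {
        m1@vertices$y[i] <- v$y[i] + h
        m2@vertices$y[i] <- v$y[i] - h
      }
      out[i, d] <- -(tissueEnergy(m1, params) -
                       tissueEnergy(m2, params)) / (2 * h)
    }
  }
  out
}
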