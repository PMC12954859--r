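# Gradient-based minimization, Kabsch superposition RMSD, round-trip
# verification.

#' Minimize a geometry under a restraint dictionary
#'
#' Quasi-Newton (L-BFGS-B via \code{stats::optim}) descent on the
#' restraint energy with its analytic gradient, until the gradient norm
#' falls below tolerance or the iteration budget is exhausted.
#' Deterministic for identical inputs and configuration.
#'
#' @param coords start coordinates (atoms x 3, rownames = atom names).
#' @param dictionary a \code{\linkS4class{RestraintDictionary}}.
#' @param model an \code{\linkS4class{EnergyModel}}.
#' @param config list with \code{max_iter} (default 2000) and
#'   \code{grad_tol} (default 1e-4, energy units per Angstrom).
#' @param elements optional named element vector (see
#'   \code{\link{restraintEnergy}}).
#' @return a \code{\linkS4class{MinimizationResult}}.
#' @export
minimizeGeometry <- function(coords, dictionary, model = EnergyModel(),
                             config = list(), elements = NULL) {
  config <- utils::modifyList(list(max_iter = 2000L, grad_tol = 1e-4),
                              config)
  e0 <- restraintEnergy(coords, dictionary, model, elements)
  if (!is.finite(e0$energy))
    stop("non-finite energy at start: degenerate input geometry",
         call. = FALSE)
  dn <- dimnames(coords)
  fn <- function(x) {
    restraintEnergy(matrix(x, ncol = 3L, dimnames = dn), dictionary,
                    model, elements)$energy
  }
  gr <- function(x) {
    as.vector(restraintEnergy(matrix(x, ncol = 3L, dimnames = dn),
                              dictionary, model, elements)$gradient)
  }
  opt <- stats::optim(as.vector(coords), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iter,
                                     pgtol = config$grad_tol / 10,
                                     factr = 10))
  final <- matrix(opt$par, ncol = 3L, dimnames = dn)
  gnorm <- vnorm(as.vector(restraintEnergy(final, dictionary, model,
                                           elements)$gradient))
  rmsd <- if (nrow(coords) >= 3L) kabschRMSD(coords, final)
          else sqrt(mean(rowSums((coords - final)^2)))
  new("MinimizationResult", startCoords = coords, finalCoords = final,
      rmsdToStart = rmsd,
      nIterations = as.integer(opt$counts[["gradient"]]),
      finalGradNorm = gnorm,
      converged = gnorm < config$grad_tol || opt$convergence == 0L)
}

#' Kabsch superposition RMSD
#'
#' Least-squares optimal rigid superposition (rotation plus translation,
#' proper rotations only -- no reflection) of two coordinate sets over a
#' common atom subset, and the RMSD after superposition.
#'
#' @param coordsA,coordsB coordinate matrices with atom-name rownames.
#' @param atoms atom subset to superpose (default: rownames shared by
#'   both, in \code{coordsA} order).
#' @return the RMSD in Angstrom.
#' @export
kabschRMSD <- function(coordsA, coordsB, atoms = NULL) {
  if (is.null(atoms))
    atoms <- intersect(rownames(coordsA), rownames(coordsB))
  if (length(atoms) < 3L)
    stop("need at least 3 atoms for a superposition", call. = FALSE)
  A <- coordsA[atoms, , drop = FALSE]
  B <- coordsB[atoms, , drop = FALSE]
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Round-trip check of a restraint dictionary
#'
#' Minimizes the source geometry under the dictionary generated from it
#' and reports the Kabsch-superposed RMSD between start and final
#' coordinates.  A self-consistent dictionary reproduces its own ideal
#' geometry (small RMSD); a corrupted ideal value pulls the minimum away
#' from the start and is detected as a large RMSD.
#'
#' @param dictionary a \code{\linkS4class{RestraintDictionary}}.
#' @param component the source \code{\linkS4class{Component}} providing
#'   the starting coordinates (and elements for the nonbonded term).
#' @param model an \code{\linkS4class{EnergyModel}}.
#' @param config minimizer configuration (see
#'   \code{\link{minimizeGeometry}}).
#' @return a \code{\linkS4class{MinimizationResult}}.
#' @examples
#' cc <- makeComponent("benzene")
#' g <- assignHybridization(buildGraph(cc), cc)
#' dict <- buildDictionary(cc, measureGeometry(cc, g), graph = g)
#' roundtripCheck(dict, cc)
#' @export
roundtripCheck <- function(dictionary, component, model = EnergyModel(),
                           config = list()) {
  if (!hasCoords(component))
    stop("component has no coordinates", call. = FALSE)
  el <- stats::setNames(normElement(component@atoms$element),
                        component@atoms$name)
  minimizeGeometry(component@coords, dictionary, model, config,
                   elements = el)
}
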