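#' @include AllClasses.R constructors.R
NULL

# Embedded van der Waals radii (Angstrom) used for SASA; unlisted
# elements fall back to 1.80 A.
.sasaRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

.radiusFor <- function(element) {
  r <- .sasaRadii[toupper(element)]
  r[is.na(r)] <- 1.80
  unname(r)
}

# Deterministic near-uniform sphere points (golden-spiral lattice).
.spherePoints <- function(n = 960L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic test-point SASA: each atom is expanded by the probe radius
#' (default 1.4 A, water) and sampled with a fixed deterministic lattice
#' of sphere points (default 960); a point is accessible if it lies
#' outside every neighbouring expanded sphere. Radii come from an
#' embedded table (C 1.70, N 1.55, O 1.52, S 1.80, others 1.80 A) so
#' results are bit-reproducible.
#'
#' @param model a \code{\linkS4class{StructureModel}}, or an n x 3
#'   coordinate matrix (all atoms then take the fallback radius unless
#'   \code{element} is given)
#' @param element optional element vector overriding the model's
#' @param probe probe radius (A)
#' @param nPoints sphere points per atom
#' @return list with \code{total} (A^2) and \code{perAtom}
#' @export
shrakeRupleySasa <- function(model, element = NULL, probe = 1.4,
                             nPoints = 960L) {
  if (is(model, "StructureModel")) {
    coords <- model@coords
    if (is.null(element)) element <- model@element
  } else {
    coords <- as.matrix(model)
    if (is.null(element)) element <- rep("X", nrow(coords))
  }
  n <- nrow(coords)
  if (n == 0) stop("empty structure: SASA is undefined")
  rad <- .radiusFor(element) + probe
  pts <- .spherePoints(nPoints)
  per <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    per[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  list(total = sum(per), perAtom = per)
}

#' Buried interface area between two structure parts
#'
#' BSA = SASA(A) + SASA(B) - SASA(A union B), by
#' \code{\link{shrakeRupleySasa}}; the convention is the total over both
#' sides (not halved). Non-negative up to the lattice discretisation.
#'
#' @param partA,partB \code{\linkS4class{StructureModel}}s (non-empty,
#'   non-overlapping atom sets)
#' @param probe probe radius (A)
#' @param nPoints sphere points per atom
#' @return buried surface area (A^2)
#' @export
buriedInterfaceArea <- function(partA, partB, probe = 1.4, nPoints = 960L) {
  if (!is(partA, "StructureModel") || !is(partB, "StructureModel"))
    stop("partA and partB must be StructureModel objects")
  if (nrow(partA@coords) == 0 || nrow(partB@coords) == 0)
    stop("empty part: interface area is undefined")
  sa <- shrakeRupleySasa(partA, probe = probe, nPoints = nPoints)$total
  sb <- shrakeRupleySasa(partB, probe = probe, nPoints = nPoints)$total
  both <- structureModel(rbind(partA@coords, partB@coords),
                         element = c(partA@element, partB@element))
  sab <- shrakeRupleySasa(both, probe = probe, nPoints = nPoints)$total
  sa + sb - sab
}
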