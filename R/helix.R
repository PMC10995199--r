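#' @include AllClasses.R constructors.R utils.R
NULL

rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Build a helical filament from a protomer
#'
#' Unit k (k = 0..n-1) is the protomer rotated by k * twist about the
#' z-axis and translated k * rise along z. Under D1 point symmetry each
#' unit additionally carries its C2 mate, generated by a two-fold
#' rotation about an axis perpendicular to z through the unit origin.
#' Unit indices are recorded in the \code{unit} slot; mates are
#' distinguished by subunit suffix.
#'
#' @param protomer a \code{\linkS4class{StructureModel}}
#' @param params a \code{\linkS4class{HelicalParams}}
#' @param nUnits number of helical units (>= 1)
#' @return a \code{\linkS4class{StructureModel}} filament
#' @examples
#' p <- makeToyProtomer(20, 10, seed = 2)
#' fil <- applyHelicalSymmetry(p, helicalParams(-108, 51, "C1"), 5)
#' recoverHelicalParams(fil)$params
#' @export
applyHelicalSymmetry <- function(protomer, params, nUnits) {
  validObject(protomer); validObject(params)
  if (nUnits < 1) stop("nUnits must be >= 1")
  xyz <- protomer@coords
  # C2 about the x-axis (perpendicular to the helix axis)
  c2 <- cbind(xyz[, 1], -xyz[, 2], -xyz[, 3])
  pieces <- list(); n <- nrow(xyz)
  for (k in 0:(nUnits - 1)) {
    R <- rotZ(k * params@twist)
    shift <- c(0, 0, k * params@rise)
    u <- xyz %*% t(R)
    u <- sweep(u, 2, shift, "+")
    pieces[[length(pieces) + 1]] <- list(
      coords = u, subunit = paste0("u", k, "A"), unit = k)
    if (params@pointGroup == "D1") {
      m <- c2 %*% t(R)
      m <- sweep(m, 2, shift, "+")
      pieces[[length(pieces) + 1]] <- list(
        coords = m, subunit = paste0("u", k, "B"), unit = k)
    }
  }
  coords <- do.call(rbind, lapply(pieces, `[[`, "coords"))
  structureModel(
    coords,
    element = rep(protomer@element, length(pieces)),
    chain = rep(vapply(pieces, `[[`, "", "subunit"), each = n),
    subunit = rep(vapply(pieces, `[[`, "", "subunit"), each = n),
    unit = rep(vapply(pieces, function(p) p$unit, 0), each = n))
}

# Rotation matrix -> (angle deg in [0, 180], unit axis), via quaternion
# (robust near 180 deg).
.rotToAxisAngle <- function(R) {
  tr <- sum(diag(R))
  if (tr >= max(diag(R))) {
    s <- sqrt(tr + 1) * 2
    qw <- 0.25 * s
    qv <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / s
  } else {
    i <- which.max(diag(R)); j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    qw <- (R[k, j] - R[j, k]) / s
    qv <- numeric(3)
    qv[i] <- 0.25 * s
    qv[j] <- (R[j, i] + R[i, j]) / s
    qv[k] <- (R[k, i] + R[i, k]) / s
  }
  if (qw < 0) { qw <- -qw; qv <- -qv }
  nv <- sqrt(sum(qv^2))
  angle <- 2 * atan2(nv, qw) * 180 / pi
  axis <- if (nv > 0) qv / nv else c(0, 0, 1)
  list(angle = angle, axis = axis)
}

#' Screw-axis decomposition of the transform superposing two point sets
#'
#' Least-squares rigid superposition (Kabsch) of A onto B, decomposed
#' into a rotation about the screw axis and a translation along it. The
#' axis is oriented so the translation is non-negative; the angle is
#' signed by the right-hand rule about that axis and reported in
#' (-180, 180]. For a pure translation the angle is 0 and the axis
#' points along the translation.
#'
#' @param A,B matched n x 3 coordinate matrices (>= 3 non-collinear
#'   points, same order)
#' @return a \code{\linkS4class{ScrewTransform}}
#' @export
screwDecompose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("A and B must be matched n x 3 matrices")
  if (nrow(A) < 3) stop("at least 3 matched points are required")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  if (qr(Ac, tol = 1e-10)$rank < 2)
    stop("degenerate (collinear) point set: superposition is ambiguous")
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cB - as.numeric(R %*% cA)

  aa <- .rotToAxisAngle(R)
  angle <- aa$angle; axis <- aa$axis
  trans <- sum(t_ * axis)
  if (angle < 1e-9) {
    # pure translation: axis along t
    nt <- sqrt(sum(t_^2))
    axis <- if (nt > 0) t_ / nt else c(0, 0, 1)
    angle <- 0
    trans <- nt
    point <- c(0, 0, 0)
  } else {
    if (trans < 0) { axis <- -axis; angle <- -angle; trans <- -trans }
    # axis point: least-squares solution of (I - R) p = t_perp with
    # p constrained to the plane through the origin normal to the axis
    tperp <- t_ - trans * axis
    M <- diag(3) - R
    G <- t(M) %*% M + axis %*% t(axis)
    point <- as.numeric(solve(G, t(M) %*% tperp))
  }
  fitB <- sweep(A %*% t(R), 2, t_, "+")
  rmsd <- sqrt(mean(rowSums((B - fitB)^2)))
  new("ScrewTransform", angle = wrapAngle(angle), axis = axis,
      point = point, translation = trans, rmsd = rmsd)
}

#' Recover helical parameters from a filament model
#'
#' Screw-decomposes the transform between successive helical units
#' (matched by atom order within units) and reports the circular mean of
#' the rotation angles and the mean translation, together with the
#' per-pair spread.
#'
#' @param filament a \code{\linkS4class{StructureModel}} with >= 2 units
#' @param unitPairs optional 2-column matrix of unit index pairs to
#'   decompose; defaults to all successive pairs
#' @return a list with \code{params} (a
#'   \code{\linkS4class{HelicalParams}}; the point group is not inferred
#'   and is reported as \code{"C1"}), \code{transforms} (per-pair
#'   \code{\linkS4class{ScrewTransform}}s), \code{twistSpread} and
#'   \code{riseSpread} (max absolute deviation from the mean)
#' @export
recoverHelicalParams <- function(filament, unitPairs = NULL) {
  validObject(filament)
  units <- sort(unique(filament@unit[!is.na(filament@unit)]))
  if (length(units) < 2) stop("at least 2 helical units are required")
  counts <- vapply(units, function(u) sum(filament@unit == u), 0L)
  if (length(unique(counts)) != 1)
    stop("units have differing atom counts; match atoms by name per unit ",
         "before recovery")
  if (is.null(unitPairs))
    unitPairs <- cbind(units[-length(units)], units[-1])
  transforms <- apply(unitPairs, 1, function(pr) {
    A <- filament@coords[filament@unit == pr[1], , drop = FALSE]
    B <- filament@coords[filament@unit == pr[2], , drop = FALSE]
    screwDecompose(A, B)
  })
  ang <- vapply(transforms, function(s) s@angle, 0)
  ris <- vapply(transforms, function(s) s@translation, 0)
  # circular mean keeps angles near +/-180 from cancelling
  meanAng <- atan2(mean(sin(ang * pi / 180)),
                   mean(cos(ang * pi / 180))) * 180 / pi
  params <- helicalParams(wrapAngle(meanAng), mean(ris), "C1")
  list(params = params, transforms = transforms,
       twistSpread = max(abs(wrapAngle(ang - meanAng))),
       riseSpread = max(abs(ris - mean(ris))))
}

#' Helical units per 360-degree turn
#'
#' @param twist signed twist in degrees (non-zero)
#' @return list with \code{unitsPerTurn} = 360/|twist| and
#'   \code{nearestInteger} (round-half-up)
#' @examples
#' dimersPerTurn(-108)    # 3.33 -> 3 dimers per turn (basal)
#' dimersPerTurn(-178.6)  # 2.02 -> 2 dimers per turn (activated)
#' @export
dimersPerTurn <- function(twist) {
  if (twist == 0) stop("twist of 0 defines no turn")
  upt <- 360 / abs(twist)
  list(unitsPerTurn = upt, nearestInteger = as.integer(roundHalfUp(upt)))
}
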