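#' @include AllClasses.R constructors.R utils.R
NULL

# Stamp a filled disc into the (logical) canvas; returns linear indices.
discIndices <- function(nr, nc, row0, col0, radius) {
  r1 <- max(1L, floor(row0 - radius)); r2 <- min(nr, ceiling(row0 + radius))
  c1 <- max(1L, floor(col0 - radius)); c2 <- min(nc, ceiling(col0 + radius))
  if (r1 > r2 || c1 > c2) return(integer(0))
  rr <- r1:r2; cc <- c1:c2
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - row0)^2 + (g$c - col0)^2 <= radius^2
  (g$c[keep] - 1L) * nr + g$r[keep]
}

# Rasterise a quadratic Bezier stroke of a given half-thickness.
bezierIndices <- function(nr, nc, p0, p1, p2, halfThick) {
  # chord length in px decides the sampling density
  chord <- sqrt(sum((p2 - p0)^2)) + sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(16L, ceiling(chord * 3)))
  pts <- outer((1 - ts)^2, p0) + outer(2 * (1 - ts) * ts, p1) +
    outer(ts^2, p2)
  idx <- integer(0)
  for (i in seq_along(ts))
    idx <- c(idx, discIndices(nr, nc, pts[i, 1], pts[i, 2], halfThick))
  unique(idx)
}

#' Generate a synthetic multi-channel micrograph with ground truth
#'
#' Draws \code{nCells} cells on a jittered grid (non-overlap enforced by
#' the grid spacing), each with a nucleus disc in the nuclear channel and
#' cytoplasmic reporter objects in the reporter channel: filamented cells
#' carry 1-3 anti-overlapping curved strokes (quadratic Bezier polylines),
#' punctuated cells carry small filled discs. Gaussian read noise of sd
#' \code{noiseSd} is added to both channels. The number of filamented
#' cells is exactly \code{round-half-up(nCells * fracFilamented)};
#' which cells they are is randomised.
#'
#' @param config an \code{\linkS4class{ImageSimConfig}}
#' @param index image index within a cohort; the RNG stream is derived
#'   from \code{(seed, index)} so cohorts are parallel-safe reproducible
#' @param condition optional condition label attached to the image
#' @return a \code{\linkS4class{CellImageSet}} whose \code{groundTruth}
#'   data.frame has one row per cell (columns \code{cell_id},
#'   \code{true_class}, \code{nucleus_row}, \code{nucleus_col},
#'   \code{object_count}), in \code{cell_id} order
#' @export
generateCellImage <- function(config, index = 1L, condition = NA_character_) {
  validObject(config)
  nr <- config@height; nc <- config@width
  px <- config@pixelSize
  n <- config@nCells

  set.seed(deriveSeed(config@seed, index))
  nuclear <- matrix(config@backgroundLevel, nr, nc)
  reporter <- matrix(config@backgroundLevel, nr, nc)
  truth <- matrix(0L, nr, nc)

  labels <- data.frame(cell_id = integer(0), true_class = character(0),
                       nucleus_row = numeric(0), nucleus_col = numeric(0),
                       object_count = integer(0))

  if (n > 0) {
    # jittered grid placement
    g <- ceiling(sqrt(n))
    spacing <- min(nr, nc) / g
    maxNucPx <- config@nucleusRadius[2] / px
    if (spacing < 2 * (maxNucPx + 4))
      stop(sprintf(
        "cannot place %d cells in a %d x %d image: grid spacing %.1f px is below the %.1f px needed per cell (reduce cell density)",
        n, nc, nr, spacing, 2 * (maxNucPx + 4)))
    slots <- expand.grid(gr = seq_len(g), gc = seq_len(g))
    slots <- slots[seq_len(n), , drop = FALSE]
    jitter <- 0.15 * spacing
    rows <- (slots$gr - 0.5) * (nr / g) + runif(n, -jitter, jitter)
    cols <- (slots$gc - 0.5) * (nc / g) + runif(n, -jitter, jitter)

    nFil <- roundHalfUp(n * config@fracFilamented)
    classes <- rep("punctuated", n)
    if (nFil > 0) classes[sample.int(n, nFil)] <- "filamented"

    maxReach <- 0.45 * spacing      # keep objects inside the cell's territory
    objCount <- integer(n)

    for (i in seq_len(n)) {
      nucRadPx <- runif(1, config@nucleusRadius[1], config@nucleusRadius[2]) / px
      nid <- discIndices(nr, nc, rows[i], cols[i], nucRadPx)
      nuclear[nid] <- config@signalLevel

      if (classes[i] == "filamented") {
        k <- sample(seq(config@filamentCount[1], config@filamentCount[2]), 1)
        for (j in seq_len(k)) {
          halfThick <- runif(1, config@filamentThickness[1],
                             config@filamentThickness[2]) / (2 * px)
          # midpoint clear of the (blur-dilated) nucleus mask, stroke
          # oriented tangentially and bowed outward so it wraps around
          # the nucleus instead of crossing it
          off <- nucRadPx + 4 + runif(1, 0, 6)
          lenPx <- runif(1, config@filamentLength[1],
                         config@filamentLength[2]) / px
          lenPx <- min(lenPx, 1.9 * sqrt(max(maxReach^2 - off^2, 25)))
          phi <- runif(1, 0, 2 * pi)
          radial <- c(cos(phi), sin(phi))
          mid <- c(rows[i], cols[i]) + off * radial
          jit <- runif(1, -pi / 7, pi / 7)
          dir <- c(-radial[2], radial[1])
          dir <- c(cos(jit) * dir[1] - sin(jit) * dir[2],
                   sin(jit) * dir[1] + cos(jit) * dir[2])
          curv <- runif(1, config@filamentCurvature[1],
                        config@filamentCurvature[2])
          p0 <- mid - dir * lenPx / 2
          p2 <- mid + dir * lenPx / 2
          p1 <- mid + radial * curv * lenPx / 2
          oid <- bezierIndices(nr, nc, p0, p1, p2, halfThick)
          oid <- setdiff(oid, nid)
          reporter[oid] <- config@signalLevel
          truth[oid] <- i
          objCount[i] <- objCount[i] + 1L
        }
      } else {
        k <- sample(seq(config@punctaCount[1], config@punctaCount[2]), 1)
        for (j in seq_len(k)) {
          rad <- runif(1, config@punctaDiameter[1],
                       config@punctaDiameter[2]) / (2 * px)
          d <- runif(1, nucRadPx + rad + 2, maxReach - rad)
          phi <- runif(1, 0, 2 * pi)
          oid <- discIndices(nr, nc, rows[i] + d * cos(phi),
                             cols[i] + d * sin(phi), rad)
          reporter[oid] <- config@signalLevel
          truth[oid] <- i
          objCount[i] <- objCount[i] + 1L
        }
      }
    }
    labels <- data.frame(cell_id = seq_len(n), true_class = classes,
                         nucleus_row = rows, nucleus_col = cols,
                         object_count = objCount)
  }

  nuclear <- nuclear + matrix(rnorm(nr * nc, 0, config@noiseSd), nr, nc)
  reporter <- reporter + matrix(rnorm(nr * nc, 0, config@noiseSd), nr, nc)

  new("CellImageSet", nuclear = nuclear, reporter = reporter,
      pixelSize = px, labels = labels, truthMask = truth,
      condition = condition)
}

#' Generate a reproducible toy protomer point cloud
#'
#' Returns a rigid pseudo-atomic cloud with distinct inter-point
#' distances (so rigid superposition onto transformed copies is
#' unambiguous), exactly centred at the origin. Used as the asymmetric
#' unit for helical-geometry round trips.
#'
#' @param nPseudoAtoms number of points (>= 3)
#' @param spread Gaussian spread of the cloud (Angstrom)
#' @param seed integer seed; identical calls are bit-identical
#' @return a \code{\linkS4class{StructureModel}} with unit index 0
#' @export
makeToyProtomer <- function(nPseudoAtoms, spread = 10, seed = 1L) {
  if (nPseudoAtoms < 3) stop("at least 3 pseudo-atoms are required")
  set.seed(deriveSeed(as.integer(seed), 0L))
  for (attempt in 1:25) {
    xyz <- matrix(rnorm(nPseudoAtoms * 3, 0, spread), ncol = 3)
    xyz <- sweep(xyz, 2, colMeans(xyz))
    # non-collinear: centred cloud must have rank >= 2
    if (qr(xyz)$rank < 2) next
    d <- dist(xyz)
    if (min(d) < 1e-6 * spread) next
    if (length(d) > 1 && min(diff(sort(d))) < 1e-9 * spread) next
    return(structureModel(xyz, element = "C", chain = "A", unit = 0L))
  }
  stop("could not generate a non-degenerate point cloud")
}
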