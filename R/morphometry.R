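#' @include AllClasses.R constructors.R
NULL

# Accept a logical matrix or an (row, col) coordinate matrix.
.asCoords <- function(mask) {
  if (is.matrix(mask) && ncol(mask) == 2 && !is.logical(mask) &&
      all(mask == round(mask)))
    return(mask)
  which(mask > 0, arr.ind = TRUE)
}

#' Box-counting fractal dimension of an object mask
#'
#' Overlays grids of each box size (anchored at the object's bounding-box
#' origin, single offset), counts the boxes containing at least one
#' foreground pixel, and returns D = -slope of the ordinary
#' least-squares fit of log N(eps) against log eps. Box sizes larger
#' than the bounding box contribute N = 1; sizes where the count repeats
#' are retained (no deduplication). A single pixel therefore has D = 0, a
#' thin line D near 1, a filled region sampled well below its extent D
#' near 2, and a small punctum (plateauing at N = 1 for most sizes) a low
#' D - the contrast the filament/punctum threshold of 0.7 exploits.
#'
#' @param mask logical matrix, or a two-column (row, col) pixel
#'   coordinate matrix
#' @param config a \code{\linkS4class{MorphometryConfig}}
#' @return list with \code{D}, the per-size counts data.frame
#'   (\code{eps}, \code{N}) and \code{flag} (\code{"ok"} or
#'   \code{"few_informative_sizes"} when the bounding box is smaller than
#'   the third box size)
#' @export
boxCountDimension <- function(mask, config = morphometryConfig()) {
  validObject(config)
  xy <- .asCoords(mask)
  if (nrow(xy) == 0) stop("empty mask: fractal dimension is undefined")
  r <- xy[, 1] - min(xy[, 1])
  c_ <- xy[, 2] - min(xy[, 2])
  eps <- config@boxSizes
  N <- vapply(eps, function(e) {
    length(unique(floor(r / e) * 1e9 + floor(c_ / e)))
  }, numeric(1))
  extent <- max(max(r), max(c_)) + 1
  flag <- if (extent < eps[3]) "few_informative_sizes" else "ok"
  D <- if (length(eps) < 2 || all(N == N[1])) 0 else
    -unname(coef(lm(log(N) ~ log(eps)))[2])
  list(D = D, counts = data.frame(eps = eps, N = N), flag = flag)
}

#' Object perimeter by boundary-step counting
#'
#' Counts the exposed edges of the 4-connected object (foreground pixel
#' sides adjacent to background) and multiplies by the pixel size, so a
#' single pixel at 0.3 um/px measures 1.2 um and a 10 x 10 square 12 um.
#'
#' @param mask logical matrix or (row, col) coordinate matrix
#' @param pixelSize um per pixel
#' @return perimeter in um
#' @export
objectPerimeter <- function(mask, pixelSize = 0.3) {
  xy <- .asCoords(mask)
  if (nrow(xy) == 0) stop("empty mask: perimeter is undefined")
  stride <- max(xy[, 2]) + 2
  key <- xy[, 1] * stride + xy[, 2]
  exposed <- 0L
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nk <- (xy[, 1] + d[1]) * stride + (xy[, 2] + d[2])
    exposed <- exposed + sum(!nk %in% key)
  }
  exposed * pixelSize
}

#' Classify one cell by the fractal dimensions of its objects
#'
#' Majority vote: \code{"filamented"} if more objects meet or exceed the
#' D-threshold (default 0.7) than fall below it, \code{"punctuated"} if
#' fewer, \code{"tie"} on equal counts or when the cell has no objects.
#'
#' @param D numeric vector of per-object fractal dimensions (one cell)
#' @param config a \code{\linkS4class{MorphometryConfig}}
#' @return one of \code{"filamented"}, \code{"punctuated"}, \code{"tie"}
#' @export
classifyCellByD <- function(D, config = morphometryConfig()) {
  if (length(D) == 0) return("tie")
  above <- sum(D >= config@dThreshold)
  below <- sum(D < config@dThreshold)
  if (above > below) "filamented" else if (above < below) "punctuated"
  else "tie"
}

#' Classify one cell by the perimeters of its objects
#'
#' Majority vote against the perimeter threshold (default 10 um):
#' \code{"longer"} if most objects meet or exceed it, \code{"shorter"} if
#' most fall below, \code{"tie"} otherwise (including empty cells).
#'
#' @param perimeter numeric vector of per-object perimeters (um)
#' @param config a \code{\linkS4class{MorphometryConfig}}
#' @return one of \code{"longer"}, \code{"shorter"}, \code{"tie"}
#' @export
classifyCellByPerimeter <- function(perimeter, config = morphometryConfig()) {
  if (length(perimeter) == 0) return("tie")
  above <- sum(perimeter >= config@perimeterThreshold)
  below <- sum(perimeter < config@perimeterThreshold)
  if (above > below) "longer" else if (above < below) "shorter" else "tie"
}

#' Measure extracted objects
#'
#' Computes the box-count fractal dimension and boundary-step perimeter
#' for every object returned by \code{\link{extractObjects}}.
#'
#' @param objects the list returned by \code{\link{extractObjects}}
#' @param config a \code{\linkS4class{MorphometryConfig}}
#' @return data.frame (cell_id, object_id, area_px, D, perimeter_um,
#'   d_flag)
#' @export
measureObjects <- function(objects, config = morphometryConfig()) {
  tab <- objects$table
  if (nrow(tab) == 0)
    return(cbind(tab, D = numeric(0), perimeter_um = numeric(0),
                 d_flag = character(0)))
  res <- lapply(objects$pixels, function(px) {
    bc <- boxCountDimension(px, config)
    c(D = bc$D, P = objectPerimeter(px, config@pixelSize),
      flag = bc$flag)
  })
  tab$D <- vapply(res, function(r) as.numeric(r["D"]), numeric(1))
  tab$perimeter_um <- vapply(res, function(r) as.numeric(r["P"]), numeric(1))
  tab$d_flag <- vapply(res, function(r) r[["flag"]], character(1))
  tab
}

#' Classify all cells of a field of view
#'
#' Applies both majority-vote rules per cell. Cells with no measured
#' objects are ties under both rules (and are excluded downstream).
#'
#' @param measured data.frame from \code{\link{measureObjects}}
#' @param nCells total number of segmented cells (cells without objects
#'   are included as ties)
#' @param config a \code{\linkS4class{MorphometryConfig}}
#' @return data.frame (cell_id, n_objects, d_class, perimeter_class,
#'   mean_D, max_perimeter_um)
#' @export
classifyCells <- function(measured, nCells, config = morphometryConfig()) {
  out <- data.frame(cell_id = seq_len(nCells), n_objects = 0L,
                    d_class = "tie", perimeter_class = "tie",
                    mean_D = NA_real_, max_perimeter_um = NA_real_)
  if (nrow(measured) > 0) {
    for (k in unique(measured$cell_id)) {
      sel <- measured$cell_id == k
      out$n_objects[k] <- sum(sel)
      out$d_class[k] <- classifyCellByD(measured$D[sel], config)
      out$perimeter_class[k] <-
        classifyCellByPerimeter(measured$perimeter_um[sel], config)
      out$mean_D[k] <- mean(measured$D[sel])
      out$max_perimeter_um[k] <- max(measured$perimeter_um[sel])
    }
  }
  out
}
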