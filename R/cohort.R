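#' @include AllClasses.R
NULL

#' Summarise per-cell classifications by condition
#'
#' Computes, per image, the fraction of classified cells called
#' filamented (ties and cells without objects are excluded from both
#' numerator and denominator), then the mean and s.e.m. over the images
#' of each condition. The image (field of view) is the replicate unit.
#' Images with zero classified cells are excluded from their condition's
#' replicate list.
#'
#' @param cells data.frame with columns \code{image_id},
#'   \code{condition} and \code{d_class} (or another class column named
#'   via \code{classColumn} whose positive level is
#'   \code{positiveClass})
#' @param classColumn column holding the per-cell call (default
#'   \code{"d_class"})
#' @param positiveClass the level counted in the numerator (default
#'   \code{"filamented"}); everything that is neither positive nor
#'   \code{"tie"} forms the rest of the denominator
#' @return a list with \code{summary}, a data.frame (condition, n_images,
#'   n_cells_classified, frac, sem), and \code{perImage}, a data.frame
#'   (condition, image_id, frac, n_classified)
#' @export
summarizeCondition <- function(cells, classColumn = "d_class",
                               positiveClass = "filamented") {
  stopifnot(all(c("image_id", "condition", classColumn) %in% names(cells)))
  cl <- cells[[classColumn]]
  classified <- cl != "tie"
  perImage <- do.call(rbind, lapply(
    split(seq_len(nrow(cells)), list(cells$condition, cells$image_id),
          drop = TRUE),
    function(idx) {
      n <- sum(classified[idx])
      data.frame(condition = cells$condition[idx[1]],
                 image_id = cells$image_id[idx[1]],
                 frac = if (n > 0) sum(cl[idx] == positiveClass) / n
                        else NA_real_,
                 n_classified = n)
    }))
  rownames(perImage) <- NULL
  excluded <- perImage[perImage$n_classified == 0, , drop = FALSE]
  if (nrow(excluded) > 0)
    message(sprintf("%d image(s) with zero classified cells excluded",
                    nrow(excluded)))
  kept <- perImage[perImage$n_classified > 0, , drop = FALSE]
  summary <- do.call(rbind, lapply(split(kept, kept$condition), function(g) {
    data.frame(condition = g$condition[1], n_images = nrow(g),
               n_cells_classified = sum(g$n_classified),
               frac = mean(g$frac),
               sem = if (nrow(g) > 1) sd(g$frac) / sqrt(nrow(g))
                     else NA_real_)
  }))
  rownames(summary) <- NULL
  list(summary = summary, perImage = kept)
}

#' One-way ANOVA over per-image fractions
#'
#' Standard between/within decomposition with the p-value from the F
#' distribution. Degenerate cases are handled explicitly rather than
#' returning NaN: zero between-group variance gives F = 0, p = 1; zero
#' within-group variance with distinct group means gives p = 0 with a
#' \code{degenerate} flag (synthetic extreme cohorts must not crash the
#' pipeline).
#'
#' @param values numeric response (e.g. per-image filamented fractions)
#' @param group condition factor (>= 2 levels, each with >= 2 values)
#' @return list with \code{F}, \code{p}, \code{dfBetween},
#'   \code{dfWithin}, \code{degenerate}
#' @export
oneWayAnova <- function(values, group) {
  group <- factor(group)
  counts <- table(group)
  if (length(counts) < 2) stop("at least 2 conditions are required")
  if (any(counts < 2))
    stop("condition(s) with fewer than 2 replicates: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  k <- length(counts); n <- length(values)
  gm <- tapply(values, group, mean)
  ssb <- sum(counts * (gm - mean(values))^2)
  ssw <- sum((values - gm[group])^2)
  dfb <- k - 1; dfw <- n - k
  scale <- max(ssb, ssw, .Machine$double.eps)
  if (ssb / scale < 1e-12)
    return(list(F = 0, p = 1, dfBetween = dfb, dfWithin = dfw,
                degenerate = FALSE))
  if (ssw / scale < 1e-12)
    return(list(F = Inf, p = 0, dfBetween = dfb, dfWithin = dfw,
                degenerate = TRUE))
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE),
       dfBetween = dfb, dfWithin = dfw, degenerate = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentised-range comparisons of all condition pairs with family-wise
#' adjustment, based on the pooled within-group variance (the classic
#' follow-up to \code{\link{oneWayAnova}}). With two groups the adjusted
#' p equals the unadjusted pooled-variance two-sample result
#' (q = sqrt(2) |t|).
#'
#' @param values numeric response
#' @param group condition factor (>= 2 levels, each with >= 2 values)
#' @return data.frame (group1, group2, diff, q, pAdj, degenerate)
#' @export
tukeyHsd <- function(values, group) {
  group <- factor(group)
  counts <- table(group)
  if (length(counts) < 2) stop("at least 2 conditions are required")
  if (any(counts < 2))
    stop("condition(s) with fewer than 2 replicates: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  k <- length(counts); n <- length(values)
  gm <- tapply(values, group, mean)
  ssw <- sum((values - gm[group])^2)
  msw <- ssw / (n - k)
  pairs <- utils::combn(names(counts), 2)
  out <- do.call(rbind, apply(pairs, 2, function(pr) {
    d <- gm[pr[2]] - gm[pr[1]]
    se <- sqrt(msw / 2 * (1 / counts[pr[1]] + 1 / counts[pr[2]]))
    if (se == 0) {
      data.frame(group1 = pr[1], group2 = pr[2], diff = unname(d),
                 q = if (d == 0) 0 else Inf,
                 pAdj = if (d == 0) 1 else 0,
                 degenerate = d != 0)
    } else {
      q <- abs(d) / se
      data.frame(group1 = pr[1], group2 = pr[2], diff = unname(d),
                 q = unname(q),
                 pAdj = ptukey(q, nmeans = k, df = n - k,
                               lower.tail = FALSE),
                 degenerate = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}
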