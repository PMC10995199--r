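#' @include AllClasses.R
NULL

# Connected-component labelling of a binary matrix.
# connectivity = 4 uses EBImage::bwlabel (which is 4-connected);
# connectivity = 8 adds diagonal adjacency via igraph components.
labelComponents <- function(mask, connectivity = 4L) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(mask * 1)
    m <- matrix(as.integer(lab), nrow(mask), ncol(mask))
    return(m)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)                       # column-major linear indices
  pos <- match(seq_len(nr * nc), idx)      # linear index -> vertex id
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + d[1]; c2 <- co + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(pos[j])
    from <- which(ok)[keep]
    to <- pos[j[keep]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[idx] <- as.integer(comp)
  out
}

# Rescale to [0, 1] between the given percentiles, clipping outside.
percentileRescale <- function(img, percentiles = c(1, 99.5)) {
  q <- stats::quantile(img, probs = percentiles / 100, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(img), ncol(img)))
  out <- (img - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Deterministic per-image seed derived from a base seed and an index.
# Kept below 2^31 so it is a valid R integer.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 2654435761 + as.double(index) * 40503) %%
               2147483647)
}

# round-half-up (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

# Wrap an angle in degrees into (-180, 180].
wrapAngle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}
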