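# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force box counter: scans every grid cell of every box size.
bruteBoxCounts <- function(coords, sizes) {
  r <- coords[, 1] - min(coords[, 1])
  c_ <- coords[, 2] - min(coords[, 2])
  vapply(sizes, function(e) {
    occ <- 0
    for (br in 0:floor(max(r) / e)) for (bc in 0:floor(max(c_) / e)) {
      if (any(r >= br * e & r < (br + 1) * e &
              c_ >= bc * e & c_ < (bc + 1) * e)) occ <- occ + 1
    }
    occ
  }, numeric(1))
}

bruteBoxDimension <- function(coords, sizes) {
  N <- bruteBoxCounts(coords, sizes)
  if (all(N == N[1])) return(0)
  -unname(coef(lm(log(N) ~ log(sizes)))[2])
}

# Per-pixel boundary walk: counts exposed 4-neighbour edges one by one.
bruteBoundarySteps <- function(coords) {
  steps <- 0L
  for (i in seq_len(nrow(coords))) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- coords[i, ] + d
      if (!any(coords[, 1] == nb[1] & coords[, 2] == nb[2]))
        steps <- steps + 1L
    }
  }
  steps
}

# Analytic buried area of two intersecting spheres (probe-expanded radii
# R1, R2 at centre distance d): sum of the two spherical caps.
twoSphereBuriedArea <- function(R1, R2, d) {
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  2 * pi * R1 * h1 + 2 * pi * R2 * h2
}

# Filled square / disc / line coordinate sets.
coordsSquare <- function(n) as.matrix(expand.grid(seq_len(n), seq_len(n)))
coordsLine <- function(n) cbind(rep(1L, n), seq_len(n))

rotZdeg <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
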