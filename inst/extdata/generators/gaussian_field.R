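#PARNAME: sigma
#LOC: 1,1
#PARNAME: amplitude
#LOC: 2,1
#PARNAME: seed
#LOC: 3,1
#HASWEIGHT
# Gaussian receptive field: connect pair (i, j) with probability
# exp(-d^2 / (2 sigma^2)) where d is their Euclidean distance (um); each
# kept connection carries weight amplitude * exp(-d^2 / (2 sigma^2)).
# Draws are taken in (src-major, dst-minor) order from the seeded stream.
connect <- function(srclocs, dstlocs, sigma, amplitude, seed) {
  ns <- length(srclocs)
  nd <- length(dstlocs)
  sx <- vapply(srclocs, function(q) q[[1]], 0)
  sy <- vapply(srclocs, function(q) q[[2]], 0)
  sz <- vapply(srclocs, function(q) q[[3]], 0)
  dx <- vapply(dstlocs, function(q) q[[1]], 0)
  dy <- vapply(dstlocs, function(q) q[[2]], 0)
  dz <- vapply(dstlocs, function(q) q[[3]], 0)
  set.seed(seed)
  src <- integer(0)
  dst <- integer(0)
  weight <- numeric(0)
  for (i in seq_len(ns)) {
    d2 <- (sx[[i]] - dx)^2 + (sy[[i]] - dy)^2 + (sz[[i]] - dz)^2
    prob <- exp(-d2 / (2 * sigma^2))
    u <- runif(nd)
    hit <- which(u < prob)
    src <- c(src, rep(i - 1, length(hit)))
    dst <- c(dst, hit - 1)
    weight <- c(weight, amplitude * prob[hit])
  }
  list(src = src, dst = dst, weight = weight)
}
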