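#PARNAME: radius
#LOC: 1,1
#PARNAME: velocity
#LOC: 2,1
#PARNAME: base delay
#LOC: 3,1
#HASDELAY
# Connect source i to destination j iff their Euclidean distance is at most
# `radius` (um).  Delay = distance / velocity + base (velocity in um/ms,
# delay in ms).
connect <- function(srclocs, dstlocs, radius, velocity, base) {
  ns <- length(srclocs)
  nd <- length(dstlocs)
  sx <- vapply(srclocs, function(q) q[[1]], 0)
  sy <- vapply(srclocs, function(q) q[[2]], 0)
  sz <- vapply(srclocs, function(q) q[[3]], 0)
  dx <- vapply(dstlocs, function(q) q[[1]], 0)
  dy <- vapply(dstlocs, function(q) q[[2]], 0)
  dz <- vapply(dstlocs, function(q) q[[3]], 0)
  src <- integer(0)
  dst <- integer(0)
  delay <- numeric(0)
  for (i in seq_len(ns)) {
    d <- sqrt((sx[[i]] - dx)^2 + (sy[[i]] - dy)^2 + (sz[[i]] - dz)^2)
    hit <- which(d <= radius)
    src <- c(src, rep(i - 1, length(hit)))
    dst <- c(dst, hit - 1)
    delay <- c(delay, d[hit] / velocity + base)
  }
  list(src = src, dst = dst, delay = delay)
}
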