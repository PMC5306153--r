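# Seeding and small shared helpers.

# Evaluate `code` under a pinned, locally scoped RNG state.  The stream
# algorithm is pinned (Mersenne-Twister / Inversion / Rejection) so seeded
# results are stable across sessions and platforms.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(as.integer(seed) %% .Machine$integer.max,
                            kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  force(code)
}

# Run code while protecting the caller's RNG state (the code may seed and
# draw from its own stream without disturbing the session).
preserve_rng <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# 32-bit FNV-1a hash of a string, used to derive per-object sub-seeds from a
# master seed by stable hashing of an object "path" (e.g. "pop/SD1/tau").
fnv1a32 <- function(text) {
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime, split to stay in exact doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

# Deterministic sub-seed in [1, 2^31 - 2] from a master seed and a path.
derive_seed <- function(master_seed, path) {
  h <- fnv1a32(paste0(path, ":", as.integer(master_seed)))
  as.integer(h %% (2^31 - 2)) + 1L
}

# md5 of a character scalar (base R only hashes files, so spool to a temp
# file).  Used as the cache key for generation recipes.
md5_of_text <- function(text) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(text, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

num_attr <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(default)
  as.numeric(v)
}

chr_attr <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

# Format numbers for XML attributes with full precision.
xnum <- function(x) formatC(x, digits = 17, format = "g")
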