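# Internal helpers shared across modules. Images are numeric matrices in
# [0, 1], indexed [row, col] with the top-left pixel at [1, 1]; physical
# coordinates are in mm, origin at the image top-left, x rightward,
# y downward, pixel centers at (i + 0.5) * mm_per_px.

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.nextPow2 <- function(n) 2L^ceiling(log2(n))

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
.shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Mirror (symmetric, edge-repeating: ... c b a | a b c ... ) index lookup,
# valid for arbitrarily large padding (the reflection tiles periodically).
.mirrorIdx <- function(i, n) {
  j <- ((i - 1L) %% (2L * n)) + 1L
  ifelse(j > n, 2L * n + 1L - j, j)
}

# Pad a matrix by symmetric reflection.
.padReflect <- function(m, top, bottom = top, left = top, right = left) {
  ri <- .mirrorIdx(seq.int(1L - top, nrow(m) + bottom), nrow(m))
  ci <- .mirrorIdx(seq.int(1L - left, ncol(m) + right), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 8-connected components of a logical matrix. Returns the number of
# components and a per-foreground-pixel membership vector (in the order of
# which(mask)). EBImage::bwlabel is 4-connected, hence this routine.
.components8 <- function(mask) {
  idx <- which(mask)
  nf <- length(idx)
  if (nf == 0L) return(list(n = 0L, membership = integer(0), idx = idx))
  nr <- nrow(mask)
  rank <- integer(length(mask))
  rank[idx] <- seq_len(nf)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  # neighbor offsets covering all 8-adjacencies once: E, S, SE, SW
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[j]
    if (any(hit)) {
      from <- rank[idx[ok][hit]]
      to <- rank[j[hit]]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_empty_graph(n = nf, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  list(n = comp$no, membership = as.integer(comp$membership), idx = idx)
}

.countComponents8 <- function(mask) .components8(mask)$n

# Deterministic seed scoping: run `expr` under `seed` and restore the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
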