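## shared internal helpers

## Euclidean k-nearest neighbours by brute force; ties broken by cell index.
## Returns an n x k integer matrix of neighbour indices (self excluded).
.knn_index <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells (k=", k, ", n=", n, ")")
  sq <- rowSums(coords^2)
  ## squared distances in blocks to bound memory
  out <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * coords[rows, , drop = FALSE] %*% t(coords)
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      d <- d2[ii, ]
      d[i] <- Inf
      o <- order(d, seq_len(n))[seq_len(k)]
      out[i, ] <- o
    }
  }
  out
}

## deterministic substream seed from a master seed and a stage name
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

.as_dense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}
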