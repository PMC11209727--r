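# Shared small helpers. Coordinate convention used throughout the package:
# pixels are 0-based and continuous, x grows rightward, y grows downward;
# boxes are closed on the min edge and open on the max edge.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

# Euclidean distance between two matrices of points, rowwise-paired
paired_dist <- function(a, b) {
  sqrt(rowSums((a - b)^2))
}

# Full cross distance matrix between n x 2 and m x 2 point matrices
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

# Minimal union-find used by duplicate grouping in the merging step
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

uf_groups <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}
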