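# Upper-triangle pair bookkeeping.
#
# All voxel-pair matrices (synchronisation theta, differential z) are stored
# once as a dense vector over unordered pairs i < j of voxel ids, in the
# column-major upper-triangle order used by `m[upper.tri(m)]`:
# (1,2), (1,3), (2,3), (1,4), ... so that index(i, j) = (j-1)(j-2)/2 + i.

n_pairs <- function(n) n * (n - 1) / 2

# Linear triangle index for pairs (i, j); order-insensitive.
pair_index <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo < 1L) || any(hi > n) || any(lo == hi)) {
    stop("pair_index: ids must be distinct and within 1..n")
  }
  (hi - 1) * (hi - 2) / 2 + lo
}

# Inverse of pair_index: k -> (i, j) with i < j. Vectorised; uses a float
# solve of j(j-1)/2 >= k with an integer correction step.
index_pairs <- function(k, n) {
  if (any(k < 1) || any(k > n_pairs(n))) stop("index_pairs: index out of range")
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  j <- j - ((j - 1) * (j - 2) / 2 >= k)
  j <- j + (j * (j - 1) / 2 < k)
  i <- k - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}
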