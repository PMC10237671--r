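#' Map a linear test index to an unordered gene pair
#'
#' The exhaustive scan enumerates the `m = n(n-1)/2` unordered pairs of `n`
#' genes by a single 1-based linear index so the work can be split into
#' arbitrary contiguous chunks. For index `i`, with `y = m - i`,
#' `d = 1 + floor((sqrt(8y + 1) - 1) / 2)` and `k = n - d`, the pair is
#' `(k, i + k + d(d+1)/2 - m)`; pairs are emitted in order of the first
#' member. The mapping is a bijection onto all pairs `j1 < j2`, and
#' [linear_index_from_pair()] is its inverse.
#'
#' @param i Vector of 1-based linear indices in `1..n(n-1)/2`.
#' @param n Number of genes (>= 2).
#' @return Integer matrix with columns `j1`, `j2` (`j1 < j2`).
#' @export
#' @examples
#' pair_from_linear_index(1:6, 4)
pair_from_linear_index <- function(i, n) {
  stopifnot(n >= 2)
  m <- n * (n - 1) / 2
  i <- as.numeric(i)
  if (any(i < 1 | i > m | i != floor(i))) {
    stop("index out of range 1..", format(m, scientific = FALSE))
  }
  y <- m - i
  d <- 1 + floor((sqrt(8 * y + 1) - 1) / 2)
  # guard the floating sqrt near triangular-number boundaries
  d <- d - (y < d * (d - 1) / 2) + (y >= d * (d + 1) / 2)
  k <- n - d
  j2 <- i + k + d * (d + 1) / 2 - m
  cbind(j1 = as.integer(k), j2 = as.integer(j2))
}

#' @rdname pair_from_linear_index
#' @param j1,j2 Pair members, `1 <= j1 < j2 <= n`.
#' @export
linear_index_from_pair <- function(j1, j2, n) {
  stopifnot(n >= 2)
  if (any(j1 < 1 | j2 <= j1 | j2 > n)) stop("need 1 <= j1 < j2 <= n")
  m <- n * (n - 1) / 2
  d <- n - j1
  as.numeric(m - d * (d + 1) / 2 + (j2 - j1))
}

#' Contiguous chunking of the linear pair index
#'
#' Splits `1..n(n-1)/2` into `chunks` contiguous ranges whose sizes differ
#' by at most one, mirroring the way an exhaustive scan is distributed over
#' compute nodes. Chunk IDs are 1-based.
#'
#' @param chunk_id Chunk number in `1..chunks`.
#' @param n Number of genes.
#' @param chunks Total chunk count (default 1000).
#' @return Numeric vector `c(from, to)` of linear indices (inclusive);
#'   `to < from` denotes an empty chunk.
#' @export
pair_chunk_range <- function(chunk_id, n, chunks = 1000L) {
  m <- n * (n - 1) / 2
  if (chunk_id < 1 || chunk_id > chunks) {
    stop("chunk_id out of range 1..", chunks)
  }
  base <- floor(m / chunks)
  extra <- m %% chunks
  sizes <- rep(base, chunks) + (seq_len(chunks) <= extra)
  to <- cumsum(sizes)
  from <- to - sizes + 1
  c(from = from[chunk_id], to = to[chunk_id])
}

#' Planned number of pairwise tests
#'
#' `n(n-1)/2` exactly (binomial coefficient), kept in double precision,
#' exact for any realistic gene count.
#'
#' @param n Gene count (vectorized).
#' @return Numeric vector of pair counts.
#' @export
#' @examples
#' pair_count(14729) # 108,464,356
pair_count <- function(n) {
  n <- as.numeric(n)
  n * (n - 1) / 2
}
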