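# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a key
#'
#' Hashes the master seed together with an arbitrary sequence of key
#' components (condition labels, bootstrap indices, ...) into an integer
#' seed below 2^31, so that every stochastic step of a run owns an
#' independent, order-insensitive stream.
#'
#' @param seed Integer master seed.
#' @param ... Key components (coerced to character) identifying the stream.
#' @return A single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  ints <- utf8ToInt(key)
  h <- abs(as.numeric(seed)) %% 2147483647
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  as.integer(h %% 2147483645L + 1L)
}

# Squared Euclidean cross-distance matrix between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# k-nearest-neighbour majority vote; ties broken by the smallest label.
knn_majority <- function(train_coords, train_labels, new_coords, k = 5L) {
  if (nrow(new_coords) == 0L) return(integer(0))
  k <- min(k, nrow(train_coords))
  d2 <- cross_dist2(new_coords, train_coords)
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- table(train_labels[nn])
    as.integer(names(votes)[which.max(votes)])  # which.max -> first (smallest label)
  })
}

# Nearest-centroid assignment; ties broken by the smallest cluster label.
nearest_centroid <- function(centers, x) {
  if (nrow(x) == 0L) return(integer(0))
  d2 <- cross_dist2(x, centers)
  max.col(-d2, ties.method = "first")
}

# Per-column min-max rescaling to [0, 1]; constant columns map to 0.
minmax_fit <- function(x) {
  mn <- apply(x, 2L, min)
  mx <- apply(x, 2L, max)
  list(min = mn, range = pmax(mx - mn, .Machine$double.eps))
}

minmax_apply <- function(mm, x) {
  out <- sweep(sweep(x, 2L, mm$min, "-"), 2L, mm$range, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Map the labels of `from` onto the label space of `ref` by maximum-overlap
# (Hungarian) matching of their contingency table. Both vectors refer to the
# same observations. Returns the relabeled `from`.
match_labels <- function(from, ref) {
  keep <- !is.na(from) & !is.na(ref)
  if (!any(keep)) return(from)
  fl <- sort(unique(from[keep]))
  rl <- sort(unique(ref[keep]))
  m <- max(length(fl), length(rl))
  tab <- matrix(0, m, m)
  tab[seq_along(fl), seq_along(rl)] <-
    as.matrix(table(factor(from[keep], fl), factor(ref[keep], rl)))
  sol <- as.integer(clue::solve_LSAP(tab, maximum = TRUE))
  # padded reference columns get fresh ids for any surplus `from` clusters
  ext <- c(rl, max(rl) + seq_len(max(0L, m - length(rl))))
  mapping <- ext[sol][seq_along(fl)]
  out <- from
  out[!is.na(from)] <- mapping[match(from[!is.na(from)], fl)]
  out
}

stop_if_not_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("`%s` must be a numeric matrix", arg))
  # drop stray attributes (e.g. scale()'s scaled:center) that would leak
  # into downstream model fits
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
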