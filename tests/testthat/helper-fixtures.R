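# Shared fixtures and independent oracles for the test suite.

# Two tight, well-separated Gaussian blobs in `dim` dimensions.
make_blobs <- function(n_per = 30L, dim = 4L, sep = 20, sd = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n_per * dim, 0, sd), n_per)
    b <- matrix(stats::rnorm(n_per * dim, sep, sd), n_per)
  })
  # shift into positive territory so NMF stages see usable structure
  x <- rbind(a, b) + sep
  colnames(x) <- paste0("f", seq_len(dim))
  list(x = x, labels = rep(1:2, each = n_per))
}

# Three tiny well-separated blobs (for 3-cluster recovery checks).
make_blobs3 <- function(n_per = 25L, dim = 3L, sep = 15, sd = 0.05, seed = 2L) {
  # every dimension varies across classes so z-scoring keeps all of them
  # informative (a class-constant column would become pure noise)
  centers <- matrix(0, 3L, dim)
  centers[2L, seq_len(min(2L, dim))] <- sep
  centers[3L, seq.int(min(2L, dim), dim)] <- sep
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(n_per * dim, 0, sd), n_per) +
        matrix(centers[k, ], n_per, dim, byrow = TRUE)))
  })
  x <- x + sep
  colnames(x) <- paste0("f", seq_len(dim))
  list(x = x, labels = rep(1:3, each = n_per))
}

# All set partitions of n items into at most kmax blocks, as label vectors.
all_partitions <- function(n, kmax = n) {
  if (n == 1L) return(list(1L))
  smaller <- all_partitions(n - 1L, kmax)
  out <- list()
  for (p in smaller) {
    m <- max(p)
    for (k in seq_len(min(m + 1L, kmax))) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}

# Brute-force adjusted Rand index by exhaustive pair enumeration.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2L)
  same_a <- a[pairs[1L, ]] == a[pairs[2L, ]]
  same_b <- b[pairs[1L, ]] == b[pairs[2L, ]]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  npairs <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / npairs
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(maxi - expected) < 1e-12) return(as.numeric(abs(n11 - maxi) < 1e-12))
  (n11 - expected) / (maxi - expected)
}

# Brute-force Cramer's V from an explicitly assembled contingency table.
cramers_v_bruteforce <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  if (length(la) < 2L || length(lb) < 2L) return(0)
  n <- length(a)
  tab <- matrix(0, length(la), length(lb))
  for (i in seq_len(n))
    tab[match(a[i], la), match(b[i], lb)] <- tab[match(a[i], la), match(b[i], lb)] + 1
  chi2 <- 0
  for (r in seq_along(la)) for (c in seq_along(lb)) {
    e <- sum(tab[r, ]) * sum(tab[, c]) / n
    chi2 <- chi2 + (tab[r, c] - e)^2 / e
  }
  sqrt(chi2 / n / min(length(la) - 1L, length(lb) - 1L))
}

# Hand-coded Davies-Bouldin oracle following the definition term by term.
dbi_oracle <- function(points, labels) {
  labs <- sort(unique(labels))
  cent <- lapply(labs, function(l) colMeans(points[labels == l, , drop = FALSE]))
  S <- vapply(seq_along(labs), function(i) {
    xi <- points[labels == labs[i], , drop = FALSE]
    mean(apply(xi, 1L, function(r) sqrt(sum((r - cent[[i]])^2))))
  }, numeric(1))
  k <- length(labs)
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# Alternating nonnegative least squares via pracma::lsqnonneg, as an
# independent NMF route for reconstruction-error comparison.
nmf_als_oracle <- function(x, rank, sweeps = 30L, seed = 1L) {
  n <- nrow(x); p <- ncol(x)
  W <- withr::with_seed(seed, matrix(stats::runif(n * rank, 0.1, 1), n))
  H <- matrix(0, rank, p)
  for (s in seq_len(sweeps)) {
    for (j in seq_len(p)) H[, j] <- pracma::lsqnonneg(W, x[, j])$x
    for (i in seq_len(n)) W[i, ] <- pracma::lsqnonneg(t(H), x[i, ])$x
  }
  sqrt(sum((x - W %*% H)^2)) / sqrt(sum(x^2))
}
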