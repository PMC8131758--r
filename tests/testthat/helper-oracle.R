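# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# 8-connected component count by flood fill on a logical matrix
count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- matrix(c(i, j), 1, 2)
    seen[i, j] <- TRUE
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  count
}

# exhaustive one-sided hypergeometric tail by summing the pmf
enum_fisher_greater <- function(mn_d, n_d, mn_c, n_c) {
  m <- mn_d + mn_c
  total <- n_d + n_c
  xs <- max(0, m - n_c):min(m, n_d)
  pmf <- stats::dhyper(xs, m, total - m, n_d)
  sum(pmf[xs >= mn_d])
}

# Gaussian feature blobs with labels: the synthetic ground for embedding and
# prediction tests
make_blobs <- function(n_per, k, dim = 16, sep = 12, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim), k, dim)
  centers <- sep * centers / sqrt(rowSums(centers^2))
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * dim, 0, sd), n_per, dim) +
      matrix(centers[i, ], n_per, dim, byrow = TRUE)))
  list(x = x, y = rep(paste0("class", seq_len(k)), each = n_per))
}

# small easy-mode dataset shared by several tests, built once per run
easy_dataset <- local({
  cache <- NULL
  function(n = 180, seed = 42) {
    if (is.null(cache)) {
      cfg <- synth_config(n, seed = seed, difficulty = "easy")
      cache <<- mnscore:::normalize_dataset(generate_labeled_dataset(cfg))
    }
    cache
  }
})
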