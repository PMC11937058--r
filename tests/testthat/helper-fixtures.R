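# Small configurations reused across tests.

tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(seed = seed, grid_shape = c(24L, 24L),
                                 n_plots = 30L, n_months = 40L), list(...))
  do.call(synthetic_config, args)
}

# constant coefficient fields for hand-built climate cubes
const_coeff_fields <- function(nr, nc, a = 0, b = 0, c = 0.5, k = 1,
                               tem_mean = 8, pre_mean = 60) {
  m <- function(v) matrix(v, nr, nc)
  list(a = m(a), b = m(b), c = m(c), k = m(k),
       tem_mean = m(tem_mean), pre_mean = m(pre_mean))
}

# brute-force Jenks oracle: exhaustive search over all split placements
brute_jenks <- function(x, n_classes = 3) {
  xs <- sort(x)
  n <- length(xs)
  ss <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_breaks <- NULL
  splits <- utils::combn(n - 1, n_classes - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- sum(vapply(seq_len(n_classes),
                      function(m) ss(xs[(cuts[m] + 1):cuts[m + 1]]), 0))
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- xs[splits[, j]]
    }
  }
  list(ssw = best, breaks = best_breaks)
}

# SSW implied by a break set, for comparing optimal partitions with ties
ssw_of_breaks <- function(x, breaks) {
  lab <- findInterval(x, breaks, left.open = TRUE)
  sum(unlist(lapply(split(x, lab), function(v) sum((v - mean(v))^2))))
}
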