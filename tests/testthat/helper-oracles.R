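# Independent oracles and shared fixtures for the test suite.

# Gaussian peak spectrum on the standard axis
gauss_peak <- function(nu, center, hwhm, height) {
  height * exp(-log(2) * (nu - center)^2 / hwhm^2)
}

std_axis <- function(lo = 350, hi = 1825, step = 3) seq(lo, hi, by = step)

trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Monte-Carlo oracle for the Brownian retention probability: draw isotropic
# 3-D Gaussian displacements directly (independent of the closed form)
mc_retention <- function(t_off, diameter_nm, n = 1e5,
                         temperature = 298, viscosity = 0.89e-3,
                         capture_radius_um = 0.5) {
  D <- 1.380649e-23 * temperature / (3 * pi * viscosity * diameter_nm * 1e-9)
  s <- sqrt(2 * D * t_off)
  r2 <- rowSums(matrix(stats::rnorm(3 * n, 0, s), ncol = 3)^2)
  mean(r2 <= (capture_radius_um * 1e-6)^2)
}

# Brute-force O(n^3) Ward oracle: greedy merge minimising the increase in
# total within-cluster sum of squares, recomputed from members at each step;
# ties broken towards the lexicographically smallest pair of smallest
# original member indices (same rule as ward_cluster)
brute_ward_labels <- function(x, k) {
  x <- rbind(x)
  n <- nrow(x)
  cl <- as.list(seq_len(n))
  sse <- function(idx) {
    m <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, m)^2)
  }
  while (length(cl) > k) {
    best <- Inf; bi <- bj <- 0L; bk <- c(Inf, Inf)
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      d <- sse(c(cl[[i]], cl[[j]])) - sse(cl[[i]]) - sse(cl[[j]])
      key <- sort(c(min(cl[[i]]), min(cl[[j]])))
      better <- d < best - 1e-12 ||
        (abs(d - best) <= 1e-12 &&
           (key[1] < bk[1] || (key[1] == bk[1] && key[2] < bk[2])))
      if (better) { best <- d; bi <- i; bj <- j; bk <- key }
    }
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(cl)) lab[cl[[g]]] <- g
  lab
}

# partitions equal up to relabelling
same_partition <- function(a, b) {
  all(outer(a, a, `==`) == outer(b, b, `==`))
}

# small spectra matrix with one contrast band, for chemometrics tests:
# class 1 has the band at `on` amplitude, class 2 at zero
contrast_matrix <- function(n_per_class, on = 1, noise = 0.02, seed = 1) {
  set.seed(seed)
  nu <- std_axis()
  shape_a <- gauss_peak(nu, 700, 10, 1)
  shape_b <- gauss_peak(nu, 1400, 10, 1)
  cls <- rep(1:2, n_per_class)[order(rep(seq_len(n_per_class), 2))]
  cls <- rep_len(c(1L, 2L), 2 * n_per_class)  # interleaved acquisition order
  rows <- t(vapply(cls, function(cl) {
    y <- shape_b + (if (cl == 1L) on * shape_a else 0) +
      stats::rnorm(length(nu), 0, noise)
    y / trapz_oracle(nu, y)
  }, numeric(length(nu))))
  list(x = rows, classes = cls, axis = nu)
}
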