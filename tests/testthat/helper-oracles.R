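# Brute-force oracles kept deliberately independent of the package's
# vectorised / compiled code paths.

# remote stimulus of cell i by a plain double loop over the decay law
brute_remote <- function(i, cells, params) {
  out <- 0
  for (j in seq_len(nrow(cells))) {
    if (j == i) next
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    if (d <= params$d_hat) {
      out <- out + params$M0 * exp(-params$lambda_att * d / params$R)
    }
  }
  out
}

# per-cell summed contact energy by a plain double loop
brute_contact_sum <- function(cells, params) {
  n <- nrow(cells)
  s <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      rsum <- cells$radius[i] + cells$radius[j]
      if (d < rsum) {
        h <- min(rsum - d, rsum - 0.1)
        m <- 4 / (15 * sqrt(2)) * (params$E_c / pi) *
          (h / min(cells$radius[i], cells$radius[j]))^2.5
        s[i] <- s[i] + m
        s[j] <- s[j] + m
      }
    }
  }
  s
}

# the printed normal-approximation interval, written out longhand
brute_ci <- function(v) {
  m <- sum(v) / length(v)
  sdev <- sqrt(sum((v - m)^2) / (length(v) - 1))
  c(m - 1.96 * sdev / sqrt(length(v)), m + 1.96 * sdev / sqrt(length(v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_population <- function(n, params, span = 30, seed = 1) {
  withr::with_seed(seed, {
    cell_population(runif(n, -span, span), runif(n, -span, span),
                    "epithelial", params)
  })
}
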