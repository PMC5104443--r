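# Independent brute-force oracles, deliberately loop-based and kept
# separate from the package's vectorised implementations.

# Double-loop evaluation of the NODF definition: unordered pairs on
# each side, T = overlap / min(degree) unless degrees are equal (or
# both zero), summed and divided by C(C-1)/2 + P(P-1)/2.
nodf_brute <- function(M) {
  side_sum <- function(X) {
    k <- sapply(seq_len(nrow(X)), function(i) sum(X[i, ]))
    s <- 0
    for (i in seq_len(nrow(X) - 1)) {
      for (j in (i + 1):nrow(X)) {
        if (k[i] == k[j] || min(k[i], k[j]) == 0) next
        o <- sum(X[i, ] * X[j, ])
        s <- s + o / min(k[i], k[j])
      }
    }
    s
  }
  (side_sum(M) + side_sum(t(M))) /
    (choose(nrow(M), 2) + choose(ncol(M), 2))
}

degrees_brute <- function(M) {
  list(k_country = sapply(seq_len(nrow(M)), function(i) sum(M[i, ])),
       k_product = sapply(seq_len(ncol(M)), function(j) sum(M[, j])))
}

overlap_brute <- function(M, side = "country") {
  if (side == "product") M <- t(M)
  n <- nrow(M)
  o <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      o[i, j] <- sum(M[i, ] * M[j, ])
    }
  }
  o
}

# Elementwise-loop version of one fitness iteration (the matrix-form
# implementation's oracle).
fitness_step_brute <- function(W, F_prev, Q_prev) {
  n <- nrow(W); m <- ncol(W)
  F_raw <- numeric(n)
  for (c in seq_len(n)) {
    for (p in seq_len(m)) F_raw[c] <- F_raw[c] + W[c, p] * Q_prev[p]
  }
  Q_raw <- numeric(m)
  for (p in seq_len(m)) {
    s <- 0
    for (c in seq_len(n)) s <- s + W[c, p] / max(F_prev[c], 1e-15)
    Q_raw[p] <- 1 / s
  }
  list(F = F_raw / mean(F_raw), Q = Q_raw / mean(Q_raw))
}

random_binary <- function(nr, nc, fill = 0.5) {
  matrix(rbinom(nr * nc, 1, fill), nr, nc)
}

# Small in-memory record fixtures written to temp files.
write_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_production <- function() {
  write_fixture(c(
    "country,product,year,tonnes",
    "A,wheat,2011,100",
    "A,rice,2011,40",
    "A,wheat,2011,60",
    "B,wheat,2011,30",
    "B,maize,2011,0",
    "C,rice,2011,10"
  ))
}

toy_population <- function() {
  write_fixture(c(
    "country,year,persons",
    "A,2011,100",
    "B,2011,600000",
    "C,2011,400000"
  ))
}
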