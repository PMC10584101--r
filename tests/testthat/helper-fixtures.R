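# Shared fixtures and independent oracles, all built in code.

# smallest circular distance between two directions, degrees
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Independent brute-force petal oracle: linear scan over the sequence
# concatenated with itself; runs that start in the first copy are kept, a run
# covering >= n points is the full circle.  Deliberately a different
# algorithm from the package's rotate-then-rle tracer.
oracle_petals <- function(decay, tau) {
  n <- length(decay)
  above <- rep(decay > tau, 2L)
  runs <- list()
  i <- 1L
  while (i <= 2L * n) {
    if (above[i] && (i == 1L && !above[2L * n] || i > 1L && !above[i - 1L])) {
      j <- i
      while (j < 2L * n && above[j + 1L]) j <- j + 1L
      if (i <= n) runs[[length(runs) + 1L]] <- c(start = i, len = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (all(decay > tau)) return(list(c(start = 1L, len = n)))
  # drop runs that are the tail half of a wrapped run (start > n handled
  # above); clip lengths at n and convert to member index sets
  lapply(runs, function(r) {
    idx <- ((r[["start"]] - 1L + seq_len(min(r[["len"]], n)) - 1L) %% n) + 1L
    c(start = idx[1L], len = length(idx))
  })
}

# deterministic tiny profile collection spanning all 9 groups: 2 eyes per
# group, constant-ish profiles
nine_group_profiles <- function(n_points = 16L, per_group = 2L) {
  ages <- c(Age1 = 45, Age2 = 55, Age3 = 65)
  discs <- c(Small = 1.2, Average = 2.0, Large = 3.0)
  vals <- NULL; age <- c(); disc <- c()
  base <- 80
  for (a in ages) for (d in discs) for (k in seq_len(per_group)) {
    vals <- rbind(vals, rep(base + k, n_points))
    age <- c(age, a); disc <- c(disc, d)
  }
  rnfl_profiles(vals, age = age, disc_area = disc, status = "normal")
}

# small synthetic spec for fast cohort tests
fast_spec <- function(...) synthetic_spec(n_points = 64L, ...)

# random decay sequence with some angular smoothness, values in [0, 1]
random_decay <- function(n, smooth = 3L) {
  x <- stats::runif(n)
  if (smooth > 0) {
    idx <- outer(seq_len(n), -smooth:smooth,
                 function(j, o) ((j + o - 1L) %% n) + 1L)
    x <- vapply(seq_len(n), function(j) mean(x[idx[j, ]]), numeric(1))
    x <- (x - min(x)) / (max(x) - min(x) + 1e-12)
  }
  x
}
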