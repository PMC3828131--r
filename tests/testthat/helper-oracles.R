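# Independent brute-force oracles, kept deliberately naive: plain loops over
# observed symbols, no shared code with the package internals.

oracle_entropy <- function(chars) {
  n <- length(chars)
  h <- 0
  for (a in unique(chars)) {
    p <- sum(chars == a) / n
    h <- h - p * log2(p)
  }
  h
}

oracle_joint_entropy <- function(ci, cj) {
  n <- length(ci)
  key <- paste(ci, cj)
  h <- 0
  for (a in unique(key)) {
    p <- sum(key == a) / n
    h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(ci, cj) {
  oracle_entropy(ci) + oracle_entropy(cj) - oracle_joint_entropy(ci, cj)
}

# hypergeometric upper tail P(X >= C) by direct combinatorial summation
oracle_hyper_tail <- function(C, n_marked, universe, n_drawn) {
  tot <- 0
  for (c in seq.int(C, min(n_marked, n_drawn))) {
    tot <- tot + choose(n_marked, c) * choose(universe - n_marked, n_drawn - c)
  }
  tot / choose(universe, n_drawn)
}

# phi coefficient from a 2x2 contingency table built by counting
oracle_phi <- function(u, v) {
  n11 <- sum(u & v); n10 <- sum(u & !v)
  n01 <- sum(!u & v); n00 <- sum(!u & !v)
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(0)
  (n11 * n00 - n10 * n01) / den
}

# Jensen-Shannon divergence (bits) written independently of the package
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) s <- s + 0.5 * p[k] * log2(p[k] / m[k])
    if (q[k] > 0) s <- s + 0.5 * q[k] * log2(q[k] / m[k])
  }
  s
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
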