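# Shared fixture builders; everything is generated in code.

toy_counts <- function(n_otu = 4, n_sample = 4, seed = 7, lambda = 50) {
  set.seed(seed)
  matrix(rpois(n_otu * n_sample, lambda) + 1L, n_otu, n_sample,
         dimnames = list(sprintf("OTU%03d", seq_len(n_otu)),
                         sprintf("s%02d", seq_len(n_sample))))
}

# naive weighted UniFrac: per-branch double loop over sample pairs
naive_weighted_unifrac <- function(counts, tree) {
  P <- sweep(counts, 2, colSums(counts), "/")
  E <- tree$edge
  bl <- tree$edge.length
  ntip <- length(tree$tip.label)
  descend <- function(node) {
    if (node <= ntip) return(node)
    kids <- E[E[, 1] == node, 2]
    unlist(lapply(kids, descend))
  }
  B <- t(sapply(seq_len(nrow(E)), function(i) {
    tips <- tree$tip.label[descend(E[i, 2])]
    colSums(P[tips, , drop = FALSE])
  }))
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(bl * abs(B[, i] - B[, j]))
      den <- sum(bl * (B[, i] + B[, j]))
      d[i, j] <- d[j, i] <- num / den
    }
  }
  d
}

# trapezoid integration oracle for the factorized marginal likelihood
trapezoid_marginal_loglik <- function(coef, sigma2, y, offsets, X,
                                      half_width = 10, n_grid = 4001) {
  eta <- offsets + drop(X %*% coef)
  s <- sqrt(sigma2)
  z <- seq(-half_width * s, half_width * s, length.out = n_grid)
  dz <- z[2] - z[1]
  total <- 0
  for (i in seq_along(y)) {
    f <- dpois(y[i], exp(eta[i] + z)) * dnorm(z, 0, s)
    total <- total + log(sum((f[-1] + f[-length(f)]) / 2) * dz)
  }
  total
}
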