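# Shared oracles and fixtures, all built in code.

# log of integral over [a, b] of prod_i Normal(x_i; mu, s_i^2) d mu (one axis)
log_gauss_prod_integral <- function(x, s, a, b) {
  w <- 1 / s^2
  sw <- sum(w); m <- sum(w * x) / sw; v <- 1 / sw
  lg <- sum(dnorm(x, m, s, log = TRUE)) -
    dnorm(0, 0, sqrt(v), log = TRUE)  # product = g * N(mu; m, v)
  lg + log(pnorm(b, m, sqrt(v)) - pnorm(a, m, sqrt(v)))
}

# All surjective allocation vectors of n items into K labelled groups
surjective_allocations <- function(n, K) {
  z <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  z[apply(z, 1, function(r) length(unique(r)) == K), , drop = FALSE]
}

# Exhaustive posterior over K for the sampler's documented target:
#   P(K, Z) propto Pois(N; K*lambda) * K^-N * prod_i L_i(Z_i) * A^-K,
# restricted to surjective Z, positions integrated over the box exactly.
enumerate_K_posterior <- function(set, lambda, box, K_max = nrow(set)) {
  N <- nrow(set)
  A <- (box[2] - box[1]) * (box[4] - box[3])
  logm <- rep(-Inf, K_max)
  for (K in seq_len(K_max)) {
    z_all <- surjective_allocations(N, K)
    if (nrow(z_all) == 0) next
    lp <- apply(z_all, 1, function(z) {
      sum(vapply(seq_len(K), function(k) {
        ii <- which(z == k)
        log_gauss_prod_integral(set$x[ii], set$sigma_x[ii], box[1], box[2]) +
          log_gauss_prod_integral(set$y[ii], set$sigma_y[ii], box[3], box[4])
      }, numeric(1)))
    })
    lw <- dpois(N, K * lambda, log = TRUE) - N * log(K) - K * log(A)
    logm[K] <- lw + max(lp) + log(sum(exp(lp - max(lp))))
  }
  p <- exp(logm - max(logm))
  p / sum(p)
}

# Monte-Carlo standard error of a proportion from an autocorrelated chain,
# via batch means.
batch_se <- function(ind, n_batch = 30) {
  n <- length(ind)
  bs <- floor(n / n_batch)
  m <- vapply(seq_len(n_batch), function(b) mean(ind[((b - 1) * bs + 1):(b * bs)]),
              numeric(1))
  sd(m) / sqrt(n_batch)
}

# Brute-force neighbor counts within radius r (self excluded)
psi_brute <- function(x, y, r) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    sum(sqrt((x - x[i])^2 + (y - y[i])^2) <= r) - 1L, integer(1))
}

# Brute-force optimal assignment over all permutations (n <= 7), with pairs
# beyond the cutoff removed after assignment of the cutoff-capped cost.
match_brute <- function(truth, est, cutoff) {
  nt <- nrow(truth); ne <- nrow(est)
  d <- as.matrix(stats::dist(rbind(truth, est)))[seq_len(nt), nt + seq_len(ne),
                                                 drop = FALSE]
  dc <- pmin(d, cutoff * 1.0001)
  small <- min(nt, ne)
  if (nt <= ne) {
    perms <- gtools_permutations(ne, small)
    best <- NULL; bestc <- Inf
    for (r in seq_len(nrow(perms))) {
      cost <- sum(dc[cbind(seq_len(small), perms[r, ])])
      if (cost < bestc) { bestc <- cost; best <- perms[r, ] }
    }
    pairs <- data.frame(true = seq_len(small), est = best,
                        distance = d[cbind(seq_len(small), best)])
  } else {
    perms <- gtools_permutations(nt, small)
    best <- NULL; bestc <- Inf
    for (r in seq_len(nrow(perms))) {
      cost <- sum(dc[cbind(perms[r, ], seq_len(small))])
      if (cost < bestc) { bestc <- cost; best <- perms[r, ] }
    }
    pairs <- data.frame(true = best, est = seq_len(small),
                        distance = d[cbind(best, seq_len(small))])
  }
  pairs[pairs$distance <= cutoff, , drop = FALSE]
}

# permutations of k out of n (rows), base R
gtools_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (j in seq_len(k - 1)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(rep(out[r, ], length(rest)), nrow = length(rest),
                   byrow = TRUE), rest)
    }))
  }
  out
}

# environment for results shared between acceptance-criterion tests
.acc_cache <- new.env(parent = emptyenv())
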