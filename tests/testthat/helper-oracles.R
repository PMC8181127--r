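# independent oracles, kept free of the code paths they check

# recursive kinship: f(i,j) = coefficient of coancestry; a_ij = 2 f(i,j)
kinship_recursive <- function(ped) {
  ids <- ped$id
  par <- rbind(ped$parent1, ped$parent2)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    pi <- match(i, ids); pj <- match(j, ids)
    if (pi > pj) { tmp <- i; i <- j; j <- tmp; tmp <- pi; pi <- pj; pj <- tmp }
    if (i == j) {
      p <- par[, pj]
      return(0.5 * (1 + f(p[1L], p[2L])))
    }
    p <- par[, pj]  # j is the later individual
    0.5 * (f(i, p[1L]) + f(i, p[2L]))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- 2 * f(ids[j], ids[i])
  A
}

# brute-force REML maximizer: iteratively refined grid over the variance
# components, scoring with the dense restricted log-likelihood
grid_reml <- function(y, X, Z_list, upper, n_grid = 7L, n_rounds = 4L) {
  k <- length(Z_list)
  lo <- rep(0, k + 1L)
  hi <- rep(upper, k + 1L)
  best <- NULL
  for (round in seq_len(n_rounds)) {
    axes <- lapply(seq_len(k + 1L), function(i)
      seq(lo[i], hi[i], length.out = n_grid))
    grid <- as.matrix(do.call(expand.grid, axes))
    ll <- apply(grid, 1L, function(s2) {
      if (s2[k + 1L] <= 1e-10) return(-Inf)
      restricted_loglik(y, X, Z_list, s2[seq_len(k)], s2[k + 1L])
    })
    best <- grid[which.max(ll), ]
    step <- (hi - lo) / (n_grid - 1L)
    lo <- pmax(0, best - step)
    hi <- best + step
  }
  setNames(best, c(names(Z_list), "residual"))
}

# incidence matrix for a factor
Zmat <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}
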