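# Shared fixtures (memoised per test run) and independent oracles.

fx_env <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(fx_env[[key]])) fx_env[[key]] <- force(expr)
  fx_env[[key]]
}

fx_panel <- function(n = 60, seed = 11) {
  fx_memo(paste("panel", n, seed), generate_panel(n, seed = seed))
}

fx_freqs <- function(n = 60, n_scaffolds = 8, markers_per_scaffold = 25,
                     seed = 11, ...) {
  fx_memo(
    paste("freqs", n, n_scaffolds, markers_per_scaffold, seed, ...),
    simulate_frequencies(fx_panel(n, seed), n_scaffolds, markers_per_scaffold,
      seed = seed, ...)
  )
}

# Moran's I by the definitional double loop.
oracle_moran <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    }
  }
  (n / sum(w)) * num / sum((x - xb)^2)
}

# Benjamini-Hochberg by the O(m^2) definition:
# q_i = min over {j : p_j >= p_i} of p_j * m / rank(p_j).
oracle_bh <- function(p) {
  m <- length(p)
  rnk <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(pmin(p[js] * m / rnk[js], 1))
  }, numeric(1))
}

# Dense GLS with an explicit H inverse: t-test of the last column of W.
oracle_gls_p <- function(y, X0, x, H) {
  y <- as.numeric(y)
  W <- cbind(X0, as.numeric(x))
  n <- length(y)
  Hi <- solve(H)
  A <- crossprod(W, Hi %*% W)
  b <- solve(A, crossprod(W, Hi %*% y))
  r <- y - W %*% b
  df <- n - ncol(W)
  s2 <- drop(crossprod(r, Hi %*% r)) / df
  se <- sqrt(s2 * diag(solve(A)))
  tstat <- drop(b)[ncol(W)] / se[ncol(W)]
  2 * pt(-abs(tstat), df)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- all_perms(n - 1L)
  out <- list()
  for (perm in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
    }
  }
  out
}

# Adjusted means by a direct normal-equations solve of the cell-mean model.
oracle_ls_means <- function(dat) {
  X <- model.matrix(~ 0 + pop_id + block, data = dat)
  b <- solve(crossprod(X), crossprod(X, dat$value))
  pops <- levels(dat$pop_id)
  blocks <- grep("^block", rownames(b), value = TRUE)
  block_avg <- sum(c(0, b[blocks, 1])) / (length(blocks) + 1)
  setNames(b[paste0("pop_id", pops), 1] + block_avg, pops)
}
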