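# Independent oracles used across tests. These deliberately re-derive
# quantities by the dumbest correct route (loops, enumeration, textbook
# formulas) so they share no code with the implementation they check.

# hat-matrix diagonal via explicit pseudoinverse (MASS::ginv)
hat_matrix_scores <- function(M) {
  H <- M %*% MASS::ginv(t(M) %*% M) %*% t(M)
  diag(H)
}

# BH step-up by direct definition: find the largest k with
# p_(k) <= alpha*k/m, reject every p <= p_(k)
brute_force_bh <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- max(c(0, which(ps <= alpha * seq_len(m) / m)))
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

# full row-major enumeration of region pairs (i < j, 0-based)
enumerate_pairs <- function(r) {
  do.call(rbind, lapply(0:(r - 2), function(i) cbind(i = i, j = (i + 1):(r - 1))))
}

# random symmetric unit-diagonal matrix (a genuine correlation matrix)
random_corr <- function(r, t = r + 10, seed = 1) {
  x <- connectoprint:::with_seed(seed, matrix(rnorm(r * t), r, t))
  cor(t(x))
}

# small default synthetic study, memoised per seed for reuse across tests
study_cache <- new.env(parent = emptyenv())
default_study <- function(seed) {
  key <- as.character(seed)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- generate_study(simulation_config(seed = seed))
  }
  study_cache[[key]]
}

full_feature_set <- function(M) feature_set(0:(M$m - 1), m = M$m)
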