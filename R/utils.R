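# Internal numerical helpers.

# Counter-based seed derivation: replicate (b, m) seeds are a deterministic
# function of the master seed, so a replicate is reproducible in isolation
# and the grid is invariant to execution order.  Kept inside 2^31 - 1.
.derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- (master %% 2147483647) + 1
  for (k in seq_along(idx)) {
    # 48271 and 69621 are classic Lehmer multipliers; exact in doubles here
    h <- (h * 48271 + (idx[k] + 1) * 69621 + k) %% 2147483647
  }
  as.integer(h + 1)
}

# Weighted logistic IRLS on a prebuilt model matrix.  Used for the
# imputation conditionals (capped iterations and a weak ridge on the
# non-intercept coefficients: near-deterministic variable pairs such as
# blood/oral tests separate the conditional likelihood, and an unpenalized
# fit saturates the Gibbs transition kernel) and, at full convergence with
# ridge = 0, as the pseudo-MLE solver behind fit_weighted_logistic().
.irls_logistic <- function(x, y, w = NULL, maxit = 25L, tol = 1e-10,
                           ridge = 0, firth = FALSE) {
  if (is.null(w)) w <- rep(1, length(y))
  res <- .irls_logistic_cpp(x, as.numeric(y), as.numeric(w),
                            as.integer(maxit), tol, ridge, firth)
  list(coefficients = drop(res$coefficients),
       converged = res$converged || maxit <= 8L,
       separated = res$separated)
}

# Rank (Mann-Whitney) AUC; ties handled by midranks.
.auc_rank <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Draw one level per row from a matrix of per-level probabilities.
.sample_levels <- function(prob, levels) {
  prob <- prob / rowSums(prob)
  n <- nrow(prob)
  u <- stats::runif(n)
  idx <- rep.int(length(levels), n)
  acc <- numeric(n)
  chosen <- logical(n)
  for (k in seq_along(levels)) {
    acc <- acc + prob[, k]
    hit <- !chosen & u <= acc
    idx[hit] <- k
    chosen <- chosen | hit
  }
  levels[idx]
}

# Categorical draw from a named probability vector, n times.
.rcat <- function(n, prob) {
  names(prob)[findInterval(stats::runif(n), cumsum(prob / sum(prob)),
                           rightmost.closed = TRUE) + 1L]
}

# Solve the intercept a of P(miss) = mean plogis(a + off) = rate on the
# realized offsets, so MAR missingness hits the configured marginal rate.
.mar_intercept <- function(rate, offsets) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  if (all(offsets == 0)) return(stats::qlogis(rate))
  f <- function(a) mean(stats::plogis(a + offsets)) - rate
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}
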