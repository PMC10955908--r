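# Independent Shapley oracle: permutation form. For every ordering of the
# features, the marginal contribution of feature i is v(pred_i U {i}) -
# v(pred_i) where pred_i is the set of features before i in the ordering;
# the Shapley value is the average over all n! orderings. Uses the same
# coalition valuation but none of the power-set enumeration code paths.
shapley_perm_oracle <- function(model, x, background) {
  x <- as.matrix(x)
  n <- ncol(x)
  perms <- gtools_permutations(n)
  ne <- nrow(x)
  v_cache <- new.env(parent = emptyenv())
  value <- function(subset) {
    key <- paste0("s", paste(sort(subset), collapse = ","))
    if (!is.null(v_cache[[key]])) return(v_cache[[key]])
    v_cache[[key]] <- coalition_value(model, x, subset, background)
    v_cache[[key]]
  }
  K <- ncol(value(integer(0)))
  phi <- array(0, dim = c(ne, K, n))
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    pre <- integer(0)
    for (i in ord) {
      phi[, , i] <- phi[, , i] + (value(c(pre, i)) - value(pre))
      pre <- c(pre, i)
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# a tiny trained classifier reused across attribution tests
small_model <- function(k = 3, seed = 5) {
  with_seed(seed, {
    X <- matrix(rnorm(120 * k), 120, k,
                dimnames = list(NULL, paste0("b", 1:k)))
    y <- factor(ifelse(X[, 1] + 0.5 * X[, 2] > 0, "awake", "REM"))
    list(fit = stagenet(X, y, arch = "original", epochs = 20, seed = 2),
         X = X, y = y)
  })
}

# additive "model": f_k(x) = sum_i a_i x_i + c_k, returned per state without
# any softmax, so single-background Shapley values have the closed form
# phi_i = a_i (x_i - b_i).
additive_model <- function(A, const) {
  function(X) {
    out <- as.matrix(X) %*% A
    out + matrix(const, nrow(out), length(const), byrow = TRUE)
  }
}
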