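#' Model prediction under a feature coalition
#'
#' Evaluates the model when only the features in subset `S` are "known":
#' features in `S` keep the epoch's observed values while the remaining
#' features are replaced by background values, averaging the model output over
#' all background rows (the interventional expectation). With the full feature
#' set this is exactly the model prediction; with the empty set it is the
#' background-mean prediction, which for a calibrated model approximates the
#' class prevalences.
#'
#' @param model A fitted [stagenet()], or any function mapping a feature
#'   matrix to a per-row probability matrix.
#' @param x Feature matrix (epochs x features) at which to attribute.
#' @param subset Integer or character vector naming the known features (may be
#'   empty).
#' @param background Background feature matrix (rows x features), e.g. a
#'   seeded sample of training epochs, or a single row of per-subject means
#'   for mean-imputation.
#' @return Matrix epochs x states of probabilities.
#' @export
coalition_value <- function(model, x, subset, background) {
  x <- as.matrix(x); background <- as.matrix(background)
  if (nrow(background) < 1) stop("background must contain at least one row")
  if (ncol(background) != ncol(x))
    stop("background and x must have the same features")
  if (is.character(subset)) subset <- match(subset, colnames(x))
  subset <- as.integer(subset)
  if (length(subset) && (any(is.na(subset)) || any(subset < 1) ||
                         any(subset > ncol(x))))
    stop("subset must index features of x")
  predict_fn <- if (is.function(model)) model else
    function(X) predict(model, X, type = "prob")
  ne <- nrow(x); nb <- nrow(background)
  # rows: for each background row, all epochs with S-columns swapped in
  big <- background[rep(seq_len(nb), each = ne), , drop = FALSE]
  if (length(subset))
    big[, subset] <- x[rep(seq_len(ne), times = nb), subset, drop = FALSE]
  P <- predict_fn(big)
  K <- ncol(P)
  acc <- matrix(0, ne, K, dimnames = list(NULL, colnames(P)))
  for (b in seq_len(nb))
    acc <- acc + P[((b - 1L) * ne + 1L):(b * ne), , drop = FALSE]
  acc / nb
}

#' Exact Shapley attribution of features to class probabilities
#'
#' Computes, for every epoch, state and feature, the exact Shapley value
#' \deqn{\phi_i = \sum_{S \subseteq F \setminus \{i\}}
#'   \frac{|S|!\,(|F|-|S|-1)!}{|F|!}\,[v(S \cup \{i\}) - v(S)]}
#' by enumerating all `2^n` feature coalitions, with the coalition value
#' `v(S)` given by [coalition_value()]. Attribution is on softmax
#' probabilities, so for each epoch and state the feature contributions plus
#' the base value (empty-coalition prediction) sum exactly to the full-model
#' probability (efficiency).
#'
#' @param model A fitted [stagenet()] or a prediction function (see
#'   [coalition_value()]).
#' @param x Feature matrix (epochs x features) to attribute, typically
#'   held-out epochs.
#' @param background Background matrix for the coalition valuation.
#' @param max_features Guard on the power-set size; more than this many
#'   features (default 15) is refused with advice to subsample features or
#'   use a sampling approximation (not implemented here).
#' @return Object of class `shap_array`: list with `values` (3-D array
#'   epochs x states x features), `base` (per-state empty-coalition
#'   prediction) and `prediction` (full-model probabilities).
#' @export
shapley_values <- function(model, x, background, max_features = 15L) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n > max_features)
    stop(sprintf(paste("%d features would need %s coalition evaluations;",
                       "exact enumeration is limited to %d features",
                       "(use a sampling approximation instead)"),
                 n, format(2^n, big.mark = ","), max_features))
  feats <- colnames(x) %||% paste0("x", seq_len(n))
  nmask <- bitwShiftL(1L, n)
  # v[[mask + 1]] = coalition value for the subset encoded by mask bits
  v <- vector("list", nmask)
  for (mask in 0:(nmask - 1L)) {
    subset <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    v[[mask + 1L]] <- coalition_value(model, x, subset, background)
  }
  ne <- nrow(x); K <- ncol(v[[1]])
  states <- colnames(v[[1]])
  # Shapley kernel weight by coalition size |S| (excluding player i)
  wt <- factorial(0:(n - 1L)) * factorial(n - 1L - 0:(n - 1L)) / factorial(n)
  sizes <- vapply(0:(nmask - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L), 0L)
  phi <- array(0, dim = c(ne, K, n), dimnames = list(NULL, states, feats))
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(nmask - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      d <- v[[mask + bit + 1L]] - v[[mask + 1L]]
      phi[, , i] <- phi[, , i] + wt[sizes[mask + 1L] + 1L] * d
    }
  }
  structure(list(values = phi,
                 base = colMeans(v[[1]]),
                 prediction = v[[nmask]]),
            class = "shap_array")
}

#' @export
print.shap_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Shapley attribution: %d epochs x %d states x %d features\n",
              d[1], d[2], d[3]))
  cat("base values:", paste(sprintf("%s=%.3f", names(x$base), x$base),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Long-format Shapley table
#'
#' Flattens a [shapley_values()] result to one row per epoch, state and band,
#' suitable for per-epoch scatter displays or CSV export.
#'
#' @param shap A `shap_array`.
#' @param labels Optional per-epoch true labels added as a `label` column.
#' @return Data.frame with `epoch`, `state`, `band`, `shap` (and `label`).
#' @export
shap_long <- function(shap, labels = NULL) {
  stopifnot(inherits(shap, "shap_array"))
  d <- dim(shap$values)
  out <- expand.grid(epoch = seq_len(d[1]),
                     state = dimnames(shap$values)[[2]],
                     band = dimnames(shap$values)[[3]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$shap <- as.vector(shap$values)
  if (!is.null(labels)) out$label <- as.character(labels)[out$epoch]
  out
}

#' Median absolute Shapley contribution per state and band
#'
#' Summarizes a Shapley array the way band importances are reported: for each
#' state, over the epochs truly belonging to that state, the median of the
#' absolute Shapley value of each band for that state's probability. States
#' with no epochs are omitted with a warning.
#'
#' @param shap A `shap_array` from [shapley_values()].
#' @param labels Per-epoch true class labels (same classes as the model
#'   states).
#' @return Data.frame `state`, `band`, `median_abs_shap`, with a
#'   `wide` attribute holding the state x band matrix.
#' @export
shap_summary <- function(shap, labels) {
  stopifnot(inherits(shap, "shap_array"))
  states <- dimnames(shap$values)[[2]]
  bands <- dimnames(shap$values)[[3]]
  labels <- as.character(labels)
  if (length(labels) != dim(shap$values)[1])
    stop("labels must have one entry per attributed epoch")
  present <- states[states %in% labels]
  missing <- setdiff(states, present)
  if (length(missing))
    warning(sprintf("no epochs for state(s) %s; omitted",
                    paste(missing, collapse = ", ")))
  wide <- matrix(NA_real_, length(present), length(bands),
                 dimnames = list(present, bands))
  for (s in present) {
    rows <- which(labels == s)
    for (b in bands)
      wide[s, b] <- stats::median(abs(shap$values[rows, s, b]))
  }
  out <- expand.grid(state = present, band = bands,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$median_abs_shap <- as.vector(wide[cbind(out$state, out$band)])
  attr(out, "wide") <- wide
  out
}

#' @export
plot.shap_array <- function(x, labels, ...) {
  sm <- shap_summary(x, labels)
  wide <- attr(sm, "wide")
  graphics::matplot(t(wide), type = "b", pch = 16, lty = 1, xaxt = "n",
                    xlab = "band", ylab = "median |SHAP|", ...)
  graphics::axis(1, at = seq_len(ncol(wide)), labels = colnames(wide),
                 las = 2, cex.axis = 0.8)
  graphics::legend("topright", legend = rownames(wide), col = seq_len(nrow(wide)),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
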