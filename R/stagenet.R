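#' Output label schemes
#'
#' Maps the five raw hypnogram stages onto classifier output classes.
#' `three_state` merges all NREM sub-stages into one `NREM` label;
#' `four_state` keeps `NREM1` separate and merges NREM2 with NREM3 into
#' `NREM2&3` (deep-sleep epochs are too scarce in the Parkinsonian population
#' to model NREM3 on its own). `W` maps to `awake` and `R` to `REM` in both.
#'
#' @param name `"three_state"` or `"four_state"`.
#' @return List of class `label_scheme` with `name`, `map` (named character)
#'   and `classes` (output class order).
#' @export
label_scheme <- function(name = c("four_state", "three_state")) {
  name <- match.arg(name)
  map <- if (name == "three_state")
    c(W = "awake", N1 = "NREM", N2 = "NREM", N3 = "NREM", R = "REM")
  else
    c(W = "awake", N1 = "NREM1", N2 = "NREM2&3", N3 = "NREM2&3", R = "REM")
  structure(list(name = name, map = map, classes = unique(unname(map))),
            class = "label_scheme")
}

#' Map raw stages to scheme classes
#'
#' @param stages Character vector of raw stage codes (`W,N1,N2,N3,R`).
#' @param scheme A [label_scheme()].
#' @return Factor with the scheme's class levels.
#' @export
map_stages <- function(stages, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  bad <- setdiff(unique(stages), names(scheme$map))
  if (length(bad))
    stop(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")))
  factor(scheme$map[as.character(stages)], levels = scheme$classes)
}

#' Stratified train/test split of a feature table
#'
#' Splits epochs into disjoint, exhaustive train and test sets. By default the
#' split is stratified by stage within subject, so each stratum contributes
#' `fraction` of its epochs (within one epoch) to the training set. Strata
#' with fewer than 2 epochs are kept whole in the training set, with a
#' warning.
#'
#' @param features Feature data.frame with `subject` and `stage` columns.
#' @param fraction Training fraction, default 0.75.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratify Stratify by subject x stage (default `TRUE`); otherwise a
#'   simple random split.
#' @return List with `train` and `test` data.frames.
#' @export
split_data <- function(features, fraction = 0.75, seed = 1L,
                       stratify = TRUE) {
  stopifnot(nrow(features) >= 4, fraction > 0, fraction < 1)
  n <- nrow(features)
  idx_train <- with_seed(seed, {
    if (!stratify) {
      sample.int(n, round(fraction * n))
    } else {
      strata <- interaction(features$subject, features$stage, drop = TRUE)
      unlist(lapply(levels(strata), function(s) {
        rows <- which(strata == s)
        if (length(rows) < 2) {
          warning(sprintf("stratum %s has < 2 epochs; kept whole in train", s))
          return(rows)
        }
        sample(rows, round(fraction * length(rows)))
      }), use.names = FALSE)
    }
  })
  list(train = features[sort(idx_train), , drop = FALSE],
       test  = features[setdiff(seq_len(n), idx_train), , drop = FALSE])
}

#' Inverse-frequency class weights
#'
#' Weights each class inversely to its frequency in the training labels,
#' `w_c = N / (K * N_c)` with `K` classes and `N` epochs, so a balanced set
#' gets unit weights and the weighted loss reduces to the unweighted one.
#'
#' @param labels Factor (or character) of training labels; every level must
#'   be present.
#' @return Named numeric vector of weights, one per class.
#' @export
class_weights <- function(labels) {
  f <- if (is.factor(labels)) labels else factor(labels)
  counts <- table(f)
  if (any(counts == 0))
    stop(sprintf("class(es) absent from training labels: %s",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  w <- length(f) / (nlevels(f) * as.numeric(counts))
  names(w) <- names(counts)
  w
}

stagenet_spec <- function(arch = c("large", "original"), n_features,
                          n_classes, epochs = NULL, batch_size = 256L,
                          seed = 1L) {
  arch <- match.arg(arch)
  if (arch == "original") {
    spec <- list(arch = arch, hidden = 32L, batchnorm = FALSE, dropout = 0,
                 lr = 1, lr_factor = 1, lr_step = Inf,
                 epochs = epochs %||% 100L)
  } else {
    spec <- list(arch = arch, hidden = c(1000L, 1000L), batchnorm = TRUE,
                 dropout = 0.5, lr = 0.1, lr_factor = 0.5, lr_step = 100L,
                 epochs = epochs %||% 1000L)
  }
  spec$batch_size <- as.integer(batch_size)
  spec$seed <- as.integer(seed)
  spec$n_features <- n_features
  spec$n_classes <- n_classes
  spec
}

# learning rate at (1-based) training epoch e: lr0 * factor^floor((e-1)/step)
stagenet_lr <- function(spec, epoch) {
  if (!is.finite(spec$lr_step)) return(spec$lr)
  spec$lr * spec$lr_factor^((epoch - 1) %/% spec$lr_step)
}

#' Feedforward sleep-stage classifier
#'
#' Fits a fully connected softmax network on normalized band-power features,
#' minimizing inverse-frequency-weighted categorical cross-entropy by plain
#' SGD. Two reference capacities are built in:
#'
#' * `"original"`: one hidden layer of 32 ReLU units, no batchnorm/dropout,
#'   fixed learning rate 1, 100 training epochs.
#' * `"large"`: two hidden layers of 1000 ReLU units, batch normalization and
#'   dropout 0.5 after each hidden layer
#'   (linear -> batchnorm -> ReLU -> dropout), initial learning rate 0.1
#'   halved every 100 epochs, 1000 training epochs. The long schedule
#'   deliberately trains past interpolation (double descent); no early
#'   stopping is used.
#'
#' Weights use He-uniform initialization; training is bit-reproducible given
#' `seed` (fixed initialization, shuffling and dropout masks).
#'
#' @param x Numeric feature matrix (epochs x bands), or a formula.
#' @param y Factor (or character) of class labels, e.g. from [map_stages()].
#' @param arch `"large"` or `"original"`.
#' @param epochs Training epochs; defaults to the architecture's canonical
#'   count (100 original / 1000 large).
#' @param batch_size Minibatch size, default 256.
#' @param weights `"inverse_frequency"` (default), a named numeric vector of
#'   per-class weights, or `NULL` for uniform.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param data,... Formula interface: `stagenet(stage ~ ., data)` where
#'   `stage` holds labels and remaining columns are features.
#' @return Object of class `stagenet` with elements `spec`, `params`,
#'   `classes`, `features`, `loss` (per-epoch training loss) and
#'   `class_weights`.
#' @examples
#' \donttest{
#' xy <- data.frame(a = rnorm(100), b = rnorm(100))
#' y <- factor(ifelse(xy$a > 0, "awake", "REM"))
#' fit <- stagenet(as.matrix(xy), y, arch = "original", epochs = 20)
#' table(predict(fit, as.matrix(xy), type = "class"), y)
#' }
#' @export
stagenet <- function(x, ...) UseMethod("stagenet")

#' @rdname stagenet
#' @export
stagenet.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[, -1, drop = FALSE])
  fit <- stagenet.default(X, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname stagenet
#' @export
stagenet.default <- function(x, y, arch = c("large", "original"),
                             epochs = NULL, batch_size = 256L,
                             weights = "inverse_frequency", seed = 1L,
                             ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must be finite")
  f <- if (is.factor(y)) droplevels(y) else factor(y)
  if (length(f) != nrow(X)) stop("x and y lengths differ")
  classes <- levels(f)
  K <- length(classes)
  spec <- stagenet_spec(arch, ncol(X), K, epochs = epochs,
                        batch_size = batch_size, seed = seed)
  cw <- if (is.null(weights)) {
    stats::setNames(rep(1, K), classes)
  } else if (identical(weights, "inverse_frequency")) {
    class_weights(f)
  } else {
    stopifnot(is.numeric(weights), all(classes %in% names(weights)))
    weights[classes]
  }
  yi <- as.integer(f)
  n <- nrow(X)
  wi <- as.numeric(cw[yi])
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1

  trained <- with_seed(seed, {
    mlp_train(X, Y, wi, as.integer(spec$hidden), spec$batchnorm,
              spec$dropout, spec$lr, spec$lr_factor, spec$lr_step,
              spec$epochs, spec$batch_size)
  })
  params <- trained$params
  loss_hist <- as.numeric(trained$loss)
  fit <- structure(list(spec = spec, params = params, classes = classes,
                        features = colnames(X) %||%
                          paste0("x", seq_len(ncol(X))),
                        loss = loss_hist, class_weights = cw,
                        n_train = n, call = match.call()),
                   class = "stagenet")
  fit$fitted <- predict(fit, X)
  fit
}

stagenet_forward <- function(object, X) {
  p <- object$params; spec <- object$spec
  L <- length(p)
  m <- nrow(X)
  A <- X
  eps <- 1e-5
  for (l in seq_len(L - 1L)) {
    Z <- A %*% p[[l]]$W + rep(p[[l]]$b, each = m)
    if (spec$batchnorm) {
      Z <- (Z - rep(p[[l]]$bn$mean, each = m)) /
        rep(sqrt(p[[l]]$bn$var + eps), each = m)
      Z <- Z * rep(p[[l]]$bn$gamma, each = m) + rep(p[[l]]$bn$beta, each = m)
    }
    A <- Z * (Z > 0)                  # dropout disabled at inference
  }
  Z <- A %*% p[[L]]$W + rep(p[[L]]$b, each = m)
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P / rowSums(P)
}

#' Predict method for stagenet models
#'
#' @param object A fitted [stagenet()].
#' @param newdata Feature matrix or data.frame; band columns must match the
#'   training features (a feature table from [extract_features()] is
#'   subsetted automatically).
#' @param type `"prob"` for the epochs x classes probability matrix (rows sum
#'   to 1) or `"class"` for argmax labels (ties broken by fixed class order).
#' @param ... Unused.
#' @return Probability matrix or factor of class labels.
#' @export
predict.stagenet <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (all(object$features %in% names(newdata)))
      newdata <- newdata[, object$features, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$spec$n_features)
    stop(sprintf("model expects %d features, got %d",
                 object$spec$n_features, ncol(newdata)))
  P <- stagenet_forward(object, newdata)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.stagenet <- function(x, ...) {
  cat(sprintf("stagenet '%s': %s -> softmax(%d classes)\n", x$spec$arch,
              paste(c(x$spec$n_features, x$spec$hidden), collapse = "-"),
              x$spec$n_classes))
  cat(sprintf("  trained %d epochs on %d epochs of data; final loss %.4f\n",
              x$spec$epochs, x$n_train, utils::tail(x$loss, 1)))
  invisible(x)
}

#' @export
summary.stagenet <- function(object, ...) {
  npar <- sum(vapply(object$params, function(p)
    length(p$W) + length(p$b) +
      if (!is.null(p$bn)) 2 * length(p$bn$gamma) else 0L, 0))
  structure(list(spec = object$spec, classes = object$classes,
                 features = object$features, n_parameters = npar,
                 class_weights = object$class_weights,
                 initial_loss = object$loss[1],
                 final_loss = utils::tail(object$loss, 1)),
            class = "summary.stagenet")
}

#' @export
print.summary.stagenet <- function(x, ...) {
  cat(sprintf("stagenet '%s' (%d trainable parameters)\n", x$spec$arch,
              x$n_parameters))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%s=%.3g", names(x$class_weights),
                            x$class_weights), collapse = ", ")))
  cat(sprintf("  training loss %.4f -> %.4f over %d epochs\n",
              x$initial_loss, x$final_loss, x$spec$epochs))
  invisible(x)
}

#' @export
coef.stagenet <- function(object, ...) {
  stats::setNames(lapply(object$params, function(p) p[c("W", "b")]),
                  paste0("layer", seq_along(object$params)))
}

#' @export
plot.stagenet <- function(x, ...) {
  plot(seq_along(x$loss), x$loss, type = "l", xlab = "training epoch",
       ylab = "weighted cross-entropy", main = sprintf(
         "stagenet '%s' training loss", x$spec$arch), ...)
  invisible(x)
}

#' @export
fitted.stagenet <- function(object, ...) object$fitted

#' @export
residuals.stagenet <- function(object, y = NULL, ...) {
  if (is.null(y)) stop("supply the training labels y to compute residuals")
  f <- factor(y, levels = object$classes)
  Y <- matrix(0, length(f), length(object$classes))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y - object$fitted
}
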