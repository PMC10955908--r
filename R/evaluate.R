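#' Confusion matrix and per-class classification metrics
#'
#' Tabulates predictions against truth and derives, per class (one-vs-rest):
#' accuracy `(TP+TN)/n`, sensitivity (= recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1 (harmonic mean of precision
#' and recall), plus the overall error rate `incorrect / (correct +
#' incorrect)`. Classes absent from the truth get `NA` metrics (undefined,
#' not zero).
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param classes Class order; default the union of levels.
#' @return Object of class `confusion_summary`: list with `table`
#'   (predicted x true counts), `metrics` (per-class data.frame),
#'   `error_rate` and `n`.
#' @export
confusion_summary <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  lv <- function(z) if (is.factor(z)) levels(z) else sort(unique(as.character(z)))
  if (is.null(classes)) classes <- union(lv(truth), lv(pred))
  pred <- factor(pred, levels = classes)
  truth <- factor(truth, levels = classes)
  tab <- table(predicted = pred, true = truth)
  n <- sum(tab)
  metrics <- do.call(rbind, lapply(classes, function(cl) {
    tp <- tab[cl, cl]
    fn <- sum(tab[, cl]) - tp
    fp <- sum(tab[cl, ]) - tp
    tn <- n - tp - fn - fp
    if (tp + fn == 0) {             # class absent from truth: undefined
      return(data.frame(class = cl, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, support = 0L))
    }
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    data.frame(class = cl, accuracy = (tp + tn) / n, sensitivity = sens,
               specificity = spec, precision = prec, recall = sens, f1 = f1,
               support = as.integer(tp + fn))
  }))
  rownames(metrics) <- NULL
  structure(list(table = tab, metrics = metrics,
                 error_rate = 1 - sum(diag(tab)) / n, n = n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Confusion summary (n = %d, error rate = %.3f)\n", x$n,
              x$error_rate))
  print(x$table)
  m <- x$metrics
  m[, -c(1, ncol(m))] <- round(m[, -c(1, ncol(m))], digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Per-subject error rates
#'
#' Error rate of the predictions within each subject, with the across-subject
#' mean and standard deviation. The SD convention (population, divisor `n`,
#' the default, or sample, divisor `n-1`) is recorded in the output. Subjects
#' listed but absent from the data are excluded with a warning; with a single
#' subject the spread is reported as `NA`.
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param subject Subject id per epoch.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List of class `subject_errors`: `per_subject` data.frame,
#'   `mean`, `sd`, `sd_type`.
#' @export
per_subject_error <- function(pred, truth, subject,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(pred) == length(truth), length(truth) == length(subject))
  subs <- unique(as.character(subject))
  err <- vapply(subs, function(s) {
    rows <- subject == s
    mean(as.character(pred[rows]) != as.character(truth[rows]))
  }, 0)
  per <- data.frame(subject = subs, error_rate = unname(err),
                    n_epochs = as.integer(table(factor(subject,
                                                       levels = subs))[subs]))
  sdv <- if (length(err) < 2) NA_real_
  else if (sd_type == "population") sqrt(mean((err - mean(err))^2))
  else stats::sd(err)
  structure(list(per_subject = per, mean = mean(err), sd = sdv,
                 sd_type = sd_type),
            class = "subject_errors")
}

#' @export
print.subject_errors <- function(x, ...) {
  cat(sprintf("Per-subject error rate: mean %.3f, %s sd %s\n", x$mean,
              x$sd_type, ifelse(is.na(x$sd), "NA", sprintf("%.3f", x$sd))))
  print(x$per_subject, row.names = FALSE)
  invisible(x)
}

#' Run one experiment cell end-to-end from a raw feature table
#'
#' A single cell of the evaluation grid: optionally restrict to a feature
#' sub-band set, split epochs 75/25 stratified by stage within subject,
#' normalize per subject using training-split statistics only, map raw stages
#' through a label scheme, train a [stagenet()] with inverse-frequency class
#' weights, and summarize held-out performance.
#'
#' @param features Raw (unnormalized) feature table from
#'   [extract_features()]/[extract_cohort_features()].
#' @param arch `"large"` or `"original"`.
#' @param scheme A [label_scheme()] or its name.
#' @param bands Optional character subset of band columns (e.g.
#'   `"high_beta"`, `c("high_beta", "low_gamma")`); default all.
#' @param fraction Training fraction (default 0.75).
#' @param epochs Training epochs override (default: architecture canonical).
#' @param seed Seed controlling split and training; a cell is fully
#'   reproducible from its arguments plus this seed.
#' @param normalization `"train"` (statistics from training split only,
#'   default) or `"full"` (statistics from all epochs, the leakage-prone
#'   variant).
#' @param batch_size Minibatch size passed to [stagenet()].
#' @return Object of class `stage_experiment`: list with `model`,
#'   `confusion` ([confusion_summary()]), `subject_errors`
#'   ([per_subject_error()]), `train` and `test` (normalized feature
#'   tables), `test_truth` and `config`.
#' @export
run_experiment <- function(features, arch = "large",
                           scheme = label_scheme("four_state"),
                           bands = NULL, fraction = 0.75, epochs = NULL,
                           seed = 1L, normalization = c("train", "full"),
                           batch_size = 256L) {
  normalization <- match.arg(normalization)
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  all_bands <- feature_bands(features)
  if (is.null(bands)) bands <- all_bands
  if (!all(bands %in% all_bands))
    stop(sprintf("unknown band(s): %s",
                 paste(setdiff(bands, all_bands), collapse = ", ")))
  feats <- features[, c("subject", "epoch", "stage", bands), drop = FALSE]
  sp <- split_data(feats, fraction = fraction, seed = seed)
  if (normalization == "train") {
    tr <- normalize_features(sp$train)
    te <- normalize_features(sp$test, stats = attr(tr, "stats"))
  } else {
    full <- normalize_features(feats)
    st <- attr(full, "stats")
    tr <- normalize_features(sp$train, stats = st)
    te <- normalize_features(sp$test, stats = st)
  }
  y_tr <- map_stages(tr$stage, scheme)
  y_te <- map_stages(te$stage, scheme)
  fit <- stagenet(as.matrix(tr[, bands, drop = FALSE]), y_tr, arch = arch,
                  epochs = epochs, batch_size = batch_size,
                  seed = child_seed(seed, 17L))
  pred <- predict(fit, as.matrix(te[, bands, drop = FALSE]), type = "class")
  structure(list(model = fit,
                 confusion = confusion_summary(pred, y_te,
                                               classes = scheme$classes),
                 subject_errors = per_subject_error(pred, y_te, te$subject),
                 train = tr, test = te, test_truth = y_te,
                 config = list(arch = arch, scheme = scheme$name,
                               bands = bands, fraction = fraction,
                               epochs = fit$spec$epochs, seed = seed,
                               normalization = normalization)),
            class = "stage_experiment")
}

#' @export
print.stage_experiment <- function(x, ...) {
  cat(sprintf("Experiment cell: %s / %s / %d band(s), seed %d\n",
              x$config$arch, x$config$scheme, length(x$config$bands),
              x$config$seed))
  print(x$confusion)
  invisible(x)
}

#' Sub-band and architecture ablation grid
#'
#' Runs [run_experiment()] over a grid of cells (architecture x label scheme
#' x band subset x seed) on one feature table and collects held-out metrics.
#'
#' @param features Raw feature table.
#' @param cells Data.frame with columns `arch`, `scheme`, `bandset` (name
#'   into `bandsets`) and `seed`.
#' @param bandsets Named list of band-column subsets; `NULL` entries mean all
#'   bands.
#' @param ... Passed to [run_experiment()] (e.g. `epochs`).
#' @return Data.frame of cells with `error_rate`, `macro_f1`, and the list of
#'   `stage_experiment` objects as attribute `experiments`.
#' @export
run_grid <- function(features, cells, bandsets = list(all = NULL), ...) {
  stopifnot(all(c("arch", "scheme", "bandset", "seed") %in% names(cells)))
  exps <- vector("list", nrow(cells))
  out <- cells
  out$error_rate <- NA_real_
  out$macro_f1 <- NA_real_
  for (i in seq_len(nrow(cells))) {
    ex <- run_experiment(features, arch = cells$arch[i],
                         scheme = cells$scheme[i],
                         bands = bandsets[[cells$bandset[i]]],
                         seed = cells$seed[i], ...)
    exps[[i]] <- ex
    out$error_rate[i] <- ex$confusion$error_rate
    out$macro_f1[i] <- mean(ex$confusion$metrics$f1, na.rm = TRUE)
  }
  attr(out, "experiments") <- exps
  out
}

#' Leave-one-subject-out evaluation
#'
#' For each subject, trains on all other subjects and tests on the held-out
#' subject, measuring cross-subject generalization. Normalization of the
#' held-out subject uses that subject's own statistics by default (per-subject
#' scaling is part of the preprocessing contract); `heldout_norm = "pooled"`
#' instead applies the average training-subject statistics.
#'
#' @param features Raw feature table with at least 2 subjects.
#' @param arch,scheme,epochs,seed,batch_size As in [run_experiment()].
#' @param heldout_norm `"self"` (default) or `"pooled"`.
#' @return Object of class `loso_result`: per-fold confusion summaries,
#'   per-subject error data.frame, and across-subject `mean`/`sd`.
#' @export
loso_evaluate <- function(features, arch = "large",
                          scheme = label_scheme("four_state"), epochs = NULL,
                          seed = 1L, batch_size = 256L,
                          heldout_norm = c("self", "pooled")) {
  heldout_norm <- match.arg(heldout_norm)
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  subs <- unique(features$subject)
  if (length(subs) < 2) stop("leave-one-subject-out requires >= 2 subjects")
  bands <- feature_bands(features)
  folds <- lapply(seq_along(subs), function(k) {
    s <- subs[k]
    tr_raw <- features[features$subject != s, , drop = FALSE]
    te_raw <- features[features$subject == s, , drop = FALSE]
    tr <- normalize_features(tr_raw)
    te <- if (heldout_norm == "self") {
      normalize_features(te_raw)
    } else {
      st <- attr(tr, "stats")
      ctr <- rowMeans(vapply(st$subjects, `[[`, numeric(length(bands)),
                             "center"))
      scl <- rowMeans(vapply(st$subjects, `[[`, numeric(length(bands)),
                             "scale"))
      pooled <- list(scale_type = st$scale_type, log_power = st$log_power,
                     subjects = stats::setNames(
                       list(list(center = ctr, scale = scl)), s))
      normalize_features(te_raw, stats = pooled)
    }
    y_tr <- map_stages(tr$stage, scheme)
    y_te <- map_stages(te$stage, scheme)
    fit <- stagenet(as.matrix(tr[, bands, drop = FALSE]), y_tr, arch = arch,
                    epochs = epochs, batch_size = batch_size,
                    seed = child_seed(seed, k))
    pred <- predict(fit, as.matrix(te[, bands, drop = FALSE]), type = "class")
    list(subject = s,
         confusion = confusion_summary(pred, y_te, classes = scheme$classes))
  })
  err <- vapply(folds, function(f) f$confusion$error_rate, 0)
  structure(list(folds = folds,
                 per_subject = data.frame(subject = subs, error_rate = err),
                 mean = mean(err),
                 sd = if (length(err) > 1) stats::sd(err) else NA_real_),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out: %d folds, mean error %.3f (sd %.3f)\n",
              nrow(x$per_subject), x$mean, x$sd))
  print(x$per_subject, row.names = FALSE)
  invisible(x)
}
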