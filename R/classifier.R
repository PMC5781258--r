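#' Prevalence-filtered relative-abundance features
#'
#' Keeps OTUs with a nonzero count in at least `min_prevalence` of the
#' samples (boundary inclusive: exactly 80% passes at the 0.80 default) and
#' returns their per-sample relative abundances as a samples x OTUs feature
#' matrix.
#'
#' @param table an [otu_table].
#' @param min_prevalence fraction of samples an OTU must occur in (default 0.80).
#' @return Numeric matrix, samples x OTUs.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.80) {
  stopifnot(inherits(table, "cs_otu_table"))
  prev <- rowMeans(table$counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("no OTU reaches prevalence ", min_prevalence)
  t(relative_abundance(table)[keep, , drop = FALSE])
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Per class: empirical prior (or uniform), per-feature mean and
#' maximum-likelihood variance with an additive smoothing floor
#' `eps = 1e-9 * max overall feature variance`, so constant features never
#' produce a zero variance.
#'
#' @param features numeric matrix, samples x features.
#' @param labels class label per sample (>= 2 classes, each >= 2 samples).
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return Object of class `gnb` with elements `classes`, `priors`, `means`,
#'   `vars`, `eps`.
#' @export
gnb_fit <- function(features, labels, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  features <- as.matrix(features)
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least two classes")
  if (any(table(f) < 2)) stop("every class needs at least two samples")
  classes <- sort(levels(f))   # deterministic tie-break order
  ml_var <- function(x) mean((x - mean(x))^2)
  means <- matrix(NA_real_, length(classes), ncol(features),
                  dimnames = list(classes, colnames(features)))
  vars <- means
  for (cl in classes) {
    sub <- features[f == cl, , drop = FALSE]
    means[cl, ] <- colMeans(sub)
    vars[cl, ] <- apply(sub, 2, ml_var)
  }
  eps <- 1e-9 * max(apply(features, 2, ml_var), .Machine$double.xmin)
  pri <- if (priors == "uniform") rep(1 / length(classes), length(classes))
         else as.vector(table(f)[classes] / length(f))
  structure(list(classes = classes, priors = setNames(pri, classes),
                 means = means, vars = vars + eps, eps = eps),
            class = "gnb")
}

#' @export
print.gnb <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes: %d classes, %d features\n",
              length(x$classes), ncol(x$means)))
  cat("priors:", paste(sprintf("%s = %.3f", x$classes, x$priors), collapse = ", "), "\n")
  invisible(x)
}

#' Predict treatment labels with a Gaussian naive Bayes model
#'
#' Log-posteriors (`log prior + sum log normal density`) are computed in log
#' space and normalized by log-sum-exp; ties go to the first class in
#' class-name order.
#'
#' @param object a [gnb_fit] model.
#' @param newdata numeric matrix (samples x features) or a single feature
#'   vector; dimension must match the model.
#' @param ... unused.
#' @return List with `label` (character vector) and `posterior`
#'   (samples x classes matrix, rows summing to 1).
#' @export
predict.gnb <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != ncol(object$means))
    stop("feature dimension mismatch: model has ", ncol(object$means),
         ", data has ", ncol(newdata))
  n <- nrow(newdata)
  k <- length(object$classes)
  logpost <- matrix(NA_real_, n, k, dimnames = list(rownames(newdata), object$classes))
  for (j in seq_len(k)) {
    mu <- object$means[j, ]; v <- object$vars[j, ]
    ll <- -0.5 * t((t(newdata) - mu)^2 / v + log(2 * pi * v))
    logpost[, j] <- log(object$priors[j]) + rowSums(ll)
  }
  mx <- apply(logpost, 1, max)
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  label <- object$classes[apply(post, 1, which.max)]   # first max wins ties
  list(label = label, posterior = post)
}

#' Leave-one-out evaluation of the treatment classifier
#'
#' Each sample is predicted by a model fit on all other samples. Besides the
#' full confusion matrix, a collapsed view maps every stress treatment to one
#' "stress" label, asking only whether stressed plants are recognized as
#' stressed.
#'
#' @param features samples x features matrix (see [prevalence_filter]).
#' @param labels class label per sample; every class needs >= 3 samples so
#'   each training fold keeps >= 2.
#' @param control_label label treated as non-stress in the collapsed view.
#' @param priors passed to [gnb_fit].
#' @return Object of class `loo_report`: `predictions` (data.frame with
#'   `sample`, `truth`, `predicted` and per-class posteriors), `confusion`,
#'   `accuracy`, `collapsed_confusion`, `collapsed_accuracy`.
#' @export
loo_evaluate <- function(features, labels, control_label = "control",
                         priors = "empirical") {
  features <- as.matrix(features)
  f <- factor(labels)
  small <- names(which(table(f) < 3))
  if (length(small))
    stop("class(es) with fewer than 3 samples: ", paste(small, collapse = ", "))
  n <- nrow(features)
  classes <- sort(levels(f))
  pred <- character(n)
  post <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    fit <- gnb_fit(features[-i, , drop = FALSE], labels[-i], priors = priors)
    pr <- predict(fit, features[i, , drop = FALSE])
    pred[i] <- pr$label
    post[i, colnames(pr$posterior)] <- pr$posterior
  }
  truth <- as.character(f)
  confusion <- table(truth = factor(truth, classes), predicted = factor(pred, classes))
  collapse <- function(x) ifelse(x == control_label, control_label, "stress")
  coll_levels <- c(control_label, "stress")
  collapsed <- table(truth = factor(collapse(truth), coll_levels),
                     predicted = factor(collapse(pred), coll_levels))
  predictions <- data.frame(sample = rownames(features) %||% seq_len(n),
                            truth = truth, predicted = pred,
                            stringsAsFactors = FALSE)
  predictions <- cbind(predictions, as.data.frame(post))
  structure(list(predictions = predictions, confusion = confusion,
                 accuracy = mean(pred == truth),
                 collapsed_confusion = collapsed,
                 collapsed_accuracy = mean(collapse(pred) == collapse(truth))),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  n <- sum(x$confusion)
  cat(sprintf("leave-one-out: %d/%d correct (accuracy %.2f)\n",
              round(x$accuracy * n), n, x$accuracy))
  cat(sprintf("stress-vs-control collapsed: %d/%d (accuracy %.2f)\n",
              round(x$collapsed_accuracy * n), n, x$collapsed_accuracy))
  print(x$confusion)
  invisible(x)
}
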