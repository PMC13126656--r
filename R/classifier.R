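#' Similarity summary attributes of one sample
#'
#' Collapses a sample's similarities to the training samples into four
#' attributes: mean and SD of similarity to the normal/benign cluster and
#' to the EC/EIN cluster. When the sample *is itself* one of the training
#' samples, pass its index as `self`; its (identically 1) self-similarity
#' is then excluded from its own cluster's mean and SD so it cannot bias
#' them.
#'
#' @param row_sims numeric vector of similarities to the training
#'   samples.
#' @param training_labels factor of length `length(row_sims)` with levels
#'   `normal_benign`, `ec_ein` (in that order).
#' @param self index of this sample within the training set, or `NULL`
#'   for a held-out sample.
#' @return Named numeric vector `(mean_sim_normal, sd_sim_normal,
#'   mean_sim_ecein, sd_sim_ecein)`.
#' @export
similarity_summary <- function(row_sims, training_labels, self = NULL) {
  lab <- factor(training_labels)
  check_that(nlevels(lab) == 2, "training_labels",
             "must have exactly two levels")
  check_that(length(row_sims) == length(lab), "row_sims",
             "must match training_labels in length")
  use <- rep(TRUE, length(row_sims))
  if (!is.null(self)) use[self] <- FALSE
  out <- numeric(4)
  for (g in 1:2) {
    v <- row_sims[use & lab == levels(lab)[g]]
    if (length(v) < 2)
      stop(sprintf("cluster '%s' has fewer than 2 usable training samples",
                   levels(lab)[g]), call. = FALSE)
    out[2 * g - 1] <- mean(v)
    out[2 * g] <- sd(v)
  }
  setNames(out, c("mean_sim_normal", "sd_sim_normal",
                  "mean_sim_ecein", "sd_sim_ecein"))
}

#' Leave-one-out cross-validated similarity classifier
#'
#' For each fold, one sample is held out; the remaining `(n-1) x (n-1)`
#' similarity matrix yields a four-attribute summary
#' ([similarity_summary()]) per training sample (self-similarity excluded
#' from its own cluster), a ridge-stabilized logistic regression is fit
#' on the `(n-1) x 4` training matrix, and the held-out sample is scored
#' from its own four attributes computed against the `n-1` training
#' samples only — the held-out row and column never enter the fold's
#' training inputs. Out-of-fold probabilities are pooled into ROC/AUC and
#' a 0.5-threshold confusion matrix.
#'
#' @param sim a [cosine_similarity()] result with labels, or a
#'   `similarity_matrix`.
#' @param labels optional two-level factor overriding `sim$labels`;
#'   the second level (`ec_ein`) is the positive class.
#' @param lambda ridge penalty of the per-fold logistic fits.
#' @param threshold classification threshold on the predicted
#'   probability.
#' @return An object of class `cv_result`: `prob` (per-sample out-of-fold
#'   probability of the positive class), `labels`, `auc`, `confusion`
#'   (TP/FP/TN/FN at `threshold`), `sensitivity`, `specificity`,
#'   `accuracy`, `coefficients` (n x 5 matrix of per-fold fits),
#'   `threshold`.
#' @export
loocv_similarity <- function(sim, labels = NULL, lambda = 1e-6,
                             threshold = 0.5) {
  if (!inherits(sim, "similarity_matrix"))
    stop("`sim` must be a similarity_matrix", call. = FALSE)
  S <- sim$S
  n <- nrow(S)
  lab <- factor(labels %||% sim$labels)
  check_that(nlevels(lab) == 2, "labels", "must have exactly two levels")
  check_that(length(lab) == n, "labels", "must match the matrix size")
  check_that(n >= 6 && all(table(lab) >= 3), "labels",
             "needs n >= 6 with at least 3 samples per class")

  prob <- numeric(n)
  coefs <- matrix(NA_real_, n, 5,
                  dimnames = list(sim$ids,
                                  c("(Intercept)", "mean_sim_normal",
                                    "sd_sim_normal", "mean_sim_ecein",
                                    "sd_sim_ecein")))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fold <- loocv_fold(S[tr, tr, drop = FALSE], lab[tr], S[i, tr],
                       lambda = lambda)
    coefs[i, ] <- fold$beta
    prob[i] <- fold$prob
  }

  pos <- lab == levels(lab)[2L]
  auc <- roc_auc(prob, lab)
  cm <- confusion_at(prob, lab, threshold = threshold)
  structure(list(prob = setNames(prob, sim$ids), labels = lab, auc = auc,
                 confusion = cm$counts, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, accuracy = cm$accuracy,
                 coefficients = coefs, threshold = threshold),
            class = "cv_result")
}

# One LOOCV fold: the training inputs are exactly the reduced similarity
# matrix `Str`, its labels, and the held-out sample's similarities to the
# training samples — the held-out row/column of the full matrix never
# enters here, which is what makes the cross-validation leakage-free.
loocv_fold <- function(Str, lab_tr, sims_test, lambda = 1e-6) {
  lab_tr <- factor(lab_tr)
  if (nlevels(droplevels(lab_tr)) < 2)
    stop("degenerate fold: training set has a single class", call. = FALSE)
  A <- t(vapply(seq_along(lab_tr), function(j)
    similarity_summary(Str[j, ], lab_tr, self = j), numeric(4)))
  fit <- ridge_logistic(A, as.integer(lab_tr) - 1L, lambda = lambda)
  a_test <- similarity_summary(sims_test, lab_tr, self = NULL)
  list(prob = plogis(drop(c(1, a_test) %*% fit$beta)), beta = fit$beta,
       training = A)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> n = %d, AUC = %.3f\n", length(x$prob), x$auc))
  cat(sprintf("  threshold %.2f: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              x$threshold, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random positive
#' sample scores above a random negative one, with ties counted one half.
#'
#' @param probs numeric scores (higher = more positive).
#' @param labels two-level factor; second level is positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3),
#'         factor(c("pos", "neg", "pos", "neg"), c("neg", "pos")))
#' @export
roc_auc <- function(probs, labels) {
  lab <- factor(labels)
  check_that(nlevels(lab) == 2 && all(table(lab) >= 1), "labels",
             "must contain both classes")
  check_that(length(probs) == length(lab) && all(is.finite(probs)),
             "probs", "must be finite and match labels in length")
  pos <- lab == levels(lab)[2L]
  r <- rank(probs, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a probability threshold
#'
#' @inheritParams roc_auc
#' @param threshold samples with `probs >= threshold` are called
#'   positive.
#' @return List: `counts` (TP, FP, TN, FN), `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
confusion_at <- function(probs, labels, threshold = 0.5) {
  lab <- factor(labels)
  check_that(nlevels(lab) == 2 && all(table(lab) >= 1), "labels",
             "must contain both classes")
  check_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  pos <- lab == levels(lab)[2L]
  call_pos <- probs >= threshold
  tp <- sum(pos & call_pos); fn <- sum(pos & !call_pos)
  tn <- sum(!pos & !call_pos); fp <- sum(!pos & call_pos)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(pos))
}

#' ROC curve points from pooled probabilities
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered for
#'   plotting.
#' @export
roc_points <- function(probs, labels) {
  lab <- factor(labels)
  pos <- lab == levels(lab)[2L]
  th <- c(Inf, sort(unique(probs), decreasing = TRUE), -Inf)
  pts <- t(vapply(th, function(t0) {
    cp <- probs >= t0
    c(fpr = sum(cp & !pos) / sum(!pos), tpr = sum(cp & pos) / sum(pos))
  }, numeric(2)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}
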