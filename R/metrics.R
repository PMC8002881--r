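#' Confusion counts
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @seealso [mcc()], [f1_score()]
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  # stored as doubles: the MCC denominator multiplies four marginals and
  # overflows 32-bit integers on realistically sized site universes
  counts <- c(tp = as.numeric(tp), tn = as.numeric(tn),
              fp = as.numeric(fp), fn = as.numeric(fn))
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(counts), class = "confusion_counts")
}

# counts from scores and labels at a decision threshold (score > threshold
# predicts a site)
counts_at_threshold <- function(scores, labels, threshold = 0.5) {
  pred <- scores > threshold
  confusion_counts(tp = sum(pred & labels == 1L),
                   tn = sum(!pred & labels == 0L),
                   fp = sum(pred & labels == 0L),
                   fn = sum(!pred & labels == 1L))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced binary-classification statistic in \[-1, 1\]. When any marginal
#' factor of the denominator is zero the coefficient is defined as 0 (the
#' 0/0 convention).
#'
#' @param counts A [confusion_counts()].
#' @return MCC in \[-1, 1\].
#' @examples
#' mcc(confusion_counts(tp = 2, tn = 3, fp = 1, fn = 1))  # 5/12
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' F1 score
#'
#' The harmonic mean of precision and recall, `2*TP / (2*TP + FP + FN)`;
#' defined as 0 when the denominator is zero.
#'
#' @param counts A [confusion_counts()].
#' @return F1 in \[0, 1\].
#' @examples
#' f1_score(confusion_counts(tp = 2, tn = 0, fp = 1, fn = 1))  # 2/3
#' @export
f1_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$tn + counts$fp + counts$fn == 0) {
    stop("all confusion counts are zero")
  }
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(0)
  2 * counts$tp / den
}

precision_score <- function(counts) {
  den <- counts$tp + counts$fp
  if (den == 0) 0 else counts$tp / den
}

recall_score <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) 0 else counts$tp / den
}

#' ROC curve
#'
#' Sensitivity (true-positive rate) against 1 - specificity (false-positive
#' rate) over every decision threshold; the curve starts at (0, 0), ends at
#' (1, 1) and is monotone nondecreasing in both coordinates.
#'
#' @param scores Numeric scores (higher = more site-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`, of class
#'   `roc_curve`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  # collapse tied scores: operating points exist only between distinct values
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last_of_tie]
  fp <- cumsum(y == 0L)[last_of_tie]
  out <- data.frame(threshold = c(Inf, s[last_of_tie]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @rdname roc_curve
#' @param curve A `roc_curve`.
#' @return `auc_trapezoid()`: area under the curve by the trapezoidal rule.
#' @export
auc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (curve$tpr[-1L] + curve$tpr[-nrow(curve)]) / 2)
}

# AUC as the Mann-Whitney probability that a random positive outscores a
# random negative, ties counting one half (midrank formulation)
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores)  # average ranks for ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC AUC with bootstrap confidence interval
#'
#' The AUC is computed as the Mann-Whitney probability that a random
#' positive outscores a random negative (ties count one half); this equals
#' the trapezoidal integral of the ROC curve. The 95% confidence interval
#' is a seeded stratified bootstrap (resampling positives and negatives
#' separately) with the percentile method.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param n_boot Bootstrap resamples (default 2000; 0 skips the interval).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @return List of class `roc_result`: `auc`, `ci` (lower/upper), `curve`,
#'   `n_pos`, `n_neg`, `n_boot`, `seed`.
#' @examples
#' r <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), n_boot = 200)
#' r$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L, conf = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  auc <- auc_mann_whitney(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    ipos <- which(labels == 1L)
    ineg <- which(labels == 0L)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ipos, length(ipos), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
      auc_mann_whitney(scores[i], labels[i])
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE))
    # percentile interval may not cover the point estimate on tiny samples;
    # widen so the reported triple is always ordered
    ci[1L] <- min(ci[1L], auc)
    ci[2L] <- max(ci[2L], auc)
  }
  structure(list(auc = auc, ci = ci, curve = roc_curve(scores, labels),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("AUC ", format(x$auc, digits = 4),
      if (!anyNA(x$ci)) paste0(" (95% CI ", format(x$ci[1], digits = 4), "-",
                               format(x$ci[2], digits = 4), ", ", x$n_boot,
                               " bootstrap resamples)"),
      "; ", x$n_pos, " positives / ", x$n_neg, " negatives\n", sep = "")
  invisible(x)
}

#' Evaluate a cleavage-site predictor against ground truth
#'
#' Works identically for this package's ensemble predictions and for any
#' external predictor's score table (`protein_id`, `p1`, `score`). The
#' candidate universe is every inter-residue bond of the truth proteins;
#' candidates missing from the score table are scored 0 with a warning.
#' Threshold metrics (MCC, F1, precision, recall) use `score > threshold`;
#' AUC is threshold-free with a stratified bootstrap confidence interval.
#'
#' @param scores Score `data.frame` (`protein_id`, `p1`, `score`).
#' @param truth Annotation `data.frame` holding the true sites (filtered to
#'   `protease` when that column is present).
#' @param proteins Named list of [protein_record()]s defining the candidate
#'   universe.
#' @param protease Protease identifier being evaluated.
#' @param threshold Decision threshold for the counted metrics (default 0.5).
#' @param n_boot,seed Bootstrap settings for the AUC interval.
#' @return Object of class `metrics_report`: `mcc`, `f1`, `precision`,
#'   `recall`, `auc`, `auc_ci`, `n_pos`, `n_neg`, `counts`, `threshold`.
#' @export
evaluate_predictor <- function(scores, truth, proteins, protease,
                               threshold = 0.5, n_boot = 2000L, seed = 1L) {
  if ("protease" %in% names(truth)) {
    truth <- truth[truth$protease == protease, , drop = FALSE]
  }
  cand <- do.call(rbind, lapply(proteins, function(p) {
    cs <- candidate_sites(p)
    if (length(cs) == 0L) return(NULL)
    data.frame(protein_id = p$id, p1 = cs, stringsAsFactors = FALSE)
  }))
  key <- function(d) paste(d$protein_id, d$p1)
  labels <- as.integer(key(cand) %in% key(truth))
  if (sum(labels) == 0L) stop("no truth positives among the candidate sites")
  sc <- scores$score[match(key(cand), key(scores))]
  n_missing <- sum(is.na(sc))
  if (n_missing > 0L) {
    warning(n_missing, " candidate site(s) missing from the score table; scored 0")
    sc[is.na(sc)] <- 0
  }
  counts <- counts_at_threshold(sc, labels, threshold)
  roc <- roc_auc(sc, labels, n_boot = n_boot, seed = seed)
  structure(list(mcc = mcc(counts), f1 = f1_score(counts),
                 precision = precision_score(counts),
                 recall = recall_score(counts),
                 auc = roc$auc, auc_ci = roc$ci, roc = roc,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 counts = counts, threshold = threshold, protease = protease),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", if (!is.null(x$protease)) x$protease, "\n",
      sprintf("  AUC %.4f (95%% CI %.4f-%.4f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]),
      sprintf("  MCC %.4f  F1 %.4f  precision %.4f  recall %.4f (threshold %g)\n",
              x$mcc, x$f1, x$precision, x$recall, x$threshold),
      sprintf("  %d positives / %d negatives\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Two-sided equal-variance t-test with `df = n_a + n_b - 2`, used e.g. to
#' compare predicted susceptibilities between proteins with and without
#' experimentally detected cleavage sites.
#'
#' @param values_a,values_b Numeric vectors (each `n >= 2`).
#' @return List with `t`, `p`, `df`.
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(3, 4, 5, 6))  # t ~ -2.191, p ~ 0.0707
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  pooled <- ((length(values_a) - 1) * stats::var(values_a) +
             (length(values_b) - 1) * stats::var(values_b))
  if (pooled == 0) stop("zero pooled variance: groups are constant")
  ht <- t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
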