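# Performance statistics: recall, precision, Matthews correlation, two-class
# accuracy (Q2), F1, ROC/AUC, and a paired-bootstrap AUC comparison.

#' Truncate to two decimals
#'
#' Display convention for reported metrics: full precision is stored, two
#' decimals are shown by truncation (not rounding).
#' @param x Numeric.
#' @return `x` truncated towards zero at the second decimal.
#' @export
trunc2 <- function(x) trunc(x * 100 + sign(x) * 1e-9) / 100

#' F1 score from precision and recall
#' @param precision,recall Scalars in `[0, 1]`.
#' @return `2 * P * R / (P + R)`, or 0 when both are 0.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Confusion counts and threshold metrics
#'
#' Scores at or above the threshold call an interface residue.  MCC is
#' defined as 0 when any confusion-matrix marginal is 0; precision is
#' reported as 0 (flagged) when nothing is predicted positive.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Logical labels, same length (every scored residue must be
#'   labeled).
#' @param threshold Classification threshold (default 0.5).
#' @return An `eval_report`: counts (`tp`, `fp`, `tn`, `fn`) and `recall`,
#'   `precision`, `mcc`, `q2`, `f1`, `threshold`.
#' @export
confusion_and_rates <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scored residues must all be labeled (no missing values)")
  }
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  p_flag <- (tp + fp) == 0
  precision <- if (p_flag) 0 else tp / (tp + fp)
  q2 <- (tp + tn) / length(labels)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) /
           sqrt(denom) else 0
  out <- list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
              recall = recall, precision = precision, mcc = mcc, q2 = q2,
              f1 = f1_score(precision, recall), threshold = threshold,
              precision_undefined = p_flag)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Binding-site prediction report (threshold ", x$threshold, ")\n",
      sep = "")
  cat("  counts: TP=", x$counts["tp"], " FP=", x$counts["fp"],
      " TN=", x$counts["tn"], " FN=", x$counts["fn"], "\n", sep = "")
  cat(sprintf("  R=%.2f P=%.2f MCC=%.2f Q2=%.2f F1=%.2f\n",
              trunc2(x$recall), trunc2(x$precision), trunc2(x$mcc),
              trunc2(x$q2), trunc2(x$f1)))
  if (x$precision_undefined) cat("  (no positive predictions; P reported as 0)\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank tie correction;
#' it equals the trapezoidal area under the step ROC curve.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels; both classes must be present.
#' @return List with `roc` (data frame of `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  rk <- rank(scores)  # midranks for ties
  auc <- (sum(rk[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))  # tie groups share one operating point
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos))
  list(roc = roc, auc = auc)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Residues are resampled with replacement; both AUCs are recomputed on each
#' replicate, giving a bootstrap distribution of the AUC difference, a
#' percentile confidence interval and a two-sided p-value for the null of
#' equal AUCs.  Deterministic given the seed.
#'
#' @param scores_a,scores_b Two score vectors over the same residues.
#' @param labels Logical labels.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Random seed.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List: `delta_auc` (`auc_a - auc_b`), `auc_a`, `auc_b`,
#'   `p_value`, `ci` (length-2), `n_boot`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, n_boot = 2000, seed = 1,
                        conf_level = 0.95) {
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("score sets must cover the same residues as the labels")
  }
  labels <- as.logical(labels)
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  delta <- auc_a - auc_b
  n <- length(labels)
  set.seed(seed)
  d_boot <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
    }
    d_boot[r] <- roc_auc(scores_a[idx], labels[idx])$auc -
                 roc_auc(scores_b[idx], labels[idx])$auc
  }
  # two-sided p from the bootstrap distribution of the difference
  p <- 2 * min((sum(d_boot <= 0) + 1) / (n_boot + 1),
               (sum(d_boot >= 0) + 1) / (n_boot + 1))
  p <- min(1, p)
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(d_boot, c(alpha / 2, 1 - alpha / 2)))
  list(delta_auc = delta, auc_a = auc_a, auc_b = auc_b, p_value = p,
       ci = ci, n_boot = n_boot)
}

#' Structure-wise cross-validated scores
#'
#' Outer cross-validation with folds split by structure (never by residue):
#' each fold's structures are scored by a model trained on the remaining
#' structures.
#'
#' @inheritParams vorsite
#' @param folds Number of outer folds (capped at the number of units).
#' @return Data frame with `unit`, `res_index`, `label`,
#'   `first_step_score`, `final_score` for every exposed residue.
#' @export
vorsite_cv <- function(units, env = env_config(),
                       groups = c("s", "e", "c", "b"), folds = 5, seed = 1,
                       ntree = 500, mtry = NULL, inner_folds = 3,
                       balance = TRUE) {
  k <- min(folds, length(units))
  if (k < 2) stop("need at least two structures for cross-validation")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(units)))
  out <- vector("list", length(units))
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- vorsite(units[tr], env = env, groups = groups, ntree = ntree,
                   mtry = mtry, seed = seed + 17L * f,
                   inner_folds = inner_folds, balance = balance)
    for (u in te) {
      sc <- stats::predict(fit, units[[u]]$structure, msa = units[[u]]$msa)
      out[[u]] <- data.frame(unit = units[[u]]$id,
                             res_index = sc$res_index,
                             label = units[[u]]$labels[sc$res_index],
                             first_step_score = sc$first_step_score,
                             final_score = sc$final_score)
    }
  }
  do.call(rbind, out)
}

#' Cross-validated metrics over feature subsets and environment modes
#'
#' Runs [vorsite_cv()] for every (feature subset x environment mode) cell
#' and reports pooled AUC, MCC, recall, precision and F1 per cell.
#' Infeasible cells (e.g. conservation requested without MSAs) are marked
#' unavailable and the run continues.
#'
#' @param units List of [training_unit()]s.
#' @param subsets List of feature-group subsets, e.g.
#'   `list("s", c("s","c"), c("s","e","c","b"))`.
#' @param modes Character vector of environment modes.
#' @param folds Outer folds (by structure).
#' @param seed Random seed (one seed governs the whole matrix).
#' @param threshold Threshold for the count-based metrics.
#' @param ... Passed on to [vorsite_cv()] (e.g. `ntree`).
#' @return Data frame with one row per cell: `features`, `env`, `auc`,
#'   `mcc`, `recall`, `precision`, `f1`, `available`, `note`.
#' @export
run_experiment_matrix <- function(units, subsets, modes, folds = 5, seed = 1,
                                  threshold = 0.5, ...) {
  if (!is.list(subsets)) subsets <- list(subsets)
  rows <- list()
  for (gs in subsets) {
    for (mode in modes) {
      lab <- paste(gs, collapse = "+")
      cell <- tryCatch({
        cv <- vorsite_cv(units, env = env_config(mode), groups = gs,
                         folds = folds, seed = seed, ...)
        rep <- confusion_and_rates(cv$final_score, cv$label, threshold)
        data.frame(features = lab, env = mode,
                   auc = roc_auc(cv$final_score, cv$label)$auc,
                   mcc = rep$mcc, recall = rep$recall,
                   precision = rep$precision, f1 = rep$f1,
                   available = TRUE, note = "")
      }, error = function(e) {
        data.frame(features = lab, env = mode, auc = NA_real_,
                   mcc = NA_real_, recall = NA_real_, precision = NA_real_,
                   f1 = NA_real_, available = FALSE,
                   note = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as JSON and the ROC as two-column text
#'
#' @param report An `eval_report`.
#' @param roc Optional list from [roc_auc()].
#' @param file JSON output path; the ROC (if given) goes to
#'   `<file>.roc.tsv`.
#' @export
write_eval_report <- function(report, file, roc = NULL) {
  x <- unclass(report)
  x$counts <- as.list(x$counts)
  if (!is.null(roc)) x$auc <- roc$auc
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc)) {
    utils::write.table(roc$roc, paste0(file, ".roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
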