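#' Build a feature table from cluster-mean NH values
#'
#' One column per selected cluster, one row per subject; rows are aligned to
#' the phenotype table by subject id.
#'
#' @param nh_maps list of standardized [nh_map]s with subject ids.
#' @param clusters named list of clusters (components with `voxels`, or
#'   vectors of linear voxel indices); names become feature column names.
#' @param pheno data frame with `subject_id` and `group`.
#' @return data frame: `subject_id`, `group`, one numeric column per cluster.
#' @export
build_feature_table <- function(nh_maps, clusters, pheno) {
  if (length(clusters) == 0L) stop("no clusters supplied")
  ids <- vapply(nh_maps, function(m) as.character(m$subject_id), "")
  if (!setequal(ids, pheno$subject_id) || anyDuplicated(ids))
    stop("subject mismatch between NH maps and phenotype table")
  ord <- match(pheno$subject_id, ids)
  if (is.null(names(clusters)))
    names(clusters) <- paste0("cluster_", seq_along(clusters))
  out <- data.frame(subject_id = pheno$subject_id, group = pheno$group,
                    stringsAsFactors = FALSE)
  for (nm in names(clusters)) {
    vals <- extract_cluster_means(nh_maps, clusters[[nm]])
    out[[nm]] <- unname(vals[ord])
  }
  out
}

#' Classification performance percentages from confusion counts
#'
#' Accuracy = 100 (TP + TN) / total, sensitivity = 100 TP / (TP + FN)
#' (patients), specificity = 100 TN / (TN + FP) (controls). Values are kept
#' at full precision; rendering rounds to 2 decimals.
#'
#' @param tp,fn,tn,fp non-negative confusion counts (positive class =
#'   patient).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   and the counts.
#' @export
performance_report <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (tp + fn + tn + fp == 0 || tp + fn == 0 || tn + fp == 0)
    stop("zero denominator")
  list(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       counts = as.list(counts))
}

#' Format a performance report like a results line
#'
#' @param rep a list from [performance_report()].
#' @return character string with the three percentages and fractions.
#' @export
format_performance <- function(rep) {
  with(rep, sprintf(
    "accuracy %.2f%% (%d/%d), sensitivity %.2f%% (%d/%d), specificity %.2f%% (%d/%d)",
    accuracy, counts$tp + counts$tn,
    counts$tp + counts$fn + counts$tn + counts$fp,
    sensitivity, counts$tp, counts$tp + counts$fn,
    specificity, counts$tn, counts$tn + counts$fp))
}

cv_folds <- function(groups, scheme, k = 10L) {
  n <- length(groups)
  if (identical(scheme, "loocv")) return(as.list(seq_len(n)))
  if (k < 2L || k > n) stop("k must be in [2, n]")
  # deterministic stratified assignment: round-robin within each group
  fold <- integer(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Grid-searched RBF-SVM with cross-validation
#'
#' For every (C, gamma) pair an RBF-kernel C-SVC (via e1071/libsvm) is
#' trained and evaluated under the chosen cross-validation scheme, with
#' feature z-scoring fit on the training folds only. The best pair is chosen
#' by pooled held-out accuracy (ties: smaller C, then smaller gamma) and its
#' pooled confusion counts are reported. Deterministic given the table and
#' grids.
#'
#' @param table a feature table from [build_feature_table()] (columns after
#'   `subject_id` and `group` are features).
#' @param c_grid,gamma_grid numeric grids; defaults are the conventional
#'   powers of two, `C = 2^(-5..15)` and `gamma = 2^(-15..3)`.
#' @param scheme `"loocv"` (default) or `"kfold"`.
#' @param k folds for `"kfold"`.
#' @return an object of class `classification_result`: confusion counts,
#'   percentages, `best_c`, `best_gamma`, `scheme`, and the full accuracy
#'   `grid` (Fig-2-style surface).
#' @export
cv_svm_grid <- function(table, c_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2),
                        scheme = c("loocv", "kfold"), k = 10L) {
  scheme <- match.arg(scheme)
  if (length(c_grid) == 0L || length(gamma_grid) == 0L) stop("empty grid")
  feat_cols <- setdiff(names(table), c("subject_id", "group"))
  if (length(feat_cols) == 0L) stop("no feature columns")
  X <- as.matrix(table[, feat_cols, drop = FALSE])
  if (anyNA(X)) stop("missing feature values")
  y <- factor(table$group, levels = c("control", "patient"))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  folds <- cv_folds(as.character(y), scheme, k)

  grid <- expand.grid(C = c_grid, gamma = gamma_grid)
  acc <- numeric(nrow(grid))
  pred_store <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
    for (f in folds) {
      tr_x <- X[-f, , drop = FALSE]; tr_y <- y[-f]
      mu <- colMeans(tr_x); sg <- apply(tr_x, 2L, sd)
      sg[sg == 0] <- 1
      tr_s <- sweep(sweep(tr_x, 2L, mu), 2L, sg, "/")
      te_s <- sweep(sweep(X[f, , drop = FALSE], 2L, mu), 2L, sg, "/")
      fit <- e1071::svm(tr_s, tr_y, type = "C-classification",
                        kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred[f] <- predict(fit, te_s)
    }
    acc[g] <- mean(pred == y)
    pred_store[[g]] <- pred
  }
  # best by accuracy; ties -> smaller C then smaller gamma
  ord <- order(-acc, grid$C, grid$gamma)
  best <- ord[1]
  pred <- pred_store[[best]]
  tp <- sum(pred == "patient" & y == "patient")
  fn <- sum(pred == "control" & y == "patient")
  tn <- sum(pred == "control" & y == "control")
  fp <- sum(pred == "patient" & y == "control")
  rep <- performance_report(tp, fn, tn, fp)
  structure(c(rep, list(
    best_c = grid$C[best], best_gamma = grid$gamma[best],
    scheme = if (scheme == "loocv") "leave-one-out"
             else sprintf("%d-fold", k),
    grid = cbind(grid, accuracy = 100 * acc),
    predictions = pred)), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s CV, best C = %g, gamma = %g\n  %s\n",
              x$scheme, x$best_c, x$best_gamma, format_performance(x)))
  invisible(x)
}
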