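# Cohort-level reporting: group mean +/- SD tables, paired t tests,
# Mann-Whitney ROC/AUC per marker, an in-sample logistic multiparameter ROC,
# and AUC-ranked marker lists.

#' Per-group mean and SD of cohort columns
#'
#' @param cohort A data frame of per-ROI values (one row per ROI).
#' @param columns Character vector of numeric columns to summarise; defaults
#'   to all numeric columns.
#' @param group Name of the grouping column (binary labels, e.g.
#'   HCC vs liver).
#' @return A data frame with one row per (group, column): `n`, `mean`, `sd`
#'   (sample SD, n - 1 denominator).
#' @export
summarize_cohort <- function(cohort, columns = NULL, group = "group") {
  if (!group %in% names(cohort)) stop("grouping column not found")
  if (is.null(columns))
    columns <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  missing_cols <- setdiff(columns, names(cohort))
  if (length(missing_cols))
    stop("unknown columns: ", paste(missing_cols, collapse = ", "))
  g <- factor(cohort[[group]])
  if (nlevels(g) < 2L)
    stop("cohort must contain at least 2 groups (a group is empty)")
  if (any(table(g) < 2L)) stop("every group needs at least 2 rows")
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    rows <- cohort[g == lev, columns, drop = FALSE]
    data.frame(group = lev, parameter = columns, n = nrow(rows),
               mean = vapply(rows, mean, numeric(1)),
               sd = vapply(rows, stats::sd, numeric(1)),
               row.names = NULL)
  }))
  out
}

#' Paired Student's t test
#'
#' Two-sided paired t test on elementwise differences, with n - 1 degrees of
#' freedom.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return A list: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("paired t test needs at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero-variance differences: t statistic undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

check_labels <- function(labels, positive) {
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(f)[2L]
  if (!positive %in% levels(f)) stop("positive class not found in labels")
  f == positive
}

#' ROC analysis of a scalar marker
#'
#' The AUC is the normalised Mann-Whitney U statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counting one half.
#' With `direction = "auto"` (default) the score is flipped when the raw AUC
#' falls below 0.5 and the flip is recorded, so reported AUCs are always
#' >= 0.5 whether the marker runs higher or lower in the positive class.
#'
#' @param values Numeric marker values.
#' @param labels Binary class labels.
#' @param direction `"auto"`, `"greater"` (higher score = positive class) or
#'   `"less"`.
#' @param positive Label of the positive class (default: the second factor
#'   level).
#' @return A `roc_result`: `auc`, `n_pos`, `n_neg`, `direction`, `flipped`,
#'   and `curve` (data frame of FPR/TPR points from (0,0) to (1,1)).
#' @export
roc_auc <- function(values, labels, direction = c("auto", "greater", "less"),
                    positive = NULL) {
  direction <- match.arg(direction)
  if (length(values) != length(labels))
    stop("values and labels must have equal length")
  pos <- check_labels(labels, positive)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  auc_of <- function(v) {
    r <- rank(v)
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  flipped <- FALSE
  v <- values
  if (direction == "less") {
    v <- -values
  } else if (direction == "auto" && auc_of(values) < 0.5) {
    v <- -values
    flipped <- TRUE
  }
  auc <- auc_of(v)
  # stepwise ROC curve over decreasing thresholds
  o <- order(v, decreasing = TRUE)
  tp <- cumsum(pos[o])
  fp <- cumsum(!pos[o])
  keep <- c(diff(v[o]) != 0, TRUE)  # collapse tied scores
  curve <- data.frame(FPR = c(0, fp[keep] / n_neg),
                      TPR = c(0, tp[keep] / n_pos))
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg,
                 direction = direction, flipped = flipped, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d pos / %d neg)%s\n", x$auc,
              x$n_pos, x$n_neg, if (x$flipped) ", direction flipped" else ""))
  invisible(x)
}

#' Multiparameter ROC via an in-sample logistic combination
#'
#' Standardises the marker columns, fits an (in-sample, unpenalised)
#' logistic regression of the class labels on them, and returns the ROC of
#' the fitted linear score together with the combination coefficients.
#' Perfectly collinear columns are dropped with a warning; complete
#' separation falls back to a lightly ridge-penalised fit so the score stays
#' finite.
#'
#' @param cohort Data frame holding the markers.
#' @param columns Marker column names (>= 1).
#' @param labels Binary labels, one per row.
#' @param positive Positive-class label.
#' @return A `roc_result` with an extra `coefficients` field.
#' @export
multiparametric_roc <- function(cohort, columns, labels, positive = NULL) {
  if (length(columns) < 1L) stop("at least one marker column is required")
  missing_cols <- setdiff(columns, names(cohort))
  if (length(missing_cols))
    stop("unknown columns: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(cohort[, columns, drop = FALSE])
  if (any(!is.finite(X))) stop("marker columns contain non-finite values")
  y <- as.numeric(check_labels(labels, positive))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant columns: ",
            paste(columns[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    columns <- columns[sds > 0]
  }
  Xs <- scale(X)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    drop <- setdiff(seq_len(ncol(Xs)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping collinear columns: ",
            paste(columns[drop], collapse = ", "))
    Xs <- Xs[, -drop, drop = FALSE]
    columns <- columns[-drop]
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, Xs), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients[-1L]
  if (sep || any(!is.finite(beta)) || any(abs(beta) > 50)) {
    # separation: a small ridge penalty keeps the combination finite
    rf <- suppressWarnings(
      glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                     lambda = 0.01, standardize = FALSE))
    beta <- as.numeric(rf$beta)
    names(beta) <- colnames(Xs)
  }
  score <- as.numeric(Xs %*% beta)
  roc <- roc_auc(score, labels, direction = "auto", positive = positive)
  roc$coefficients <- stats::setNames(beta, columns)
  roc
}

#' Rank markers by univariate AUC
#'
#' Each column is scored with [roc_auc()] (`direction = "auto"`) and the
#' markers are returned sorted by descending AUC; exact ties break
#' alphabetically by column name.
#'
#' @inheritParams multiparametric_roc
#' @return Data frame: `marker`, `auc`, `flipped`, sorted by AUC.
#' @export
rank_markers <- function(cohort, columns, labels, positive = NULL) {
  res <- lapply(columns, function(cl)
    roc_auc(cohort[[cl]], labels, positive = positive))
  out <- data.frame(marker = columns,
                    auc = vapply(res, function(r) r$auc, numeric(1)),
                    flipped = vapply(res, function(r) r$flipped, logical(1)))
  out[order(-out$auc, out$marker), , drop = FALSE]
}
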