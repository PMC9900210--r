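# Evaluation metrics: concordance index, rm2, AUPR under dataset-specific
# affinity thresholds, and multi-scale binding-region hit accuracy.

#' Concordance index
#'
#' Over all sample pairs whose labels are strictly ordered, the average of
#' the step function h of the prediction difference: h = 1 when the
#' predictions agree with the label order, 0.5 when they tie, 0 when they
#' disagree.  Label ties contribute no pair.
#'
#' @param preds,labels numeric vectors of equal length (>= 2).
#' @return CI in [0, 1].
#' @export
concordance_index <- function(preds, labels) {
  n <- length(preds)
  if (n < 2L || n != length(labels)) stop("concordance_index: need two equal-length vectors")
  dl <- outer(labels, labels, "-")
  up <- dl > 0  # pairs (i, j) with label_i > label_j
  Z <- sum(up)
  if (Z == 0L) stop("concordance_index: no strictly ordered label pair")
  dp <- outer(preds, preds, "-")[up]
  sum((dp > 0) + 0.5 * (dp == 0)) / Z
}

#' rm2 external-validation index
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r02))`, where `r2` is the squared Pearson
#' correlation between observed and predicted values (regression with
#' intercept) and `r02` the squared correlation of the regression through
#' the origin; `r2 - r02` is floored at zero before the square root.
#'
#' @param preds,labels numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return rm2 value.
#' @export
rm2_index <- function(preds, labels) {
  n <- length(preds)
  if (n < 3L || n != length(labels)) stop("rm2_index: need >= 3 paired samples")
  if (stats::sd(preds) == 0 || stats::sd(labels) == 0)
    stop("rm2_index: degenerate (constant) predictions or labels")
  r2 <- stats::cor(preds, labels)^2
  k <- sum(labels * preds) / sum(preds^2)      # slope through the origin
  ss_res0 <- sum((labels - k * preds)^2)
  ss_tot <- sum((labels - mean(labels))^2)
  r02 <- 1 - ss_res0 / ss_tot
  r2 * (1 - sqrt(max(r2 - r02, 0)))
}

#' Area under the precision-recall curve after affinity binarization
#'
#' Labels are binarized at `threshold` (`direction = "greater"`: label >
#' threshold is positive, the Davis pKd rule with threshold 7;
#' `"geq"`: label >= threshold, the KIBA rule with threshold 12.1).  The
#' curve is integrated step-wise over distinct prediction scores (ties
#' grouped), i.e. AUPR = sum over achievable recall increments of the
#' precision at that threshold.
#'
#' @param preds numeric prediction scores (higher = more likely positive).
#' @param labels numeric affinity labels.
#' @param threshold binarization threshold.
#' @param direction `"greater"` or `"geq"`.
#' @return AUPR in [0, 1].
#' @export
binarize_and_aupr <- function(preds, labels, threshold,
                              direction = c("greater", "geq")) {
  direction <- match.arg(direction)
  pos <- if (direction == "greater") labels > threshold else labels >= threshold
  if (all(pos) || !any(pos))
    stop("binarize_and_aupr: need both classes after binarization")
  ord <- order(preds, decreasing = TRUE)
  pos <- pos[ord]; sc <- preds[ord]
  grp_last <- cumsum(table(factor(sc, levels = unique(sc))))  # tie groups
  tp <- cumsum(pos)[grp_last]
  fp <- cumsum(!pos)[grp_last]
  P <- sum(pos)
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Multi-scale binding-region hit accuracy
#'
#' Fraction of evaluated pairs for which at least one annotated site residue
#' falls inside the predicted region (0-based half-open interval).  Pairs
#' without annotations must be excluded before calling.
#'
#' @param regions list (or 2-column matrix) of predicted intervals, one per
#'   pair.
#' @param sites list of annotation interval matrices (as in
#'   [protein_record()]), one per pair.
#' @return Hit probability in [0, 1].
#' @export
br_hit_accuracy <- function(regions, sites) {
  if (is.matrix(regions)) regions <- asplit(regions, 1L)
  n <- length(regions)
  if (n == 0L || n != length(sites)) stop("br_hit_accuracy: empty or mismatched inputs")
  hits <- vapply(seq_len(n), function(i) {
    reg <- as.integer(regions[[i]][1:2])
    iv <- as_interval_matrix(sites[[i]])
    if (nrow(iv) == 0L) stop("br_hit_accuracy: pair ", i, " has no annotated site")
    any(iv[, 1L] < reg[2L] & iv[, 2L] > reg[1L])  # half-open overlap
  }, logical(1))
  mean(hits)
}

#' Full metrics report
#'
#' @param preds,labels affinity predictions and labels.
#' @param dataset_mode `"davis"` (AUPR threshold 7, strict), `"kiba"`
#'   (threshold 12.1, >=) or `"generic"` (no AUPR unless `threshold` given).
#' @param threshold,direction optional explicit binarization rule.
#' @param regions,sites optional binding-region predictions and truths for
#'   [br_hit_accuracy()]; `regions` may be a named list mapping scale S to a
#'   region list, giving one accuracy per scale.
#' @return List with `ci`, `mse`, `rm2`, `aupr` (NA when unavailable) and
#'   `br_accuracy`.
#' @export
metrics_report <- function(preds, labels,
                           dataset_mode = c("generic", "davis", "kiba"),
                           threshold = NULL, direction = NULL,
                           regions = NULL, sites = NULL) {
  dataset_mode <- match.arg(dataset_mode)
  if (is.null(threshold)) {
    threshold <- switch(dataset_mode, davis = 7, kiba = 12.1, generic = NULL)
    direction <- switch(dataset_mode, davis = "greater", kiba = "geq", generic = NULL)
  } else if (is.null(direction)) direction <- "greater"
  aupr <- NA_real_
  if (!is.null(threshold))
    aupr <- tryCatch(binarize_and_aupr(preds, labels, threshold, direction),
                     error = function(e) NA_real_)
  br <- NULL
  if (!is.null(regions)) {
    if (is.list(regions) && !is.null(names(regions)) &&
        all(vapply(regions, is.list, logical(1)))) {
      br <- vapply(regions, br_hit_accuracy, numeric(1), sites = sites)
    } else br <- c(all = br_hit_accuracy(regions, sites))
  }
  list(ci = concordance_index(preds, labels), mse = mse_loss(preds, labels),
       rm2 = rm2_index(preds, labels), aupr = aupr, br_accuracy = br)
}
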