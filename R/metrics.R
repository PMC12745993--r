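# Hypnogram scoring: confusion matrix, accuracy / per-class F1 / macro F1 /
# Cohen's kappa, and optimal alignment of arbitrary cluster labels to the
# five stages.

STAGE_LEVELS <- 0:4
STAGE_NAMES <- c("W", "N1", "N2", "N3", "REM")

#' Confusion matrix between reference and predicted hypnograms
#'
#' Rows are the reference stage, columns the prediction. Reference epochs
#' coded Unknown (5) are excluded; their count is reported in the
#' `n_excluded` attribute.
#'
#' @param ref,pred integer stage sequences of equal length.
#' @return 5 x 5 integer matrix of class `stage_confusion`.
#' @export
confusion <- function(ref, pred) {
  ref <- as.integer(ref); pred <- as.integer(pred)
  if (length(ref) != length(pred)) {
    stop("reference and prediction differ in length (",
         length(ref), " vs ", length(pred), ")")
  }
  keep <- ref != 5L
  if (any(pred[keep] < 0L | pred[keep] > 4L)) {
    stop("predicted codes must be in 0..4 for scored epochs")
  }
  cm <- table(factor(ref[keep], levels = STAGE_LEVELS),
              factor(pred[keep], levels = STAGE_LEVELS))
  cm <- unclass(matrix(as.integer(cm), 5L, 5L,
                       dimnames = list(ref = STAGE_NAMES,
                                       pred = STAGE_NAMES)))
  structure(cm, n_excluded = sum(!keep), class = "stage_confusion")
}

#' Row-normalized view of a confusion matrix
#'
#' @param cm a `stage_confusion`.
#' @return matrix whose non-empty rows sum to 1.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- unclass(cm) / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- NA_real_
  out
}

#' Staging scores from a confusion matrix
#'
#' Per-class precision, recall and F1 (with the 0/0 -> 0 convention),
#' overall accuracy, macro F1 averaged over classes present in the
#' reference, and Cohen's kappa with marginal-product chance agreement.
#'
#' @param cm a `stage_confusion`.
#' @param mf1_classes `"present"` (default: classes with reference epochs)
#'   or `"all"` (absent classes contribute F1 = 0).
#' @return list with `accuracy`, `macro_f1`, `kappa`, `per_class_f1`,
#'   `precision`, `recall`.
#' @export
score <- function(cm, mf1_classes = c("present", "all")) {
  mf1_classes <- match.arg(mf1_classes)
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  present <- if (mf1_classes == "present") rowSums(cm) > 0 else rep(TRUE, 5L)
  p_o <- sum(tp) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  list(accuracy = p_o, macro_f1 = mean(f1[present]), kappa = kappa,
       per_class_f1 = stats::setNames(f1, STAGE_NAMES),
       precision = stats::setNames(precision, STAGE_NAMES),
       recall = stats::setNames(recall, STAGE_NAMES))
}

#' Align arbitrary cluster labels to sleep stages
#'
#' Finds the one-to-one cluster-to-stage mapping maximizing total
#' agreement with the reference, solved as a linear assignment problem on
#' the contingency table, and returns the relabeled predictions. With
#' fewer clusters than stages the best injective mapping is used; stages
#' left unmapped receive no cluster.
#'
#' @param ref reference hypnogram (codes 0-4; Unknown epochs are ignored
#'   for fitting the mapping but still relabeled in the output).
#' @param clusters integer cluster labels, at most 5 distinct values.
#' @return integer vector of stage codes, same length as `clusters`, with
#'   the mapping in the `mapping` attribute.
#' @export
align_clusters <- function(ref, clusters) {
  ref <- as.integer(ref); clusters <- as.integer(clusters)
  stopifnot(length(ref) == length(clusters))
  labs <- sort(unique(clusters))
  if (length(labs) > 5L) {
    stop("more than 5 distinct cluster labels (", length(labs), ")")
  }
  keep <- ref >= 0L & ref <= 4L
  agree <- matrix(0, nrow = 5L, ncol = 5L)  # rows: clusters, cols: stages
  for (i in seq_along(labs)) {
    for (s in STAGE_LEVELS) {
      agree[i, s + 1L] <- sum(keep & clusters == labs[i] & ref == s)
    }
  }
  perm <- as.integer(clue::solve_LSAP(agree, maximum = TRUE))
  mapping <- stats::setNames(perm[seq_along(labs)] - 1L, labs)
  out <- unname(mapping[as.character(clusters)])
  attr(out, "mapping") <- mapping
  out
}
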