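#' Predict the major class a transcription factor specifies
#'
#' For each TF, mean normalized expression is computed within each fate group
#' of neurogenic progenitors; the predicted class is the fate group with the
#' highest mean. Ties are broken lexicographically and flagged; TFs with zero
#' expression everywhere are flagged and receive no prediction.
#'
#' @param expr Normalized (natural-log CPM) genes x cells matrix restricted
#'   to neurogenic progenitors.
#' @param fate Fate label per cell (cells with \code{NA} fate are dropped);
#'   every remaining fate group must be non-empty.
#' @param tfs TF gene names (must be rows of \code{expr}).
#' @return data.frame with \code{tf}, \code{predicted_class}, \code{tie},
#'   \code{all_zero}.
#' @export
predict_tf_specification <- function(expr, fate, tfs) {
  stopifnot(length(fate) == ncol(expr))
  miss <- setdiff(tfs, rownames(expr))
  if (length(miss))
    stop2(paste("TF(s) absent from matrix:", paste(miss, collapse = ", ")),
          "missing_gene")
  keep <- !is.na(fate)
  expr <- expr[tfs, keep, drop = FALSE]
  fate <- as.character(fate[keep])
  groups <- sort(unique(fate))
  if (!length(groups)) stop2("no fated cells", "invalid_argument")
  means <- vapply(groups, function(g)
    Matrix::rowMeans(expr[, fate == g, drop = FALSE]), numeric(length(tfs)))
  if (length(tfs) == 1L) means <- matrix(means, nrow = 1L,
                                         dimnames = list(tfs, groups))
  out <- lapply(seq_along(tfs), function(i) {
    m <- means[i, ]
    if (all(m == 0))
      return(data.frame(tf = tfs[i], predicted_class = NA_character_,
                        tie = FALSE, all_zero = TRUE))
    top <- groups[m == max(m)]
    data.frame(tf = tfs[i], predicted_class = sort(top)[1],
               tie = length(top) > 1L, all_zero = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Validate TF fate predictions against literature annotations
#'
#' Each prediction is compared with the literature classes recorded for that
#' TF: \code{Matched} if the predicted class is among them, \code{Unmatched}
#' if literature evidence exists for other classes only, \code{Unknown} if no
#' evidence is recorded. The match rate is
#' \code{n_matched / (n_matched + n_unmatched)} expressed as a percentage;
#' Unknown TFs are excluded from the denominator. With an empty denominator
#' the rate is reported as \code{NA}.
#'
#' @param predictions Named character vector (TF -> predicted class) or the
#'   data.frame from [predict_tf_specification()]. Defaults to the
#'   \code{predicted_class} column of \code{annotation}.
#' @param annotation A \code{TFAnnotationTable} (see [table1_fixture()]);
#'   must already exclude Muller-glia-promoting TFs.
#' @return List with \code{n_matched}, \code{n_unmatched}, \code{n_unknown},
#'   \code{match_rate} (percent) and the per-TF \code{table}.
#' @export
validate_tf_predictions <- function(predictions = NULL, annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("tf", "literature_classes") %in% names(annotation)))
  if (is.null(predictions))
    predictions <- setNames(annotation$predicted_class, annotation$tf)
  if (is.data.frame(predictions))
    predictions <- setNames(predictions$predicted_class, predictions$tf)
  tfs <- intersect(names(predictions), annotation$tf)
  lit <- strsplit(as.character(annotation$literature_classes[match(tfs, annotation$tf)]), ",")
  status <- vapply(seq_along(tfs), function(i) {
    classes <- trimws(lit[[i]] %||% character(0))
    classes <- classes[!is.na(classes) & nzchar(classes)]
    pred <- predictions[[tfs[i]]]
    if (!length(classes) || all(is.na(classes))) "Unknown"
    else if (!is.na(pred) && pred %in% classes) "Matched"
    else "Unmatched"
  }, character(1))
  n_matched <- sum(status == "Matched")
  n_unmatched <- sum(status == "Unmatched")
  n_unknown <- sum(status == "Unknown")
  rate <- if (n_matched + n_unmatched > 0)
    100 * n_matched / (n_matched + n_unmatched) else NA_real_
  list(n_matched = n_matched, n_unmatched = n_unmatched,
       n_unknown = n_unknown, match_rate = rate,
       table = data.frame(tf = tfs,
                          predicted_class = unname(predictions[tfs]),
                          status = status, stringsAsFactors = FALSE))
}
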