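#' Literature annotation of NRPC fate-specifying transcription factors
#'
#' The curated table of transcription factors active in neurogenic retinal
#' progenitors, each with the major class its expression pattern predicts it
#' specifies and a validation status against published loss-of-function
#' experiments: \code{Matched} (prediction agrees with the literature),
#' \code{Unmatched} (the literature supports a different class, recorded in
#' \code{literature_classes}) or \code{Unknown} (no published evidence).
#' TFs that promote Muller-glia differentiation are excluded by
#' construction.
#'
#' @return A \code{TFAnnotationTable} data.frame with columns \code{tf},
#'   \code{predicted_class}, \code{status}, \code{literature_classes}
#'   (comma-separated, \code{NA} when unknown).
#' @export
#' @examples
#' tab <- table1_fixture()
#' table(tab$status)
table1_fixture <- function() {
  path <- system.file("extdata", "tf_annotations.tsv", package = "retinatlas",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(!anyDuplicated(tab$tf),
            all(tab$status %in% c("Matched", "Unmatched", "Unknown")))
  class(tab) <- c("TFAnnotationTable", "data.frame")
  tab
}
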