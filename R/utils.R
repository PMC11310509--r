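#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix colSums rowSums t Diagonal sparseMatrix readMM writeMM
#' @importFrom methods as is new
#' @importFrom stats cor cor.test dnorm pnorm qnorm rnorm rnbinom runif
#'   prcomp hclust cutree as.dist p.adjust pt t.test wilcox.test sd var
#'   quantile setNames aggregate complete.cases rbinom pchisq
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom graphics matplot legend
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stop with a named error class
#' @noRd
stop2 <- function(msg, class) {
  cnd <- structure(
    class = c(class, "retinatlas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Dense matrix from possibly sparse input
#' @noRd
as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else m
}
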