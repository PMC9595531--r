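#' Expression matrix container
#'
#' A genes x samples numeric matrix carrying a processing-stage tag so that
#' pipeline steps can enforce their expected input scale. Stages advance only
#' along `tpm -> log2 -> qnorm -> residual`.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param stage one of `"tpm"`, `"log2"`, `"qnorm"`, `"residual"`.
#' @return the matrix with class `"expr_matrix"` and a `stage` attribute.
#' @export
expression_matrix <- function(values, stage = c("tpm", "log2", "qnorm", "residual")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(values, stage = stage, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples [stage: %s]\n",
              nrow(x), ncol(x), expr_stage(x)))
  invisible(x)
}

#' Stage tag of an expression matrix
#' @param x an `expr_matrix` (or plain matrix, in which case `NULL`).
#' @return the stage string.
#' @export
expr_stage <- function(x) attr(x, "stage", exact = TRUE)

## ordered stage index; used to forbid backward transitions
.stage_rank <- c(tpm = 1L, log2 = 2L, qnorm = 3L, residual = 4L)

## replace values/stage while keeping the class; stage may only move forward
set_stage <- function(x, values, stage) {
  old <- expr_stage(x)
  if (!is.null(old) && .stage_rank[[stage]] < .stage_rank[[old]])
    stop(sprintf("stage may not move backwards (%s -> %s)", old, stage))
  expression_matrix(unclass_matrix(values), stage)
}

require_stage <- function(x, stage, op) {
  got <- expr_stage(x)
  if (is.null(got) || got != stage)
    stop(sprintf("%s expects a matrix at stage '%s' but got '%s'",
                 op, stage, if (is.null(got)) "<untagged>" else got))
  invisible(TRUE)
}

unclass_matrix <- function(x) {
  attr(x, "stage") <- NULL
  class(x) <- setdiff(class(x), "expr_matrix")
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}

## subset keeping the tag
subset_expr <- function(x, i = NULL, j = NULL) {
  stage <- expr_stage(x)
  v <- unclass_matrix(x)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v, stage)
}
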