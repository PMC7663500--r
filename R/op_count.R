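#' Arithmetic operation counts for a function or algorithm stage
#'
#' An operation count tallies the additions/subtractions, multiplications,
#' divisions, square roots, comparisons and exponentials needed by one
#' function of an embedded algorithm, together with the number of integer
#' and float memory cells the function keeps live. Counts are the currency
#' of the analytical cost models: paired with a microcontroller's
#' per-operation machine-cycle table they yield execution time and energy.
#'
#' @param add,mult,div,root,comp,exp_ non-negative operation tallies.
#'   `exp_` is the exponential count (named with a trailing underscore to
#'   avoid masking `base::exp`).
#' @param int_cells,float_cells memory cells held by the function, by type.
#' @param label optional stage/function label used in printed breakdowns.
#' @return An object of class `op_count`.
#' @examples
#' oc <- op_count(add = 1500, mult = 3000, comp = 1, label = "kernel SVM")
#' oc + op_count(add = 10)
#' @export
op_count <- function(add = 0, mult = 0, div = 0, root = 0, comp = 0,
                     exp_ = 0, int_cells = 0, float_cells = 0, label = "") {
  counts <- c(add = add, mult = mult, div = div, root = root,
              comp = comp, exp = exp_)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("operation counts must be finite and non-negative")
  if (int_cells < 0 || float_cells < 0)
    stop("memory cell counts must be non-negative")
  structure(list(counts = counts,
                 int_cells = int_cells,
                 float_cells = float_cells,
                 label = label),
            class = "op_count")
}

#' @export
`+.op_count` <- function(e1, e2) {
  stopifnot(inherits(e1, "op_count"), inherits(e2, "op_count"))
  lab <- paste(c(e1$label, e2$label)[nzchar(c(e1$label, e2$label))],
               collapse = " + ")
  structure(list(counts = e1$counts + e2$counts,
                 int_cells = e1$int_cells + e2$int_cells,
                 float_cells = e1$float_cells + e2$float_cells,
                 label = lab),
            class = "op_count")
}

#' @export
`*.op_count` <- function(e1, e2) {
  if (inherits(e1, "op_count")) { oc <- e1; k <- e2 } else { oc <- e2; k <- e1 }
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  structure(list(counts = oc$counts * k,
                 int_cells = oc$int_cells * k,
                 float_cells = oc$float_cells * k,
                 label = oc$label),
            class = "op_count")
}

#' @export
print.op_count <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  cat("<op_count>", lab, "\n", sep = "")
  print(x$counts)
  cat("memory cells: int ", x$int_cells, ", float ", x$float_cells, "\n",
      sep = "")
  invisible(x)
}

#' Sum a list of operation counts
#'
#' @param counts list of `op_count` objects.
#' @return A single merged `op_count`.
#' @export
merge_op_counts <- function(counts) {
  stopifnot(length(counts) >= 1)
  Reduce(`+`, counts)
}
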