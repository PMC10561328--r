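#' Incidence matrices of a net
#'
#' The input matrix `A-` holds the arc weights place -> transition
#' (`A-[i, j] = pre(t_i, s_j)`), the output matrix `A+` the weights
#' transition -> place, and the incidence matrix `A = A+ - A-` the net token
#' change per place when each transition fires once.  Orientation is fixed
#' as **rows = transitions, columns = places** throughout the package; note
#' that the transposed convention also occurs in the literature.  `A` loses
#' self-loop information (a transition that both consumes from and produces
#' to the same place cancels in `A`), which is why `A-` and `A+` are kept.
#'
#' @param net a [petri_net].
#' @return `input_matrix()` and `output_matrix()` return an integer matrix;
#'   `incidence_matrix()` returns an `incidence_triple`: a list with
#'   components `a_minus`, `a_plus`, `a` satisfying `a == a_plus - a_minus`.
#' @examples
#' dana <- build_dana()
#' incidence_matrix(dana$net)$a
#' @export
input_matrix <- function(net) net$pre

#' @rdname input_matrix
#' @export
output_matrix <- function(net) net$post

#' @rdname input_matrix
#' @export
incidence_matrix <- function(net) {
  structure(
    list(a_minus = net$pre, a_plus = net$post, a = net$post - net$pre),
    class = "incidence_triple"
  )
}

#' @export
print.incidence_triple <- function(x, ...) {
  cat("<incidence_triple> A = A+ - A- (rows = transitions, cols = places)\n")
  print(x$a)
  invisible(x)
}

#' Evaluate the state equation
#'
#' Computes `M' = M + x' A` for a firing-count vector `x` over transitions.
#' When `x` counts the firings of an executable sequence from `m`, the
#' result is that sequence's final marking.  The result may contain negative
#' entries for infeasible `x`; feasibility is the caller's concern.
#'
#' @inheritParams input_matrix
#' @param m marking in the net's place order.
#' @param x nonnegative integer vector of firing counts, one per transition.
#' @return Integer vector over places (not necessarily a valid marking).
#' @export
apply_firing_count <- function(net, m, x) {
  m <- as_marking(net, m)
  if (length(x) != length(net$transitions)) {
    stop_pn("pn_dimension_error", sprintf(
      "firing-count length %d does not match the net's %d transitions",
      length(x), length(net$transitions)))
  }
  a <- net$post - net$pre
  res <- as.integer(m + as.integer(x) %*% a)
  stats::setNames(res, net$places)
}

#' Write a transitions-by-places integer matrix as TSV
#'
#' Header row of place identifiers, first column transition identifiers.
#'
#' @param mat integer matrix with dimnames (e.g. a component of
#'   [incidence_matrix()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  header <- paste(c("", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
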