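# Plain matrix text format.  Four tab-separated blocks:
#
#   PLACES                       id <TAB> label <TAB> initial tokens
#   TRANSITIONS                  id <TAB> label
#   A_MINUS                      one row per transition: pre weights
#   A_PLUS                       one row per transition: post weights
#
# A- and A+ are stored separately (never just A = A+ - A-) so self-loop
# information survives round-trips.  Columns of the matrix blocks follow
# the PLACES block order; rows follow the TRANSITIONS block order.

#' Write and read the plain matrix text format
#'
#' A complete, human-readable structural description of a net: a `PLACES`
#' block (`id`, label, initial tokens, tab-separated), a `TRANSITIONS`
#' block (`id`, label), then the input matrix under `A_MINUS` and the
#' output matrix under `A_PLUS`, one tab-separated integer row per
#' transition.  Reading reconstructs the net, labels and initial marking
#' exactly; writing is the inverse.
#'
#' @param annotated an [annotate()]d net (a bare [petri_net] is accepted).
#' @param path file path.
#' @return `write_matrix_text()` returns `path` invisibly;
#'   `read_matrix_text()` an `annotated_net`.
#' @export
write_matrix_text <- function(annotated, path) {
  if (inherits(annotated, "petri_net")) annotated <- annotate(annotated)
  net <- annotated$net
  lines <- c(
    "PLACES",
    vapply(net$places, function(p) {
      paste(p, annotated$place_labels[[p]], annotated$initial[[p]], sep = "\t")
    }, character(1)),
    "TRANSITIONS",
    vapply(net$transitions, function(t) {
      paste(t, annotated$transition_labels[[t]], sep = "\t")
    }, character(1)),
    "A_MINUS",
    vapply(seq_len(nrow(net$pre)), function(i) {
      paste(net$pre[i, ], collapse = "\t")
    }, character(1)),
    "A_PLUS",
    vapply(seq_len(nrow(net$post)), function(i) {
      paste(net$post[i, ], collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_text
#' @export
read_matrix_text <- function(path) {
  if (!file.exists(path)) {
    stop_pn("pn_io_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  headers <- c("PLACES", "TRANSITIONS", "A_MINUS", "A_PLUS")
  pos <- match(headers, lines)
  if (anyNA(pos) || is.unsorted(pos)) {
    stop_pn("pn_format_error", paste(
      "matrix text file must contain the blocks PLACES, TRANSITIONS,",
      "A_MINUS, A_PLUS in this order"))
  }
  block <- function(k) {
    from <- pos[k] + 1L
    to <- if (k < 4L) pos[k + 1L] - 1L else length(lines)
    if (to < from) character(0) else lines[from:to]
  }
  parse_fields <- function(raw) strsplit(raw, "\t", fixed = TRUE)
  p_rows <- parse_fields(block(1L))
  t_rows <- parse_fields(block(2L))
  pids <- vapply(p_rows, `[`, character(1), 1L)
  p_labels <- vapply(p_rows, function(f) if (length(f) >= 2L) f[2L] else f[1L],
                     character(1))
  p_init <- vapply(p_rows, function(f) {
    v <- if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else 0
    if (is.na(v) || v < 0 || v != floor(v)) {
      stop_pn("pn_format_error", sprintf("invalid token count for place '%s'", f[1L]))
    }
    as.integer(v)
  }, integer(1))
  tids <- vapply(t_rows, `[`, character(1), 1L)
  t_labels <- vapply(t_rows, function(f) if (length(f) >= 2L) f[2L] else f[1L],
                     character(1))
  parse_matrix <- function(raw, what) {
    if (length(raw) != length(tids)) {
      stop_pn("pn_format_error", sprintf(
        "%s has %d rows but the net declares %d transitions",
        what, length(raw), length(tids)))
    }
    if (length(raw) == 0L) {
      return(matrix(0L, 0L, length(pids), dimnames = list(NULL, pids)))
    }
    rows <- lapply(strsplit(raw, "\t", fixed = TRUE), function(f) {
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
        stop_pn("pn_format_error", sprintf("%s contains a non-integer entry", what))
      }
      as.integer(v)
    })
    if (any(lengths(rows) != length(pids))) {
      stop_pn("pn_format_error", sprintf(
        "%s row width does not match the %d declared places", what, length(pids)))
    }
    mat <- do.call(rbind, rows)
    dimnames(mat) <- list(tids, pids)
    mat
  }
  a_minus <- parse_matrix(block(3L), "A_MINUS")
  a_plus <- parse_matrix(block(4L), "A_PLUS")
  net <- petri_net(pids, tids)
  net$pre <- a_minus
  net$post <- a_plus
  annotate(net,
           place_labels = stats::setNames(as.list(p_labels), pids),
           transition_labels = stats::setNames(as.list(t_labels), tids),
           initial = p_init)
}
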