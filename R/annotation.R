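#' Attach biological annotations to a net
#'
#' Qualitative models of signaling or hormone systems give each place a
#' biological state (a hormone pool, a symptom) and each transition a
#' physiological event.  `annotate()` binds free-text labels and an initial
#' marking to a net; elements without a label default to their identifier.
#'
#' @inheritParams input_matrix
#' @param place_labels named character vector or list, place id -> meaning.
#' @param transition_labels named character vector or list, transition id ->
#'   meaning.
#' @param initial initial marking (defaults to the empty marking).
#' @return An `annotated_net`: list with `net`, `place_labels`,
#'   `transition_labels` (both complete, defaults filled), and `initial`.
#' @examples
#' dana <- build_dana()
#' dana$place_labels[["P5"]]       # "Blocking Depression"
#' dana$transition_labels[["T0"]]  # "Low Norepinephrine Levels"
#' @export
annotate <- function(net, place_labels = NULL, transition_labels = NULL,
                     initial = NULL) {
  fill <- function(labels, ids, what) {
    labels <- as.list(labels)
    bad <- setdiff(names(labels), ids)
    if (length(bad) > 0L) {
      stop_pn("pn_identifier_error", sprintf(
        "label for unknown %s: %s", what, paste(bad, collapse = ", ")))
    }
    out <- stats::setNames(as.list(ids), ids)
    out[names(labels)] <- lapply(labels, as.character)
    out
  }
  if (is.null(initial)) initial <- rep(0L, length(net$places))
  structure(
    list(net = net,
         place_labels = fill(place_labels, net$places, "place"),
         transition_labels = fill(transition_labels, net$transitions, "transition"),
         initial = as_marking(net, initial)),
    class = "annotated_net"
  )
}

#' @export
print.annotated_net <- function(x, ...) {
  print(x$net)
  cat("  initial marking: (", paste(x$initial, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Places common to every S-invariant support
#'
#' The intersection of the supports of a set of S-invariants: places through
#' which every conserved token set passes.  When the places carry biological
#' labels, a nonempty shared support is read as states that all conserved
#' subsystems have in common.
#'
#' @param invariants list of S-kind `pn_invariant` objects.
#' @return Character vector of place identifiers (empty set for an empty
#'   input list).
#' @export
shared_support <- function(invariants) {
  if (length(invariants) == 0L) return(character(0))
  kinds <- vapply(invariants, `[[`, character(1), "kind")
  if (any(kinds != "S")) {
    stop_pn("pn_kind_error", "shared_support is defined for S-kind invariants")
  }
  Reduce(intersect, lapply(invariants, `[[`, "support"))
}

#' Full structural analysis report for an annotated net
#'
#' Runs the complete pipeline -- incidence matrices, minimal S- and
#' T-invariant enumeration, coverage, capped reachability exploration,
#' boundedness and token-conservation checks -- and assembles a labeled
#' report.  The biological reading (e.g. "every conserved place set
#' contains ...") is derived from the labeled shared support, never
#' hard-coded, so the same pipeline applies to any annotated net.  Note that
#' S-invariants are conservation relations ("conserved place sets"), not
#' execution paths.
#'
#' @param annotated an [annotate()]d net.
#' @param max_markings reachability exploration cap; a truncated exploration
#'   marks the reachability summary partial instead of erroring.
#' @return A `pn_report` list; see [write_report_json()] for the serialized
#'   schema.
#' @export
full_report <- function(annotated, max_markings = 100000L) {
  net <- annotated$net
  inc <- incidence_matrix(net)
  s_invs <- minimal_s_invariants(net)
  t_invs <- minimal_t_invariants(net)
  warnings <- character(0)
  if (any(net$pre > 0L & net$post > 0L)) {
    warnings <- c(warnings, paste(
      "net contains self-loops (overlapping pre/post arcs); the incidence",
      "matrix A loses this information, so invariants computed from A may",
      "miss self-loop structure"))
  }
  label_places <- function(ids) unlist(annotated$place_labels[ids], use.names = FALSE)
  label_trans <- function(ids) unlist(annotated$transition_labels[ids], use.names = FALSE)
  inv_entry <- function(inv) {
    labels <- if (inv$kind == "S") label_places(inv$support) else label_trans(inv$support)
    list(vector = unname(inv$vector), support = inv$support,
         support_labels = labels)
  }
  shared <- shared_support(s_invs)
  cov_s <- coverage(net, "S")
  cov_t <- coverage(net, "T")
  graph <- reachability_graph(net, annotated$initial, max_markings)
  cons <- check_conservation(graph, s_invs)
  reach <- list(
    n_markings = nrow(graph$nodes),
    n_dead = if (graph$truncated) NA_integer_ else length(graph$dead),
    truncated = graph$truncated,
    bounds = if (graph$truncated) NULL else place_bounds(graph),
    acyclic = if (graph$truncated) NA else !has_cycle(graph),
    conservation_holds = cons$conserved,
    conserved_values = cons$values
  )
  interpretation <- if (length(s_invs) == 0L) {
    "The net has no S-invariant: no weighted token count is structurally conserved."
  } else if (length(shared) == 0L) {
    sprintf("The net has %d minimal conserved place set(s) with no place common to all of them.",
            length(s_invs))
  } else {
    sprintf(paste(
      "The net has %d minimal conserved place set(s); every one of them",
      "contains: %s. These states are common to all conserved subsystems."),
      length(s_invs), paste(label_places(shared), collapse = ", "))
  }
  structure(
    list(
      incidence = inc,
      s_invariants = lapply(s_invs, inv_entry),
      t_invariants = lapply(t_invs, inv_entry),
      shared_support = list(places = shared, labels = label_places(shared)),
      uncovered = list(
        places = cov_s$uncovered, place_labels = label_places(cov_s$uncovered),
        transitions = cov_t$uncovered,
        transition_labels = label_trans(cov_t$uncovered)),
      reachability = reach,
      interpretation = interpretation,
      warnings = warnings
    ),
    class = "pn_report"
  )
}

#' @export
print.pn_report <- function(x, ...) {
  cat(render_report_markdown(x), sep = "\n")
  invisible(x)
}

#' Serialize an analysis report
#'
#' The JSON document is a single object with keys `incidence` (objects
#' `a_minus`, `a_plus`, `a`: integer matrices as arrays of row arrays),
#' `s_invariants` / `t_invariants` (arrays of objects with `vector`,
#' `support`, `support_labels`), `shared_support` (`places`, `labels`),
#' `uncovered` (`places`, `place_labels`, `transitions`,
#' `transition_labels`), `reachability` (`n_markings`, `n_dead`,
#' `truncated`, `bounds`, `acyclic`, `conservation_holds`,
#' `conserved_values`), `interpretation` (string) and `warnings` (array of
#' strings).  Output is deterministic: repeated runs produce byte-identical
#' files.
#'
#' @param report a `pn_report` from [full_report()].
#' @param path output file path.
#' @return `path` invisibly (writers); a character scalar / vector of lines
#'   (renderers).
#' @export
render_report_json <- function(report) {
  x <- unclass(report)
  x$incidence <- lapply(unclass(x$incidence), function(m) {
    dimnames(m) <- NULL
    m
  })
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' @rdname render_report_json
#' @export
write_report_json <- function(report, path) {
  writeLines(as.character(render_report_json(report)), path)
  invisible(path)
}

#' @rdname render_report_json
#' @export
render_report_markdown <- function(report) {
  inv_lines <- function(invs, kind) {
    if (length(invs) == 0L) return(sprintf("- no %s-invariant found", kind))
    vapply(invs, function(e) {
      sprintf("- (%s)  support: %s", paste(e$vector, collapse = ","),
              paste(e$support_labels, collapse = ", "))
    }, character(1))
  }
  r <- report$reachability
  c("# Structural analysis report",
    "",
    "## Minimal S-invariants (conserved place sets)",
    inv_lines(report$s_invariants, "S"),
    "",
    "## Minimal T-invariants",
    inv_lines(report$t_invariants, "T"),
    "",
    "## Shared support",
    if (length(report$shared_support$places) == 0L) "- (empty)" else
      sprintf("- %s (%s)", paste(report$shared_support$places, collapse = ", "),
              paste(report$shared_support$labels, collapse = ", ")),
    "",
    "## Coverage",
    sprintf("- places in no S-invariant: %s",
            if (length(report$uncovered$places) == 0L) "(none)" else
              paste(report$uncovered$place_labels, collapse = ", ")),
    sprintf("- transitions in no T-invariant: %s",
            if (length(report$uncovered$transitions) == 0L) "(none)" else
              paste(report$uncovered$transitions, collapse = ", ")),
    "",
    "## Reachability",
    sprintf("- reachable markings: %d%s", r$n_markings,
            if (r$truncated) " (exploration truncated; summary is partial)" else ""),
    if (!r$truncated) sprintf("- dead markings: %d", r$n_dead) else NULL,
    if (!r$truncated) sprintf("- place bounds: (%s)",
                              paste(r$bounds, collapse = ",")) else NULL,
    if (!r$truncated) sprintf("- acyclic: %s", r$acyclic) else NULL,
    sprintf("- S-invariant token conservation holds: %s", r$conservation_holds),
    "",
    "## Interpretation",
    report$interpretation,
    if (length(report$warnings) > 0L) c("", "## Warnings",
                                        paste("-", report$warnings)) else NULL)
}

#' @rdname render_report_json
#' @export
write_report_markdown <- function(report, path) {
  writeLines(render_report_markdown(report), path)
  invisible(path)
}
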