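# PNML (ISO/IEC 15909-2, place/transition subset) reader and writer.

PNML_NS <- "http://www.pnml.org/version-2009/grammar/pnml"
PTNET_TYPE <- "http://www.pnml.org/version-2009/grammar/ptnet"

# XML NCName sanitization for node ids; original ids kept in <name><text>.
ncname <- function(id) {
  out <- gsub("[^A-Za-z0-9_.-]", "_", id)
  ifelse(grepl("^[A-Za-z_]", out), out, paste0("id_", out))
}

#' Write and read PNML
#'
#' `write_pnml()` serializes an annotated net as an ISO/IEC 15909-2
#' place/transition net: one `<place>` element per place (with
#' `<initialMarking>` from the annotated initial marking), one
#' `<transition>` per transition, one `<arc>` per arc with its weight as
#' `<inscription>`.  Biological labels are carried in `<name><text>`
#' elements.  `read_pnml()` parses the same subset back; tool-specific or
#' graphical subtrees are ignored with a warning, a missing
#' `<initialMarking>` means 0 tokens and a missing `<inscription>` weight 1.
#'
#' @param annotated an [annotate()]d net (a bare [petri_net] is accepted and
#'   gets an empty marking).
#' @param path file path.
#' @return `write_pnml()` returns `path` invisibly; `read_pnml()` an
#'   `annotated_net`.
#' @examples
#' f <- tempfile(fileext = ".pnml")
#' write_pnml(build_dana(), f)
#' rt <- read_pnml(f)
#' identical(rt$initial, build_dana()$initial)
#' @export
write_pnml <- function(annotated, path) {
  if (inherits(annotated, "petri_net")) annotated <- annotate(annotated)
  net <- annotated$net
  doc <- xml2::xml_new_root("pnml", xmlns = PNML_NS)
  net_node <- xml2::xml_add_child(doc, "net", id = "net1", type = PTNET_TYPE)
  page <- xml2::xml_add_child(net_node, "page", id = "page1")
  add_name <- function(node, text) {
    nm <- xml2::xml_add_child(node, "name")
    xml2::xml_add_child(nm, "text", text)
  }
  for (p in net$places) {
    pl <- xml2::xml_add_child(page, "place", id = ncname(p))
    add_name(pl, annotated$place_labels[[p]])
    tokens <- annotated$initial[[p]]
    if (tokens > 0L) {
      mk <- xml2::xml_add_child(pl, "initialMarking")
      xml2::xml_add_child(mk, "text", as.character(tokens))
    }
  }
  for (t in net$transitions) {
    tr <- xml2::xml_add_child(page, "transition", id = ncname(t))
    add_name(tr, annotated$transition_labels[[t]])
  }
  arc_id <- 0L
  add_arc <- function(src, tgt, w) {
    arc_id <<- arc_id + 1L
    arc <- xml2::xml_add_child(page, "arc", id = sprintf("a%d", arc_id),
                               source = ncname(src), target = ncname(tgt))
    if (w != 1L) {
      ins <- xml2::xml_add_child(arc, "inscription")
      xml2::xml_add_child(ins, "text", as.character(w))
    }
  }
  for (i in seq_along(net$transitions)) {
    for (j in seq_along(net$places)) {
      if (net$pre[i, j] > 0L) add_arc(net$places[j], net$transitions[i], net$pre[i, j])
    }
  }
  for (i in seq_along(net$transitions)) {
    for (j in seq_along(net$places)) {
      if (net$post[i, j] > 0L) add_arc(net$transitions[i], net$places[j], net$post[i, j])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_pnml
#' @export
read_pnml <- function(path) {
  if (!file.exists(path)) {
    stop_pn("pn_io_error", sprintf("file not found: %s", path))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_pn("pn_format_error", sprintf("malformed XML in %s: %s", path,
                                       conditionMessage(e)))
  })
  ns <- c(p = PNML_NS)
  find <- function(node, xp) {
    # tolerate both namespaced and namespace-free PNML
    hits <- xml2::xml_find_all(node, gsub("X:", "p:", xp), ns)
    if (length(hits) == 0L) hits <- xml2::xml_find_all(node, gsub("X:", "", xp))
    hits
  }
  text_of <- function(node, xp, default) {
    hit <- find(node, xp)
    if (length(hit) == 0L) default else xml2::xml_text(hit[[1L]])
  }
  known <- c("place", "transition", "arc", "page", "name", "text",
             "initialMarking", "inscription", "net", "pnml", "referencePlace")
  odd <- setdiff(unique(xml2::xml_name(xml2::xml_find_all(doc, "//*"))), known)
  if (length(odd) > 0L) {
    warning(sprintf("ignoring unrecognized PNML element(s): %s",
                    paste(odd, collapse = ", ")), call. = FALSE)
  }
  place_nodes <- find(doc, "//X:place")
  trans_nodes <- find(doc, "//X:transition")
  arc_nodes <- find(doc, "//X:arc")
  pids <- xml2::xml_attr(place_nodes, "id")
  tids <- xml2::xml_attr(trans_nodes, "id")
  p_labels <- vapply(seq_along(place_nodes), function(i) {
    text_of(place_nodes[[i]], "./X:name/X:text", pids[i])
  }, character(1))
  t_labels <- vapply(seq_along(trans_nodes), function(i) {
    text_of(trans_nodes[[i]], "./X:name/X:text", tids[i])
  }, character(1))
  marking <- vapply(seq_along(place_nodes), function(i) {
    v <- suppressWarnings(as.numeric(
      text_of(place_nodes[[i]], "./X:initialMarking/X:text", "0")))
    if (is.na(v) || v < 0 || v != floor(v)) {
      stop_pn("pn_format_error", sprintf(
        "invalid initial marking on place '%s'", pids[i]))
    }
    as.integer(v)
  }, integer(1))
  arcs <- NULL
  if (length(arc_nodes) > 0L) {
    src <- xml2::xml_attr(arc_nodes, "source")
    tgt <- xml2::xml_attr(arc_nodes, "target")
    w <- vapply(seq_along(arc_nodes), function(i) {
      v <- suppressWarnings(as.numeric(
        text_of(arc_nodes[[i]], "./X:inscription/X:text", "1")))
      if (is.na(v) || v < 1 || v != floor(v)) {
        stop_pn("pn_format_error", sprintf(
          "invalid inscription on arc %s -> %s", src[i], tgt[i]))
      }
      as.integer(v)
    }, integer(1))
    bad <- !((src %in% pids & tgt %in% tids) | (src %in% tids & tgt %in% pids))
    if (any(bad)) {
      k <- which(bad)[1L]
      stop_pn("pn_format_error", sprintf(
        "arc %s -> %s is not bipartite place/transition", src[k], tgt[k]))
    }
    arcs <- data.frame(from = src, to = tgt, weight = w,
                       stringsAsFactors = FALSE)
  }
  net <- petri_net(pids, tids, arcs)
  annotate(net,
           place_labels = stats::setNames(as.list(p_labels), pids),
           transition_labels = stats::setNames(as.list(t_labels), tids),
           initial = marking)
}
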