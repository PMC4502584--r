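# ---------------------------------------------------------------------------
# Neural-circuit compilation. Every nonterminal maps to one soma; terminals
# become input (sensor/dendritic) or output (actuator/axonal) ports; each
# alternate contributes synapse edges from the head soma to each symbol's
# node, labelled with the alternate weight. A rule recursing on its own head
# yields an autapse; a reference back to an earlier-defined head that closes
# a cycle yields a regular recurrent synapse.
# ---------------------------------------------------------------------------

node_type_for_kind <- function(kind) {
  switch(kind,
         nonterminal = "soma",
         sensor = "sensor_port",
         actuator = "actuator_port",
         quoted = "quote_port",
         unquoted = "unquote_port",
         stop("unclassifiable symbol kind: ", kind))
}

#' Compile a grammar to its neural-circuit graph
#'
#' @param g valid grammar.
#' @return a circuit: list with `nodes` (data frame `id`, `type`) and
#'   `edges` (data frame `from`, `to`, `weight`, `rule`, `alternate`,
#'   `autapse`, `recurrent`, `projection`, `inhibitory`). One soma per
#'   nonterminal (a bijection); one port per distinct terminal; one edge per
#'   symbol occurrence. Edges with weight below .5 are flagged inhibitory as
#'   metadata only. Quote/unquote terminals become projection ports (their
#'   edges are the describing circuit's projection onto the described one).
#' @export
circuit_graph <- function(g) {
  stopifnot(inherits(g, "arg_grammar"))
  heads <- grammar_heads(g)
  terms <- grammar_terminals(g)
  kinds <- symbol_kind(c(heads, terms), g)
  names(kinds) <- c(heads, terms)
  nodes <- data.frame(
    id = c(heads, terms),
    type = vapply(kinds, node_type_for_kind, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)

  from <- character(); to <- character(); weight <- numeric()
  rule_i <- integer(); alt_i <- integer()
  for (i in seq_along(g$rules)) {
    r <- g$rules[[i]]
    for (j in seq_along(r$alternates)) {
      a <- r$alternates[[j]]
      for (s in a$symbols) {
        from <- c(from, r$head); to <- c(to, s)
        weight <- c(weight, a$weight); rule_i <- c(rule_i, i); alt_i <- c(alt_i, j)
      }
    }
  }
  autapse <- from == to
  # reachability among somata, for cycle-closure classification
  soma_edges <- cbind(from, to)[to %in% heads & !autapse, , drop = FALSE]
  reach <- matrix(FALSE, length(heads), length(heads),
                  dimnames = list(heads, heads))
  if (nrow(soma_edges) > 0 && length(heads) > 0) {
    ig <- igraph::graph_from_data_frame(
      as.data.frame(soma_edges, stringsAsFactors = FALSE),
      directed = TRUE, vertices = heads)
    dm <- igraph::distances(ig, mode = "out")
    reach <- is.finite(dm)[heads, heads, drop = FALSE]
  }
  recurrent <- logical(length(from))
  for (k in seq_along(from)) {
    if (autapse[k] || !(to[k] %in% heads)) next
    back_ref <- match(to[k], heads) <= rule_i[k]
    recurrent[k] <- back_ref && reach[to[k], from[k]]
  }
  projection <- to %in% names(kinds) & kinds[to] %in% c("quoted", "unquoted")
  edges <- data.frame(from = from, to = to, weight = weight, rule = rule_i,
                      alternate = alt_i, autapse = autapse,
                      recurrent = recurrent,
                      projection = unname(projection),
                      inhibitory = weight < 0.5,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "arg_circuit")
}

#' @export
print.arg_circuit <- function(x, ...) {
  s <- circuit_stats(x)
  cat(sprintf(paste0("<neural circuit> %d soma(ta), %d synapse(s) ",
                     "(%d autapse(s), %d recurrent), %d sensor / %d actuator port(s)\n"),
              s[["somata"]], s[["synapses"]], s[["autapses"]], s[["recurrent"]],
              s[["sensor_ports"]], s[["actuator_ports"]]))
  invisible(x)
}

#' Structural statistics of a circuit
#'
#' @param c circuit from [circuit_graph()].
#' @return named integer vector: `somata`, `synapses`, `autapses`,
#'   `recurrent` (regular recurrent synapses, autapses excluded),
#'   `sensor_ports`, `actuator_ports`. Invariant under nonterminal renaming.
#' @export
circuit_stats <- function(c) {
  stopifnot(inherits(c, "arg_circuit"))
  c(somata = sum(c$nodes$type == "soma"),
    synapses = nrow(c$edges),
    autapses = sum(c$edges$autapse),
    recurrent = sum(c$edges$recurrent),
    sensor_ports = sum(c$nodes$type == "sensor_port"),
    actuator_ports = sum(c$nodes$type == "actuator_port"))
}

#' Circuit as an igraph object
#'
#' @param c circuit from [circuit_graph()].
#' @export
circuit_igraph <- function(c) {
  igraph::graph_from_data_frame(c$edges, directed = TRUE, vertices = c$nodes)
}

dot_quote <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")

#' Render a circuit as DOT graph text
#'
#' Visual conventions become attributes: somata are inverted triangles,
#' actuator ports boxes, sensor ports circles; autapses are self-loops;
#' projection edges (quote/unquote) are dashed; weights label edges, and
#' edges below .5 carry an `inhibitory` class. The circuit graph is never
#' truncated: unlike the schema rendering, it is faithful to the recursive
#' structure.
#'
#' @param c circuit from [circuit_graph()].
#' @return a single DOT document string.
#' @export
circuit_to_dot <- function(c) {
  shape <- c(soma = "invtriangle", sensor_port = "circle",
             actuator_port = "box", quote_port = "note",
             unquote_port = "note")
  lines <- c("digraph circuit {")
  for (i in seq_len(nrow(c$nodes)))
    lines <- c(lines, sprintf("  %s [shape=%s, class=%s];",
                              dot_quote(c$nodes$id[i]),
                              shape[[c$nodes$type[i]]], c$nodes$type[i]))
  for (i in seq_len(nrow(c$edges))) {
    e <- c$edges[i, ]
    attrs <- c(sprintf("label=%s", dot_quote(fmt_weight(e$weight))))
    if (e$projection) attrs <- c(attrs, "style=dashed")
    if (e$autapse) attrs <- c(attrs, "class=autapse")
    else if (e$recurrent) attrs <- c(attrs, "class=recurrent")
    if (e$inhibitory) attrs <- c(attrs, "tooltip=inhibitory")
    lines <- c(lines, sprintf("  %s -> %s [%s];", dot_quote(e$from),
                              dot_quote(e$to), paste(attrs, collapse = ", ")))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Render a grammar's derivation schema as DOT graph text
#'
#' Expands the derivation tree from the start symbol, cutting recursion once
#' any head occurs more than `max_depth` times along a path (the recursive
#' schema is infinite; the cut is presentational only -- the circuit graph
#' has no such limitation). `max_depth = 0` renders the start symbol alone.
#'
#' @param g grammar.
#' @param max_depth recursion cut per head along a path (default 2).
#' @return a single DOT document string.
#' @export
grammar_to_dot <- function(g, max_depth = 2) {
  stopifnot(inherits(g, "arg_grammar"), max_depth >= 0)
  heads <- grammar_heads(g)
  counter <- 0L
  lines <- character()
  new_node <- function(label, stub = FALSE) {
    counter <<- counter + 1L
    id <- paste0("n", counter)
    style <- if (stub) ", style=dotted" else ""
    lines <<- c(lines, sprintf("  %s [label=%s%s];", id, dot_quote(label), style))
    id
  }
  expand <- function(sym, seen) {
    if (!(sym %in% heads)) return(new_node(sym))
    seen[sym] <- (if (sym %in% names(seen)) seen[[sym]] else 0L) + 1L
    if (seen[[sym]] > max_depth) return(new_node(sym, stub = TRUE))
    id <- new_node(sym)
    r <- g$rules[[match(sym, heads)]]
    for (a in r$alternates) {
      for (s in a$symbols) {
        child <- expand(s, seen)
        lines <<- c(lines, sprintf("  %s -> %s [label=%s];", id, child,
                                   dot_quote(fmt_weight(a$weight))))
      }
    }
    id
  }
  expand(heads[1], integer())
  paste(c("digraph schema {", lines, "}"), collapse = "\n")
}
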