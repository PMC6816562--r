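# Carrier-connectivity graphs ---------------------------------------------
#
# Breeds carrying a rare allele are linked through previously measured
# identity-by-descent (IBD) haplotype-sharing relationships.  Starting
# from the significant-sharing subgraph induced on carriers, non-carrier
# breeds are added greedily (a Steiner-style heuristic, not a proven
# optimum) until no further addition merges carrier components.  A
# carrier breed with no significant sharing at all attaches through its
# single highest non-significant partner, flagged as a fallback (dashed)
# edge.

#' Read an IBD haplotype-sharing edge list
#'
#' Delimited columns: `breed_a`, `breed_b`, `value` (sharing level,
#' arbitrary units, may be NA), `significant` (logical or 0/1).
#' Undirected; self-edges are rejected.
#'
#' @param path file path.
#' @param sep field separator.
#' @return validated `data.frame`.
#' @export
read_ibd_edges <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("breed_a", "breed_b", "value", "significant")
  if (!all(need %in% names(df)))
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  df$significant <- as.logical(df$significant)
  if (any(df$breed_a == df$breed_b)) stop("self-edges are not allowed")
  df
}

components_of <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("breed_a", "breed_b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::components(g)$no
}

edges_within <- function(edges, nodes) {
  edges[edges$breed_a %in% nodes & edges$breed_b %in% nodes, ,
        drop = FALSE]
}

#' Connect rare-allele carrier breeds through IBD sharing
#'
#' @param edges edge list from [read_ibd_edges()].
#' @param carriers character vector of carrier breed codes.
#' @param disallowed optional subset of `carriers` whose trait is
#'   disallowed by their breed standard (for node colouring only).
#' @return object of class `carrier_graph` with elements
#'   `nodes` (`breed`, `status` in carrier_permitted /
#'   carrier_disallowed / non_carrier_connector), `edges` (with
#'   `fallback` flag), `connectors` (breeds added), `not_represented`
#'   (carriers absent from the edge list), `unconnectable` (carriers
#'   still isolated after all additions) and `n_components`.
#' @export
connect_carriers <- function(edges, carriers, disallowed = character(0)) {
  if (!length(carriers)) stop("carriers must be nonempty")
  carriers <- sort(unique(carriers))
  all_nodes <- sort(unique(c(edges$breed_a, edges$breed_b)))
  not_represented <- setdiff(carriers, all_nodes)
  carriers_in <- intersect(carriers, all_nodes)
  sig <- edges[edges$significant, , drop = FALSE]

  # fallback attachment: carriers with zero significant edges anywhere
  sig_nodes <- unique(c(sig$breed_a, sig$breed_b))
  orphan <- setdiff(carriers_in, sig_nodes)
  fallback_edges <- NULL
  for (b in orphan) {
    cand <- edges[(edges$breed_a == b | edges$breed_b == b) &
                    !edges$significant & !is.na(edges$value), ,
                  drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$value, cand$breed_a, cand$breed_b), ,
                 drop = FALSE]
    fallback_edges <- rbind(fallback_edges, cand[1L, , drop = FALSE])
  }
  work <- sig
  if (!is.null(fallback_edges)) work <- rbind(work, fallback_edges)

  # greedy connector addition: at each step add the non-carrier breed
  # whose inclusion merges the most carrier components (ties break
  # lexicographically); when no single breed merges two components but
  # disconnected components remain reachable through a chain of
  # non-carriers, merge the closest pair of components along a shortest
  # path, adding its intermediates.  Stops when remaining components are
  # mutually unreachable.  A heuristic: not guaranteed minimal.
  work_nodes <- sort(unique(c(work$breed_a, work$breed_b, carriers_in)))
  g_work <- igraph::graph_from_data_frame(
    work[, c("breed_a", "breed_b")], directed = FALSE,
    vertices = data.frame(name = work_nodes))
  chosen <- character(0)
  repeat {
    active <- c(carriers_in, chosen)
    base_comp <- components_of(active, edges_within(work, active))
    if (base_comp == 1L) break
    candidates <- sort(setdiff(work_nodes, active))
    best <- NULL; best_gain <- 0L
    for (cand in candidates) {
      comp <- components_of(c(active, cand),
                            edges_within(work, c(active, cand))) - 1L
      gain <- base_comp - 1L - comp   # carrier components merged, net of
                                      # the candidate's own node
      if (gain > best_gain) { best_gain <- gain; best <- cand }
    }
    if (!is.null(best)) { chosen <- c(chosen, best); next }
    # chain fallback: shortest path between the closest pair of
    # active components through not-yet-chosen nodes
    memb <- local({
      ga <- igraph::graph_from_data_frame(
        edges_within(work, active)[, c("breed_a", "breed_b")],
        directed = FALSE, vertices = data.frame(name = active))
      igraph::components(ga)$membership
    })
    dmat <- igraph::distances(g_work, v = active, to = active)
    best_path <- NULL
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (memb[[active[i]]] >= memb[[active[j]]]) next
      d <- dmat[active[i], active[j]]
      if (!is.finite(d)) next
      if (is.null(best_path) || d < best_path$d) {
        sp <- igraph::shortest_paths(g_work, from = active[i],
                                     to = active[j])$vpath[[1L]]
        best_path <- list(d = d, nodes = names(sp))
      }
    }
    if (is.null(best_path)) break
    add <- setdiff(best_path$nodes, active)
    if (!length(add)) break
    chosen <- c(chosen, sort(add))
  }

  active <- c(carriers_in, chosen)
  final_edges <- edges_within(work, active)
  final_edges$fallback <- !final_edges$significant
  # carriers still isolated from every other carrier
  g <- igraph::graph_from_data_frame(
    final_edges[, c("breed_a", "breed_b")], directed = FALSE,
    vertices = data.frame(name = active))
  memb <- igraph::components(g)$membership
  carrier_comp <- memb[carriers_in]
  unconnectable <- carriers_in[
    vapply(carriers_in, function(b)
      sum(carrier_comp == memb[[b]]) == 1L, logical(1))]

  status <- ifelse(active %in% chosen, "non_carrier_connector",
                   ifelse(active %in% disallowed, "carrier_disallowed",
                          "carrier_permitted"))
  structure(list(
    nodes = data.frame(breed = active, status = status,
                       stringsAsFactors = FALSE),
    edges = final_edges,
    connectors = chosen,
    not_represented = not_represented,
    unconnectable = unconnectable,
    n_components = max(memb)), class = "carrier_graph")
}

#' @export
print.carrier_graph <- function(x, ...) {
  cat("<carrier_graph> ", nrow(x$nodes), " breeds, ",
      nrow(x$edges), " edges, ", length(x$connectors),
      " non-carrier connector(s), ", x$n_components, " component(s)\n",
      sep = "")
  if (length(x$not_represented))
    cat("  not represented in IBD data:",
        paste(x$not_represented, collapse = ", "), "\n")
  if (length(x$unconnectable))
    cat("  unconnectable carriers:",
        paste(x$unconnectable, collapse = ", "), "\n")
  invisible(x)
}

#' Export a carrier graph as an edge table
#'
#' @param graph a `carrier_graph`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_carrier_edges <- function(graph, path, sep = "\t") {
  utils::write.table(graph$edges, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export a carrier graph in DOT format for visualization
#'
#' Carrier nodes are green (permitted) or red (disallowed), connectors
#' grey; fallback attachments are dashed, matching the conventional
#' rendering of these networks.
#'
#' @param graph a `carrier_graph`.
#' @param path output path.
#' @export
write_carrier_dot <- function(graph, path) {
  col <- c(carrier_permitted = "green", carrier_disallowed = "red",
           non_carrier_connector = "grey")
  lines <- c("graph carriers {",
             sprintf("  \"%s\" [color=%s];", graph$nodes$breed,
                     col[graph$nodes$status]))
  if (nrow(graph$edges))
    lines <- c(lines,
               sprintf("  \"%s\" -- \"%s\"%s;", graph$edges$breed_a,
                       graph$edges$breed_b,
                       ifelse(graph$edges$fallback, " [style=dashed]", "")))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
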