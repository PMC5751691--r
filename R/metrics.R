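# Source-to-terminal betweenness degrees on an identified subnetwork.
# Because the subnetwork is a tree, the path between any source/terminal
# pair is unique, so betweenness reduces to counting, for every element,
# the ordered pairs (i in S, j in T', i != j) whose unique tree path
# contains it. The implementation uses a single rooted traversal with
# subtree source/terminal counts rather than per-pair path walks.

#' Source-to-terminal betweenness degrees
#'
#' For every ordered pair of a source protein `i` and a terminal protein
#' `j` (`i != j`, both restricted to the tree), the unique tree path from
#' `i` to `j` contributes 1 to the betweenness degree of every protein on
#' it — endpoints included — and of every interaction on it. A protein that
#' is both a source and a terminal additionally scores 1 for the degenerate
#' pair `i = j` (vertex only, no interaction).
#'
#' @param tree A `solution_tree` (acyclic, connected).
#' @param sources Character vector of source proteins; silently intersected
#'   with the tree's vertices.
#' @param terminals Character vector of terminal proteins; likewise
#'   intersected.
#' @return A `betweenness_report`: `node_B` (named integer), `edge_B`
#'   (data frame `from`, `to`, `B`), `sources_used`, `terminals_used`, and
#'   unset selection fields (see [select_important()]).
#' @export
#' @examples
#' tr <- solution_tree(c("s", "a", "t"),
#'                     data.frame(from = c("s", "a"), to = c("a", "t")))
#' st_betweenness(tr, "s", "t")
st_betweenness <- function(tree, sources, terminals) {
  stopifnot(inherits(tree, "solution_tree"))
  verts <- tree$vertices
  nv <- length(verts)
  Sv <- sort(intersect(unique(as.character(sources)), verts),
             method = "radix")
  Tv <- sort(intersect(unique(as.character(terminals)), verts),
             method = "radix")

  node_B <- stats::setNames(integer(nv), verts)
  edge_B <- data.frame(from = tree$edges$from, to = tree$edges$to,
                       B = integer(nrow(tree$edges)),
                       stringsAsFactors = FALSE)
  if (nv == 0L || length(Sv) == 0L || length(Tv) == 0L)
    return(new_betweenness_report(node_B, edge_B, Sv, Tv))

  is_s <- verts %in% Sv
  is_t <- verts %in% Tv
  S_tot <- sum(is_s); T_tot <- sum(is_t); ST_tot <- sum(is_s & is_t)
  N <- S_tot * T_tot - ST_tot           # ordered pairs with i != j

  if (nv == 1L) {
    node_B[1L] <- ST_tot                # only the degenerate i = j pair
    return(new_betweenness_report(node_B, edge_B, Sv, Tv))
  }

  ef <- match(tree$edges$from, verts)
  et <- match(tree$edges$to, verts)
  adj <- vector("list", nv)
  for (k in seq_along(ef)) {
    adj[[ef[k]]] <- c(adj[[ef[k]]], k)
    adj[[et[k]]] <- c(adj[[et[k]]], k)
  }
  # BFS rooting at vertex 1
  parent <- rep(NA_integer_, nv)
  parent_edge <- rep(NA_integer_, nv)
  bfs <- integer(nv); seen <- logical(nv)
  bfs[1L] <- 1L; seen[1L] <- TRUE; qn <- 1L; qi <- 1L
  while (qi <= qn) {
    v <- bfs[qi]; qi <- qi + 1L
    for (k in adj[[v]]) {
      u <- if (ef[k] == v) et[k] else ef[k]
      if (!seen[u]) {
        seen[u] <- TRUE; parent[u] <- v; parent_edge[u] <- k
        qn <- qn + 1L; bfs[qn] <- u
      }
    }
  }
  # subtree counts of sources / terminals / source-and-terminal vertices
  sc <- as.integer(is_s); tc <- as.integer(is_t); stc <- as.integer(is_s & is_t)
  for (v in rev(bfs)) {
    if (!is.na(parent[v])) {
      sc[parent[v]] <- sc[parent[v]] + sc[v]
      tc[parent[v]] <- tc[parent[v]] + tc[v]
      stc[parent[v]] <- stc[parent[v]] + stc[v]
    }
  }
  # edge (v, parent(v)): pairs whose endpoints straddle the edge
  for (v in seq_len(nv)) {
    if (is.na(parent[v])) next
    k <- parent_edge[v]
    edge_B$B[k] <- sc[v] * (T_tot - tc[v]) + (S_tot - sc[v]) * tc[v]
  }
  # vertex m: pairs not confined to a single component of tree minus m,
  # plus the degenerate i = j pair when m is both source and terminal
  children <- split(which(!is.na(parent)), parent[!is.na(parent)])
  for (v in seq_len(nv)) {
    ch <- children[[as.character(v)]]
    same <- 0L
    if (!is.null(ch))
      same <- sum(sc[ch] * tc[ch] - stc[ch])
    if (!is.na(parent[v])) {
      sa <- S_tot - sc[v]; ta <- T_tot - tc[v]; sta <- ST_tot - stc[v]
      same <- same + (sa * ta - sta)
    }
    node_B[v] <- N - same + (is_s[v] && is_t[v])
  }
  new_betweenness_report(node_B, edge_B, Sv, Tv)
}

new_betweenness_report <- function(node_B, edge_B, Sv, Tv,
                                   threshold = NA_integer_,
                                   selected_nodes = character(),
                                   selected_edges = NULL) {
  if (is.null(selected_edges))
    selected_edges <- edge_B[integer(), , drop = FALSE]
  structure(list(node_B = node_B, edge_B = edge_B, threshold = threshold,
                 selected_nodes = selected_nodes,
                 selected_edges = selected_edges,
                 sources_used = Sv, terminals_used = Tv),
            class = "betweenness_report")
}

#' Select important elements by betweenness threshold
#'
#' Elements whose betweenness degree strictly exceeds the threshold are
#' selected. The `"auto"` threshold is `max(|S|, |T'|)` (both restricted to
#' the tree): a protein that merely relays every pair for a single source
#' or terminal scores exactly this much, so strict exceedance singles out
#' genuine junctions.
#'
#' @param report A `betweenness_report` from [st_betweenness()].
#' @param threshold `"auto"` (default) or a nonnegative integer.
#' @return The report with `threshold`, `selected_nodes` and
#'   `selected_edges` filled in.
#' @export
select_important <- function(report, threshold = "auto") {
  stopifnot(inherits(report, "betweenness_report"))
  if (identical(threshold, "auto")) {
    threshold <- max(length(report$sources_used),
                     length(report$terminals_used))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("`threshold` must be \"auto\" or a single nonnegative number",
         call. = FALSE)
  report$threshold <- threshold
  report$selected_nodes <- names(report$node_B)[report$node_B > threshold]
  report$selected_edges <-
    report$edge_B[report$edge_B$B > threshold, , drop = FALSE]
  rownames(report$selected_edges) <- NULL
  report
}

#' @export
print.betweenness_report <- function(x, ...) {
  cat(sprintf(paste0("Betweenness report: %d proteins, %d interactions ",
                     "(%d sources, %d terminals)\n"),
              length(x$node_B), nrow(x$edge_B),
              length(x$sources_used), length(x$terminals_used)))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold %s: %d proteins and %d interactions selected\n",
                format(x$threshold), length(x$selected_nodes),
                nrow(x$selected_edges)))
  top <- sort(x$node_B, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  if (length(top) > 0L)
    cat("  top proteins:",
        paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
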