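# Node-weighted Steiner instances built from protein-protein interaction
# records and pathway annotations.

#' Parameter set for instance generation and solving
#'
#' Bundles the constants that turn interaction confidence scores into edge
#' costs and vertex degrees into node weights, plus the solver knobs.
#'
#' @param alpha Positive scaling constant of the edge-cost transform
#'   `cost = alpha / con^beta`. The default puts typical costs of
#'   experimentally scored interactions in the low hundreds.
#' @param beta Positive exponent of the edge-cost transform; larger values
#'   spread costs of high- and low-confidence interactions further apart.
#' @param gamma Positive constant of the node-weight transform
#'   `weight = -gamma / degree` for non-terminal proteins.
#' @param boost Fractional confidence increase applied to interactions that
#'   are annotated as pathway members (0.5 means "+50%").
#' @param s Edge-splitting ratio of the growing phase (`s >= 1`); an edge of
#'   cost c is split into slacks `c/s` and `(s-1)c/s`.
#' @param mu Merge tolerance of the growing phase. `NULL` (default) resolves
#'   to `1e-6` times the mean edge cost of the instance being solved.
#' @param seed Integer seed used for the pruning root draw.
#'
#' @return A list of class `nw_params`.
#' @export
#' @examples
#' nw_params(gamma = 10)
nw_params <- function(alpha = 2e6, beta = 2, gamma = 5, boost = 0.5,
                      s = 2, mu = NULL, seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            is.numeric(boost), length(boost) == 1L, boost >= 0,
            is.numeric(s), length(s) == 1L, s >= 1,
            is.null(mu) || (is.numeric(mu) && length(mu) == 1L && mu > 0))
  structure(list(alpha = alpha, beta = beta, gamma = gamma, boost = boost,
                 s = s, mu = mu, seed = as.integer(seed)),
            class = "nw_params")
}

#' Edge cost from an interaction confidence score
#'
#' Transforms a confidence score `con` into a positive edge cost
#' `alpha / con_eff^beta`, where `con_eff` is the score increased by
#' `boost * 100` percent when the interaction is a known pathway member.
#' Higher confidence gives lower cost, so minimum-cost subnetworks prefer
#' well-supported interactions.
#'
#' @param con Positive confidence score(s).
#' @param alpha,beta Positive transform constants (see [nw_params()]).
#' @param in_pathway Logical; is the interaction an annotated pathway member?
#' @param boost Fractional confidence increase for pathway members.
#'
#' @return Numeric vector of positive edge costs.
#' @export
#' @examples
#' edge_cost(100, alpha = 2e6, beta = 2)              # 200
#' edge_cost(400, alpha = 2e6, beta = 2,
#'           in_pathway = TRUE, boost = 0.5)          # 2e6 / 600^2
edge_cost <- function(con, alpha = 2e6, beta = 2, in_pathway = FALSE,
                      boost = 0.5) {
  if (!is.numeric(con) || any(!is.finite(con)) || any(con <= 0))
    stop("`con` must be positive and finite", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  if (!is.numeric(boost) || length(boost) != 1L || boost < 0)
    stop("`boost` must be a single nonnegative number", call. = FALSE)
  in_pathway <- rep_len(as.logical(in_pathway), length(con))
  con_eff <- ifelse(in_pathway, con * (1 + boost), con)
  alpha / con_eff^beta
}

#' Node weight from vertex degree
#'
#' Non-terminal proteins get weight `-gamma / degree`: low-degree proteins
#' are penalised more strongly, so the identified subnetwork avoids poorly
#' connected detours. Compulsory terminals are REQUIRED — their inclusion is
#' a hard constraint, represented by the sentinel `NA_real_` rather than a
#' floating infinity so that no arithmetic ever produces non-finite values.
#'
#' @param degree Vertex degree(s) in the cleaned interaction network
#'   (positive integers).
#' @param gamma Positive constant (see [nw_params()]).
#' @param is_terminal Logical; is the vertex a compulsory terminal?
#'
#' @return Numeric vector: `-gamma/degree` for non-terminals, `NA_real_`
#'   (the REQUIRED sentinel) for terminals.
#' @export
#' @examples
#' node_weight(10, gamma = 5)                  # -0.5
#' node_weight(3, gamma = 5, is_terminal = TRUE)  # NA (REQUIRED)
node_weight <- function(degree, gamma = 5, is_terminal = FALSE) {
  if (!is.numeric(degree) || any(degree < 1) || any(degree != floor(degree)))
    stop("`degree` must be a positive integer (no isolated vertices)",
         call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive number", call. = FALSE)
  is_terminal <- rep_len(as.logical(is_terminal), length(degree))
  ifelse(is_terminal, NA_real_, -gamma / degree)
}

#' Pathway annotation
#'
#' @param sources Character vector of source protein identifiers (where
#'   signals enter the pathway, e.g. receptor tyrosine kinases).
#' @param terminals Character vector of terminal protein identifiers
#'   (downstream effectors where signals end).
#' @param pathway_edges Optional two-column matrix or data frame of
#'   unordered protein pairs that are annotated pathway members; their
#'   confidence scores receive the boost during edge-cost computation.
#'
#' @return A list of class `pathway_annotation`.
#' @export
pathway_annotation <- function(sources, terminals, pathway_edges = NULL) {
  sources <- unique(as.character(sources))
  terminals <- unique(as.character(terminals))
  if (length(sources) + length(terminals) == 0L)
    stop("at least one source or terminal protein is required", call. = FALSE)
  if (any(!nzchar(c(sources, terminals))))
    stop("blank protein identifiers are not allowed", call. = FALSE)
  if (!is.null(pathway_edges)) {
    pathway_edges <- as.data.frame(pathway_edges, stringsAsFactors = FALSE)
    if (ncol(pathway_edges) < 2L)
      stop("`pathway_edges` needs two identifier columns", call. = FALSE)
    pathway_edges <- canonical_pairs(as.character(pathway_edges[[1L]]),
                                     as.character(pathway_edges[[2L]]))
  } else {
    pathway_edges <- data.frame(from = character(), to = character(),
                                stringsAsFactors = FALSE)
  }
  structure(list(sources = sources, terminals = terminals,
                 pathway_edges = pathway_edges),
            class = "pathway_annotation")
}

# Canonical unordered-pair representation: from < to in C-locale byte order
# (radix rank), the same ordering the edge-splitting rule uses for i < j.
canonical_pairs <- function(a, b) {
  u <- sort(unique(c(a, b)), method = "radix")
  swap <- match(a, u) > match(b, u)
  data.frame(from = ifelse(swap, b, a), to = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

pair_key <- function(from, to) paste(from, to, sep = "\r")

#' Build a node-weighted Steiner instance
#'
#' Constructs the instance graph from raw interaction records: self-loops
#' are dropped, parallel records of the same pair are collapsed to the
#' minimum cost (the most confident evidence wins), vertex degrees are taken
#' on this cleaned graph, compulsory terminals are the annotated source and
#' terminal proteins present in the graph, and the graph is restricted to
#' the connected component containing the terminals.
#'
#' @param records Data frame with columns `protein_a`, `protein_b`, `con`
#'   (positive confidence score) and optionally `in_pathway` (logical). When
#'   `in_pathway` is absent it is derived from `annotation$pathway_edges`.
#' @param annotation A [pathway_annotation()].
#' @param params A [nw_params()].
#' @param on_no_terminal `"error"` or `"warn"`: what to do when none of the
#'   annotated proteins appears in the network.
#'
#' @return A list of class `nw_instance` with elements `nodes`, `edges`
#'   (data frame `from`, `to`, `cost`), `weight` (named numeric, `NA_real_`
#'   for REQUIRED terminals), `degree` (named integer, degrees of the
#'   cleaned graph), `terminals`, and `params`.
#' @export
build_instance <- function(records, annotation, params = nw_params(),
                           on_no_terminal = c("error", "warn")) {
  on_no_terminal <- match.arg(on_no_terminal)
  stopifnot(inherits(annotation, "pathway_annotation"),
            inherits(params, "nw_params"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "con")
  if (!all(need %in% names(records)))
    stop("`records` must have columns protein_a, protein_b, con",
         call. = FALSE)
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  a <- as.character(records$protein_a)
  b <- as.character(records$protein_b)
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("blank protein identifiers in `records`", call. = FALSE)
  con <- as.numeric(records$con)
  if (any(!is.finite(con)) || any(con <= 0))
    stop("confidence scores must be positive", call. = FALSE)

  keep <- a != b                      # drop self-loops
  a <- a[keep]; b <- b[keep]; con <- con[keep]
  if (length(a) == 0L) stop("no edges left after removing self-loops",
                            call. = FALSE)
  pairs <- canonical_pairs(a, b)

  in_pw <- if ("in_pathway" %in% names(records)) {
    as.logical(records$in_pathway)[keep]
  } else rep(FALSE, length(a))
  if (nrow(annotation$pathway_edges) > 0L) {
    pw_keys <- pair_key(annotation$pathway_edges$from,
                        annotation$pathway_edges$to)
    in_pw <- in_pw | (pair_key(pairs$from, pairs$to) %in% pw_keys)
  }

  cost <- edge_cost(con, alpha = params$alpha, beta = params$beta,
                    in_pathway = in_pw, boost = params$boost)

  # collapse duplicates, keeping minimal cost
  key <- pair_key(pairs$from, pairs$to)
  o <- order(key, cost, method = "radix")
  first <- !duplicated(key[o])
  edges <- data.frame(from = pairs$from[o][first], to = pairs$to[o][first],
                      cost = cost[o][first], stringsAsFactors = FALSE)
  eo <- order(edges$from, edges$to, method = "radix")
  edges <- edges[eo, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- sort(unique(c(edges$from, edges$to)), method = "radix")
  terminals <- sort(intersect(union(annotation$sources, annotation$terminals),
                              nodes), method = "radix")
  if (length(terminals) == 0L) {
    msg <- "no annotated source/terminal protein appears in the network"
    if (on_no_terminal == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  # restrict to the component containing the terminals
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    if (length(terminals) > 0L) {
      tc <- unique(comp$membership[terminals])
      if (length(tc) > 1L)
        stop("infeasible instance: terminals span ", length(tc),
             " connected components", call. = FALSE)
      keep_nodes <- names(comp$membership)[comp$membership == tc]
    } else {
      keep_nodes <- names(comp$membership)[
        comp$membership == which.max(comp$csize)]
      warning("disconnected network without terminals; keeping the largest ",
              "component", call. = FALSE)
    }
    nodes <- sort(intersect(nodes, keep_nodes), method = "radix")
    edges <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
    rownames(edges) <- NULL
  }

  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  degree <- stats::setNames(as.integer(deg), nodes)
  weight <- node_weight(degree, gamma = params$gamma,
                        is_terminal = nodes %in% terminals)
  names(weight) <- nodes

  new_nw_instance(nodes, edges, weight, degree, terminals, params)
}

new_nw_instance <- function(nodes, edges, weight, degree, terminals, params) {
  structure(list(nodes = nodes, edges = edges, weight = weight,
                 degree = degree, terminals = terminals, params = params),
            class = "nw_instance")
}

#' Validate an instance against its structural invariants
#'
#' Checks positive edge costs, terminal containment, finite non-terminal
#' weights and connectivity. Single-vertex edgeless instances (as produced
#' by the reductions) are allowed.
#'
#' @param x An `nw_instance`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_instance <- function(x) {
  stopifnot(inherits(x, "nw_instance"))
  if (any(x$edges$cost <= 0)) stop("nonpositive edge cost", call. = FALSE)
  if (!all(x$terminals %in% x$nodes))
    stop("terminal not among vertices", call. = FALSE)
  nonterm <- setdiff(x$nodes, x$terminals)
  if (any(!is.finite(x$weight[nonterm])))
    stop("non-terminal with non-finite weight", call. = FALSE)
  if (any(!is.na(x$weight[x$terminals])))
    stop("terminal without REQUIRED sentinel weight", call. = FALSE)
  if (nrow(x$edges) > 0L || length(x$nodes) > 1L) {
    g <- instance_graph(x)
    if (!igraph::is_connected(g)) stop("instance is disconnected",
                                       call. = FALSE)
    if (length(x$nodes) > 1L && any(igraph::degree(g) == 0L))
      stop("isolated vertex", call. = FALSE)
  }
  invisible(x)
}

instance_graph <- function(x) {
  igraph::graph_from_data_frame(x$edges[, c("from", "to")],
                                directed = FALSE, vertices = x$nodes)
}

#' @export
print.nw_instance <- function(x, ...) {
  cat("Node-weighted Steiner instance\n")
  cat(sprintf("  %d vertices, %d edges, %d compulsory terminals\n",
              length(x$nodes), nrow(x$edges), length(x$terminals)))
  if (nrow(x$edges) > 0L)
    cat(sprintf("  edge costs: [%.4g, %.4g]\n",
                min(x$edges$cost), max(x$edges$cost)))
  invisible(x)
}

#' Solution tree
#'
#' A connected acyclic subnetwork. `edges` may be empty for a single-vertex
#' (or empty) tree.
#'
#' @param vertices Character vector of vertex identifiers.
#' @param edges Data frame with columns `from`, `to` (stored in canonical
#'   unordered-pair form).
#' @return A list of class `solution_tree`.
#' @export
solution_tree <- function(vertices, edges = NULL) {
  vertices <- sort(unique(as.character(vertices)), method = "radix")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- canonical_pairs(as.character(edges$from),
                             as.character(edges$to))
    edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  tr <- structure(list(vertices = vertices, edges = edges),
                  class = "solution_tree")
  if (length(vertices) > 0L) {
    if (nrow(edges) != length(vertices) - 1L)
      stop("not a tree: |E| != |V| - 1", call. = FALSE)
    if (!all(c(edges$from, edges$to) %in% vertices))
      stop("tree edge with endpoint outside vertex set", call. = FALSE)
    if (nrow(edges) > 0L) {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = vertices)
      if (!igraph::is_connected(g)) stop("tree is disconnected",
                                         call. = FALSE)
    }
  }
  tr
}

#' @export
print.solution_tree <- function(x, ...) {
  cat(sprintf("Solution tree: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Objective value of a solution tree
#'
#' Total edge cost minus total finite node weight of the included
#' non-terminal vertices. REQUIRED terminals contribute zero: their
#' inclusion is enforced, so dropping their (conceptually infinite) reward
#' keeps objective comparisons finite and does not change solution rankings.
#'
#' @param instance An `nw_instance`.
#' @param tree A `solution_tree`, a subgraph of `instance` containing all
#'   compulsory terminals.
#' @return A single numeric objective value (lower is better).
#' @export
objective_value <- function(instance, tree) {
  stopifnot(inherits(instance, "nw_instance"),
            inherits(tree, "solution_tree"))
  if (!all(tree$vertices %in% instance$nodes))
    stop("tree vertex not in instance", call. = FALSE)
  if (!all(instance$terminals %in% tree$vertices))
    stop("tree does not contain all compulsory terminals", call. = FALSE)
  ec <- 0
  if (nrow(tree$edges) > 0L) {
    key <- pair_key(instance$edges$from, instance$edges$to)
    idx <- match(pair_key(tree$edges$from, tree$edges$to), key)
    if (anyNA(idx)) stop("tree edge not in instance", call. = FALSE)
    ec <- sum(instance$edges$cost[idx])
  }
  nonterm <- setdiff(tree$vertices, instance$terminals)
  ec - sum(instance$weight[nonterm])
}

# cost lookup for a set of canonical pairs
edge_cost_lookup <- function(instance, from, to) {
  key <- pair_key(instance$edges$from, instance$edges$to)
  instance$edges$cost[match(pair_key(from, to), key)]
}
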