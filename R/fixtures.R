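# Curated PI3K/Akt-MAPK reference subnetwork, a synthetic PPI-style
# instance generator, and brute-force oracles used to validate the solver
# and the betweenness metrics.

# ASCII-safe canonical identifiers with display names for the Greek/format
# variants (beta-catenin, IkBa, PDGFRalpha/beta, ...).
fixture_display_names <- c(
  AKT1 = "AKT1", PIK3R1 = "PIK3R1", p53 = "p53", MDM2 = "MDM2",
  EP300 = "EP300", HER1 = "HER1", Grb2 = "Grb2", CTNNB1 = "beta-catenin",
  RELA = "RELA", PDGFRA = "PDGFRalpha", PDGFRB = "PDGFRbeta",
  IGF1R = "IGF1R", ERBB2 = "ERBB2", INSRR = "INSRR", FGFR1 = "FGFR1",
  FGFR2 = "FGFR2", IKBA = "IkBalpha", NFKB = "NF-kB", p27 = "p27",
  p21 = "p21", LEF1 = "LEF1", TCF7L1 = "TCF7L1", TCF7 = "TCF7",
  TCF7L2 = "TCF7L2", AR = "AR", BAD = "BAD", CASP9 = "Caspase9",
  mTOR = "mTOR", FOXO1 = "FOXO1")

fixture_edge_table <- function() {
  # 28 interactions of the identified PI3K/Akt-MAPK subnetwork, with the
  # published interaction betweenness degrees
  e <- rbind(
    c("AKT1", "PIK3R1", 112), c("AKT1", "MDM2", 64), c("p53", "MDM2", 64),
    c("EP300", "p53", 56), c("PIK3R1", "HER1", 56), c("HER1", "Grb2", 42),
    c("EP300", "CTNNB1", 40), c("EP300", "RELA", 16),
    c("PDGFRA", "PIK3R1", 14), c("PDGFRB", "PIK3R1", 14),
    c("IGF1R", "PIK3R1", 14), c("ERBB2", "Grb2", 14),
    c("PIK3R1", "FGFR1", 14), c("Grb2", "INSRR", 14),
    c("Grb2", "FGFR2", 14),
    c("IKBA", "NFKB", 8), c("IKBA", "RELA", 8), c("p27", "AKT1", 8),
    c("p21", "AKT1", 8), c("LEF1", "CTNNB1", 8), c("AKT1", "BAD", 8),
    c("AKT1", "CASP9", 8), c("AKT1", "mTOR", 8), c("AKT1", "FOXO1", 8),
    c("TCF7L1", "CTNNB1", 8), c("TCF7", "CTNNB1", 8),
    c("CTNNB1", "AR", 8), c("CTNNB1", "TCF7L2", 8))
  data.frame(protein_a = e[, 1L], protein_b = e[, 2L],
             betweenness = as.integer(e[, 3L]), stringsAsFactors = FALSE)
}

fixture_node_betweenness <- function() {
  # published protein betweenness degrees of the identified subnetwork
  c(AKT1 = 112L, PIK3R1 = 112L, p53 = 64L, MDM2 = 64L, EP300 = 56L,
    HER1 = 56L, Grb2 = 42L, CTNNB1 = 40L, RELA = 16L, PDGFRA = 14L,
    PDGFRB = 14L, IGF1R = 14L, ERBB2 = 14L, INSRR = 14L, FGFR1 = 14L,
    FGFR2 = 14L, IKBA = 8L, NFKB = 8L, p27 = 8L, p21 = 8L, LEF1 = 8L,
    TCF7L1 = 8L, BAD = 8L, CASP9 = 8L, TCF7 = 8L, mTOR = 8L, AR = 8L,
    FOXO1 = 8L, TCF7L2 = 8L)
}

#' The identified PI3K/Akt-MAPK reference subnetwork
#'
#' The published 29-protein, 28-interaction subnetwork identified for the
#' PI3K/Akt and MAPK signaling pathways, together with its 8 source
#' proteins (receptor tyrosine kinases), 14 terminal proteins (downstream
#' effectors), and the published betweenness degrees of every protein and
#' interaction. The source/terminal labeling is derived: it is the unique
#' 8/14 assignment under which the recomputed betweenness degrees reproduce
#' every published value, and the package's test suite re-validates this.
#'
#' @return A list of class `fixture_subnetwork` with elements `tree`
#'   (`solution_tree`), `sources`, `terminals`, `node_betweenness` (named
#'   integer, published), `edge_betweenness` (data frame, published), and
#'   `display_names` (canonical id to display name).
#' @export
#' @examples
#' fx <- pi3k_mapk_subnetwork()
#' length(fx$tree$vertices)  # 29
pi3k_mapk_subnetwork <- function() {
  et <- fixture_edge_table()
  tree <- solution_tree(unique(c(et$protein_a, et$protein_b)),
                        data.frame(from = et$protein_a, to = et$protein_b,
                                   stringsAsFactors = FALSE))
  eb <- canonical_pairs(et$protein_a, et$protein_b)
  eb$B <- et$betweenness
  structure(list(
    tree = tree,
    sources = c("PDGFRA", "PDGFRB", "IGF1R", "ERBB2", "INSRR", "FGFR1",
                "FGFR2", "HER1"),
    terminals = c("p53", "RELA", "NFKB", "p27", "p21", "LEF1", "TCF7L1",
                  "TCF7", "TCF7L2", "AR", "BAD", "CASP9", "mTOR", "FOXO1"),
    node_betweenness = fixture_node_betweenness(),
    edge_betweenness = eb,
    display_names = fixture_display_names
  ), class = "fixture_subnetwork")
}

#' Reference subnetwork as pipeline inputs
#'
#' Emits the reference subnetwork in the same interaction-record and
#' annotation form the full pipeline consumes, so build, preprocessing,
#' solving and metrics can run on it unmodified. All interactions get the
#' same confidence score and are marked as pathway members; since the
#' subnetwork is a tree containing every compulsory terminal, it is the
#' unique feasible solution regardless of the scores.
#'
#' @param con Confidence score assigned to every interaction.
#' @return A list with `records` (data frame) and `annotation`
#'   ([pathway_annotation()]).
#' @export
pi3k_mapk_inputs <- function(con = 100) {
  fx <- pi3k_mapk_subnetwork()
  et <- fixture_edge_table()
  records <- data.frame(protein_a = et$protein_a, protein_b = et$protein_b,
                        con = con, in_pathway = TRUE,
                        stringsAsFactors = FALSE)
  ann <- pathway_annotation(fx$sources, fx$terminals,
                            records[, c("protein_a", "protein_b")])
  list(records = records, annotation = ann)
}

#' Generate a synthetic PPI-style instance
#'
#' Builds a connected, scale-free-ish interaction network (preferential
#' attachment tree plus random extra edges) with confidence scores drawn so
#' that the default edge-cost transform lands costs roughly in the 100-300
#' range typical of experimentally scored interactions, and plants a
#' connected pathway whose member interactions are flagged and whose
#' designated sources/terminals become the compulsory terminals.
#'
#' @param n_vertices Number of proteins.
#' @param n_edges Number of interactions (`>= n_vertices - 1`).
#' @param score_range Length-2 numeric; confidence scores are drawn
#'   uniformly from this range.
#' @param planted_pathway_size Number of proteins in the planted pathway.
#' @param n_sources,n_terminals How many planted proteins to designate as
#'   sources / terminals (`n_sources + n_terminals <=
#'   planted_pathway_size`).
#' @param seed Integer seed; output is reproducible.
#' @return A list with `records`, `annotation` and `planted` (character
#'   vector of planted pathway proteins).
#' @export
#' @examples
#' sx <- synth_ppi_instance(20, 40, seed = 1)
#' inst <- build_instance(sx$records, sx$annotation)
synth_ppi_instance <- function(n_vertices = 50, n_edges = 150,
                               score_range = c(80, 145),
                               planted_pathway_size = 10,
                               n_sources = 3, n_terminals = 4,
                               seed = 1L) {
  stopifnot(n_vertices >= 2, n_edges >= n_vertices - 1,
            n_edges <= n_vertices * (n_vertices - 1) / 2,
            planted_pathway_size >= 2,
            planted_pathway_size <= n_vertices,
            n_sources >= 1, n_terminals >= 1,
            n_sources + n_terminals <= planted_pathway_size,
            length(score_range) == 2L, all(score_range > 0))
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_vertices))
    g <- igraph::sample_pa(n_vertices, m = 1, directed = FALSE)
    el <- igraph::as_edgelist(g, names = TRUE)
    from <- ids[as.integer(el[, 1L])]
    to <- ids[as.integer(el[, 2L])]
    # extra random edges up to n_edges, no duplicates or loops
    have <- pair_key(canonical_pairs(from, to)$from,
                     canonical_pairs(from, to)$to)
    need <- n_edges - length(from)
    while (need > 0L) {
      a <- ids[sample.int(n_vertices, 2L * need, replace = TRUE)]
      b <- ids[sample.int(n_vertices, 2L * need, replace = TRUE)]
      ok <- a != b
      cp <- canonical_pairs(a[ok], b[ok])
      key <- pair_key(cp$from, cp$to)
      fresh <- !(key %in% have) & !duplicated(key)
      take <- which(fresh)[seq_len(min(need, sum(fresh)))]
      from <- c(from, cp$from[take]); to <- c(to, cp$to[take])
      have <- c(have, key[take])
      need <- n_edges - length(from)
    }
    con <- stats::runif(length(from), score_range[1L], score_range[2L])

    # plant a connected pathway: BFS ball around a random seed vertex
    gg <- igraph::graph_from_data_frame(data.frame(from, to),
                                        directed = FALSE, vertices = ids)
    start <- ids[sample.int(n_vertices, 1L)]
    bfs <- igraph::bfs(gg, root = start, order = TRUE)
    planted <- igraph::V(gg)$name[as.integer(bfs$order)][
      seq_len(planted_pathway_size)]
    in_pw <- from %in% planted & to %in% planted
    roles <- sample(planted, n_sources + n_terminals)
    sources <- roles[seq_len(n_sources)]
    terminals <- roles[n_sources + seq_len(n_terminals)]

    records <- data.frame(protein_a = from, protein_b = to, con = con,
                          in_pathway = in_pw, stringsAsFactors = FALSE)
    pw_edges <- records[records$in_pathway, c("protein_a", "protein_b")]
    ann <- pathway_annotation(sources, terminals,
                              if (nrow(pw_edges)) pw_edges else NULL)
    list(records = records, annotation = ann, planted = planted)
  })
}

#' Exact node-weighted Steiner optimum by exhaustive enumeration
#'
#' Enumerates every vertex subset containing all compulsory terminals whose
#' induced subgraph is connected, scores each by its minimum spanning tree
#' cost minus the finite node weights it includes, and returns the global
#' minimum. Intended as an independent oracle on tiny instances only.
#'
#' @param instance An `nw_instance` with at most 12 vertices.
#' @return A list with `tree` (`solution_tree`) and `objective`.
#' @export
brute_force_steiner <- function(instance) {
  stopifnot(inherits(instance, "nw_instance"))
  n <- length(instance$nodes)
  if (n > 12L) stop("brute force refused: more than 12 vertices",
                    call. = FALSE)
  optional <- setdiff(instance$nodes, instance$terminals)
  k <- length(optional)
  best_obj <- Inf
  best_tree <- NULL
  if (length(instance$terminals) == 0L) {
    best_obj <- 0                       # the empty tree
    best_tree <- solution_tree(character())
  }
  key <- pair_key(instance$edges$from, instance$edges$to)
  for (mask in 0:(2^k - 1)) {
    U <- c(instance$terminals,
           optional[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L])
    if (length(U) == 0L) next
    sub <- instance$edges[instance$edges$from %in% U &
                            instance$edges$to %in% U, , drop = FALSE]
    if (length(U) == 1L) {
      treedf <- sub[integer(), c("from", "to"), drop = FALSE]
      cost <- 0
    } else {
      if (nrow(sub) < length(U) - 1L) next
      g <- igraph::graph_from_data_frame(sub[, c("from", "to")],
                                         directed = FALSE, vertices = U)
      if (!igraph::is_connected(g)) next
      mst <- igraph::mst(g, weights = sub$cost)
      treedf <- igraph::as_data_frame(mst, what = "edges")[, c("from", "to")]
      idx <- match(pair_key(canonical_pairs(treedf$from, treedf$to)$from,
                            canonical_pairs(treedf$from, treedf$to)$to), key)
      cost <- sum(instance$edges$cost[idx])
    }
    nonterm <- setdiff(U, instance$terminals)
    obj <- cost - sum(instance$weight[nonterm])
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_tree <- solution_tree(U, treedf)
    }
  }
  list(tree = best_tree, objective = best_obj)
}

#' Betweenness degrees by explicit per-pair path walks
#'
#' Independent oracle for [st_betweenness()]: walks the unique tree path of
#' every ordered source/terminal pair and tallies elements directly.
#'
#' @inheritParams st_betweenness
#' @return A `betweenness_report` (selection fields unset).
#' @export
brute_force_betweenness <- function(tree, sources, terminals) {
  stopifnot(inherits(tree, "solution_tree"))
  verts <- tree$vertices
  Sv <- sort(intersect(unique(as.character(sources)), verts),
             method = "radix")
  Tv <- sort(intersect(unique(as.character(terminals)), verts),
             method = "radix")
  node_B <- stats::setNames(integer(length(verts)), verts)
  edge_B <- data.frame(from = tree$edges$from, to = tree$edges$to,
                       B = integer(nrow(tree$edges)),
                       stringsAsFactors = FALSE)
  if (length(verts) == 0L || length(Sv) == 0L || length(Tv) == 0L)
    return(new_betweenness_report(node_B, edge_B, Sv, Tv))
  ekey <- pair_key(edge_B$from, edge_B$to)
  g <- if (nrow(tree$edges) > 0L) {
    igraph::graph_from_data_frame(tree$edges, directed = FALSE,
                                  vertices = verts)
  } else NULL
  for (i in Sv) {
    for (j in Tv) {
      if (i == j) {
        node_B[i] <- node_B[i] + 1L
        next
      }
      p <- igraph::shortest_paths(g, from = i, to = j,
                                  output = "vpath")$vpath[[1L]]
      pv <- igraph::V(g)$name[as.integer(p)]
      node_B[pv] <- node_B[pv] + 1L
      if (length(pv) > 1L) {
        cp <- canonical_pairs(pv[-length(pv)], pv[-1L])
        idx <- match(pair_key(cp$from, cp$to), ekey)
        edge_B$B[idx] <- edge_B$B[idx] + 1L
      }
    }
  }
  new_betweenness_report(node_B, edge_B, Sv, Tv)
}
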