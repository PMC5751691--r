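# Optimum-preserving degree-1 reductions for node-weighted Steiner
# instances. Both tests only ever delete leaves, so connectivity is
# preserved, and every removal is recorded in a ledger that allows exact
# reassembly of a full solution from a solution of the reduced instance.

empty_ledger <- function() {
  structure(list(
    forced_edges = data.frame(from = character(), to = character(),
                              cost = numeric(), terminal = character(),
                              kept = character(), absorbed_weight = numeric(),
                              stringsAsFactors = FALSE),
    removed_vertices = data.frame(vertex = character(), neighbor = character(),
                                  cost = numeric(), weight = numeric(),
                                  stringsAsFactors = FALSE),
    removed_edges = data.frame(from = character(), to = character(),
                               cost = numeric(), reason = character(),
                               stringsAsFactors = FALSE),
    contraction_map = character()
  ), class = "reduction_ledger")
}

merge_ledgers <- function(a, b) {
  a$forced_edges <- rbind(a$forced_edges, b$forced_edges)
  a$removed_vertices <- rbind(a$removed_vertices, b$removed_vertices)
  a$removed_edges <- rbind(a$removed_edges, b$removed_edges)
  a$contraction_map <- c(a$contraction_map, b$contraction_map)
  a
}

#' @export
print.reduction_ledger <- function(x, ...) {
  cat(sprintf(paste0("Reduction ledger: %d forced edges, ",
                     "%d removed non-terminal leaves\n"),
              nrow(x$forced_edges), nrow(x$removed_vertices)))
  invisible(x)
}

instance_degrees <- function(instance) {
  deg <- table(factor(c(instance$edges$from, instance$edges$to),
                      levels = instance$nodes))
  stats::setNames(as.integer(deg), instance$nodes)
}

drop_vertex <- function(instance, v) {
  keep <- instance$edges$from != v & instance$edges$to != v
  instance$edges <- instance$edges[keep, , drop = FALSE]
  instance$nodes <- setdiff(instance$nodes, v)
  instance$weight <- instance$weight[instance$nodes]
  instance$degree <- instance$degree[instance$nodes]
  instance$terminals <- setdiff(instance$terminals, v)
  instance
}

#' Terminal degree-1 test
#'
#' When at least two compulsory terminals remain, the single edge incident
#' to a degree-1 terminal must be part of the optimal solution. The edge is
#' recorded as forced, the terminal is removed, and terminal status is
#' transferred to its neighbor (standard Steiner contraction). With fewer
#' than two terminals the test never applies: a lone degree-1 terminal can
#' itself be the whole optimal solution.
#'
#' @param instance An `nw_instance`.
#' @param fixpoint Apply repeatedly until no degree-1 terminal remains
#'   (default); `FALSE` performs a single sweep over the terminals that are
#'   degree-1 at entry.
#' @return A list with elements `instance` (reduced) and `ledger`
#'   (`reduction_ledger`).
#' @export
terminal_degree1_test <- function(instance, fixpoint = TRUE) {
  stopifnot(inherits(instance, "nw_instance"))
  led <- empty_ledger()
  initial <- instance$terminals
  # contraction transfers terminal status to the neighbor; original
  # terminals are processed before such newly created ones (FIFO by
  # generation, then lexicographic), so a path between two terminals
  # contracts inward from both ends
  generation <- stats::setNames(integer(length(initial)), initial)
  repeat {
    if (length(instance$terminals) < 2L) break
    deg <- instance_degrees(instance)
    cand <- instance$terminals[deg[instance$terminals] == 1L]
    if (!fixpoint) cand <- intersect(cand, initial)
    if (length(cand) == 0L) break
    cand <- sort(cand, method = "radix")
    t <- cand[order(generation[cand])][1L]
    hit <- instance$edges$from == t | instance$edges$to == t
    e <- instance$edges[hit, , drop = FALSE][1L, ]
    u <- if (e$from == t) e$to else e$from
    absorbed <- if (u %in% instance$terminals) 0 else instance$weight[[u]]
    led$forced_edges <- rbind(led$forced_edges, data.frame(
      from = e$from, to = e$to, cost = e$cost, terminal = t, kept = u,
      absorbed_weight = absorbed, stringsAsFactors = FALSE))
    led$removed_edges <- rbind(led$removed_edges, data.frame(
      from = e$from, to = e$to, cost = e$cost, reason = "terminal_degree1",
      stringsAsFactors = FALSE))
    led$contraction_map[t] <- u
    instance <- drop_vertex(instance, t)
    if (!(u %in% instance$terminals)) {
      instance$terminals <- sort(c(instance$terminals, u), method = "radix")
      instance$weight[u] <- NA_real_
      generation[u] <- generation[[t]] + 1L
    }
  }
  list(instance = instance, ledger = led)
}

#' Non-terminal degree-1 test
#'
#' Any non-terminal leaf `i` with incident edge `(i,j)` satisfying
#' `w(i) <= c(i,j)` cannot improve a solution: attaching it adds cost
#' `c(i,j) - w(i) >= 0`. Such leaves are deleted with their edge, repeatedly
#' (removals expose new leaves) until a fixpoint. Requires at least one
#' compulsory terminal; with `T` empty the test never applies.
#'
#' @inheritParams terminal_degree1_test
#' @param fixpoint Iterate until no removable leaf remains (default);
#'   `FALSE` performs one sweep.
#' @return A list with elements `instance` and `ledger`.
#' @export
nonterminal_degree1_test <- function(instance, fixpoint = TRUE) {
  stopifnot(inherits(instance, "nw_instance"))
  led <- empty_ledger()
  if (length(instance$terminals) < 1L) return(list(instance = instance,
                                                   ledger = led))
  repeat {
    deg <- instance_degrees(instance)
    leaves <- setdiff(names(deg)[deg == 1L], instance$terminals)
    if (length(leaves) == 0L) break
    removed_any <- FALSE
    for (v in sort(leaves, method = "radix")) {
      hit <- instance$edges$from == v | instance$edges$to == v
      e <- instance$edges[hit, , drop = FALSE]
      if (nrow(e) != 1L) next          # degree changed within this sweep
      if (instance$weight[[v]] <= e$cost[1L]) {
        j <- if (e$from[1L] == v) e$to[1L] else e$from[1L]
        led$removed_vertices <- rbind(led$removed_vertices, data.frame(
          vertex = v, neighbor = j, cost = e$cost[1L],
          weight = instance$weight[[v]], stringsAsFactors = FALSE))
        led$removed_edges <- rbind(led$removed_edges, data.frame(
          from = e$from[1L], to = e$to[1L], cost = e$cost[1L],
          reason = "nonterminal_degree1", stringsAsFactors = FALSE))
        instance <- drop_vertex(instance, v)
        removed_any <- TRUE
      }
    }
    if (!removed_any || !fixpoint) break
  }
  list(instance = instance, ledger = led)
}

#' Preprocess an instance with both degree-1 tests
#'
#' Alternates the terminal and non-terminal degree-1 tests. In the default
#' `"fixpoint"` mode the alternation repeats until neither test changes the
#' instance; `"single_pass"` applies each test's single sweep once, the
#' literal one-shot behavior.
#'
#' @inheritParams terminal_degree1_test
#' @param mode `"fixpoint"` (default) or `"single_pass"`.
#' @return A list with elements `instance` (reduced) and `ledger` (merged
#'   `reduction_ledger`).
#' @export
preprocess_instance <- function(instance, mode = c("fixpoint",
                                                   "single_pass")) {
  mode <- match.arg(mode)
  led <- empty_ledger()
  if (mode == "single_pass") {
    r1 <- terminal_degree1_test(instance, fixpoint = FALSE)
    r2 <- nonterminal_degree1_test(r1$instance, fixpoint = FALSE)
    return(list(instance = r2$instance,
                ledger = merge_ledgers(merge_ledgers(led, r1$ledger),
                                       r2$ledger)))
  }
  repeat {
    size <- c(length(instance$nodes), nrow(instance$edges))
    r1 <- terminal_degree1_test(instance, fixpoint = TRUE)
    led <- merge_ledgers(led, r1$ledger)
    r2 <- nonterminal_degree1_test(r1$instance, fixpoint = TRUE)
    led <- merge_ledgers(led, r2$ledger)
    instance <- r2$instance
    if (identical(size, c(length(instance$nodes), nrow(instance$edges))))
      break
  }
  list(instance = instance, ledger = led)
}

#' Replay a reduction ledger
#'
#' Applies the recorded removals to the original instance, reproducing the
#' reduced instance exactly. Used to audit that the ledger is a complete
#' account of the preprocessing.
#'
#' @param instance The original `nw_instance`.
#' @param ledger A `reduction_ledger`.
#' @return The reduced `nw_instance`.
#' @export
replay_ledger <- function(instance, ledger) {
  for (k in seq_len(nrow(ledger$forced_edges))) {
    f <- ledger$forced_edges[k, ]
    instance <- drop_vertex(instance, f$terminal)
    if (!(f$kept %in% instance$terminals)) {
      instance$terminals <- sort(c(instance$terminals, f$kept),
                                 method = "radix")
      instance$weight[f$kept] <- NA_real_
    }
  }
  for (v in ledger$removed_vertices$vertex)
    instance <- drop_vertex(instance, v)
  instance
}

# Re-attach forced edges (and their contracted terminals) to a solution
# tree computed on the reduced instance. Reverse order guarantees the kept
# endpoint of each forced edge is already present.
reattach_forced <- function(tree, ledger) {
  fe <- ledger$forced_edges
  if (nrow(fe) == 0L) return(tree)
  verts <- tree$vertices
  edges <- tree$edges
  for (k in rev(seq_len(nrow(fe)))) {
    verts <- c(verts, fe$terminal[k])
    edges <- rbind(edges, data.frame(from = fe$from[k], to = fe$to[k],
                                     stringsAsFactors = FALSE))
  }
  solution_tree(verts, edges)
}
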