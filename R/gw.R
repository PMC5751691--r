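# Modified unrooted Goemans-Williamson moat growing with dynamic edge
# splitting over positive and negative node weights, followed by strong
# pruning. The growing phase maintains one cluster per vertex (slack = node
# weight; compulsory terminals never run out of slack and never
# deactivate), splits every edge into two parts sharing its cost at ratio
# 1:(s-1), and processes edge and cluster events in order of a global
# clock. Unlike the prize-collecting original, a merged cluster may be
# born inactive because the slack of an inactive merge partner can be
# negative.

# save/restore RNG around a seeded draw so solver calls never disturb the
# caller's random stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Growing phase of the modified Goemans-Williamson algorithm
#'
#' Grows moats around vertex clusters under a global clock. Each edge is
#' split into two parts with initial slacks `c/s` and `(s-1)c/s` (the part
#' with the lexicographically smaller owner gets `c/s`). An edge part whose
#' slack reaches zero triggers an edge event: if the partner part's
#' remaining slack `r` is below `mu` the two clusters merge (the new slack
#' is the sum, which may be nonpositive, in which case the merged cluster is
#' born inactive); otherwise the remaining slack is re-split — evenly when
#' the partner's cluster is active, fully onto the firing part when it is
#' inactive. A cluster event deactivates the cluster whose slack ran out.
#' The loop ends when at most one active cluster remains; the merge edges
#' inside the final active cluster (or, if none is active, the cluster
#' deactivated last) form the raw solution tree.
#'
#' @param instance A connected `nw_instance`.
#' @param s Edge-splitting ratio, `s >= 1`.
#' @param mu Positive merge tolerance; `NULL` resolves to `1e-6` times the
#'   mean edge cost.
#' @return A raw `solution_tree` (not yet pruned).
#' @export
gw_grow <- function(instance, s = 2, mu = NULL) {
  stopifnot(inherits(instance, "nw_instance"), is.numeric(s), s >= 1)
  validate_instance(instance)
  verts <- instance$nodes
  n <- length(verts)
  m <- nrow(instance$edges)
  if (length(instance$terminals) == 0L)
    warning("no compulsory terminals; growing from positive-weight clusters",
            call. = FALSE)
  if (n <= 1L) return(solution_tree(verts))
  if (is.null(mu)) mu <- 1e-6 * mean(instance$edges$cost)
  stopifnot(is.numeric(mu), mu > 0)

  fi <- match(instance$edges$from, verts)
  ti <- match(instance$edges$to, verts)
  cost <- instance$edges$cost

  # edge parts: p in 1..m owned by `from` (slack c/s), p in m+1..2m owned
  # by `to` (slack (s-1)c/s); partner(p) = p +- m
  owner <- c(fi, ti)
  part_edge <- c(seq_len(m), seq_len(m))
  part_event <- c(cost / s, (s - 1) * cost / s)
  part_dead <- logical(2L * m)

  # union-find
  parent <- seq_len(n)
  uf_find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  required <- verts %in% instance$terminals
  w <- ifelse(required, 0, instance$weight)
  cl_required <- required
  cl_active <- required | w > 0
  cl_event <- ifelse(required, Inf, w)        # time when slack hits 0
  cl_deact <- ifelse(cl_active, NA_real_, 0)  # inactive from the start
  members <- as.list(seq_len(n))
  is_root <- rep(TRUE, n)

  t_g <- 0
  n_active <- sum(cl_active)
  raw_edges <- integer()
  # each edge re-splits at most ~log2(c/mu) times before r < mu
  max_iter <- n + 10L + 2L * m * (ceiling(log2(max(cost) / mu + 2)) + 4L)
  iter <- 0L

  while (n_active > 1L) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("growing phase failed to terminate (internal error)",
           call. = FALSE)

    owner_root <- vapply(owner, uf_find, integer(1L))
    live <- !part_dead & cl_active[owner_root]
    t_e <- Inf; p1 <- NA_integer_
    if (any(live)) {
      idx <- which(live)
      p1 <- idx[which.min(part_event[idx])]
      t_e <- part_event[p1]
    }
    roots <- which(is_root)
    ccand <- roots[cl_active[roots] & !cl_required[roots]]
    t_c <- Inf; cR <- NA_integer_
    if (length(ccand) > 0L) {
      cR <- ccand[which.min(cl_event[ccand])]
      t_c <- cl_event[cR]
    }
    if (!is.finite(t_e) && !is.finite(t_c)) break

    if (t_e <= t_c) {
      t_g <- t_e
      p2 <- if (p1 > m) p1 - m else p1 + m
      r1 <- owner_root[p1]
      r2 <- uf_find(owner[p2])
      if (r1 == r2) {                  # edge became internal
        part_dead[c(p1, p2)] <- TRUE
        next
      }
      r <- if (cl_active[r2]) part_event[p2] - t_g
           else part_event[p2] - cl_deact[r2]
      r <- max(r, 0)
      if (r < mu) {
        # merge event
        raw_edges <- c(raw_edges, part_edge[p1])
        sl1 <- if (cl_required[r1]) Inf else cl_event[r1] - t_g
        sl2 <- if (cl_required[r2]) Inf
               else if (cl_active[r2]) cl_event[r2] - t_g
               else cl_event[r2] - cl_deact[r2]
        if (!cl_active[r2]) {
          # re-base the frozen edge parts of the inactive cluster
          shift <- t_g - cl_deact[r2]
          pidx <- which(!part_dead & owner %in% members[[r2]])
          part_event[pidx] <- part_event[pidx] + shift
        }
        was_active <- cl_active[r1] + cl_active[r2]
        R <- min(r1, r2); other <- max(r1, r2)
        parent[other] <- R
        is_root[other] <- FALSE
        members[[R]] <- c(members[[R]], members[[other]])
        members[other] <- list(NULL)
        cl_required[R] <- cl_required[r1] || cl_required[r2]
        sl <- sl1 + sl2
        if (cl_required[R]) {
          cl_active[R] <- TRUE; cl_event[R] <- Inf; cl_deact[R] <- NA_real_
        } else if (sl > 0) {
          cl_active[R] <- TRUE; cl_event[R] <- t_g + sl
          cl_deact[R] <- NA_real_
        } else {
          cl_active[R] <- FALSE; cl_event[R] <- t_g + sl; cl_deact[R] <- t_g
        }
        n_active <- n_active - was_active + cl_active[R]
        part_dead[c(p1, p2)] <- TRUE
      } else if (cl_active[r2]) {
        # Case 1: partner active; split the remaining slack evenly
        part_event[p1] <- t_g + r / 2
        part_event[p2] <- t_g + r / 2
      } else {
        # Case 2: partner inactive; assume it stays so until this edge
        # merges, so the firing part absorbs all remaining slack
        part_event[p1] <- t_g + r
        part_event[p2] <- cl_deact[r2]
      }
    } else {
      # cluster event
      t_g <- t_c
      cl_active[cR] <- FALSE
      cl_deact[cR] <- t_g
      n_active <- n_active - 1L
    }
  }

  roots <- which(is_root)
  act <- roots[cl_active[roots]]
  R <- if (length(act) >= 1L) {
    act[1L]
  } else {
    # no active cluster left: take the one deactivated last
    roots[order(-cl_deact[roots], roots)][1L]
  }
  mem <- members[[R]]
  keep <- raw_edges[fi[raw_edges] %in% mem & ti[raw_edges] %in% mem]
  solution_tree(verts[mem],
                instance$edges[keep, c("from", "to"), drop = FALSE])
}

#' Strong pruning of a raw solution tree
#'
#' Roots the tree at a randomly chosen compulsory terminal and processes
#' the non-root vertices from the leaves inward. A vertex `i` with parent
#' `j` is cut off (with its whole subtree) when its accumulated reward
#' `nw(i)` cannot pay for the connecting edge, `c(i,j) > nw(i)`; otherwise
#' the parent absorbs the surplus, `nw(j) <- nw(j) + nw(i) - c(i,j)`.
#' Branches carrying a compulsory terminal are never cut (REQUIRED weight
#' dominates any edge cost).
#'
#' @param raw A `solution_tree` from [gw_grow()] containing at least one
#'   compulsory terminal.
#' @param instance The `nw_instance` the tree was grown on.
#' @param seed Integer seed for the root draw (the only randomness).
#' @return The pruned `solution_tree`; contains every terminal of `raw`.
#' @export
strong_prune <- function(raw, instance, seed = 1L) {
  stopifnot(inherits(raw, "solution_tree"), inherits(instance, "nw_instance"))
  terms <- sort(intersect(instance$terminals, raw$vertices),
                method = "radix")
  if (length(terms) == 0L)
    stop("raw tree contains no compulsory terminal", call. = FALSE)
  nv <- length(raw$vertices)
  if (nv <= 1L) return(raw)
  root <- with_seed(seed, terms[sample.int(length(terms), 1L)])

  vid <- match(raw$vertices, raw$vertices)
  adj <- vector("list", nv)
  ef <- match(raw$edges$from, raw$vertices)
  et <- match(raw$edges$to, raw$vertices)
  ecost <- edge_cost_lookup(instance, raw$edges$from, raw$edges$to)
  for (k in seq_along(ef)) {
    adj[[ef[k]]] <- c(adj[[ef[k]]], k)
    adj[[et[k]]] <- c(adj[[et[k]]], k)
  }

  # BFS from the root for parent pointers and processing order
  ri <- match(root, raw$vertices)
  parent <- rep(NA_integer_, nv)
  parent_cost <- rep(NA_real_, nv)
  order_bfs <- integer(nv)
  seen <- logical(nv)
  queue <- ri; seen[ri] <- TRUE; qi <- 1L; qn <- 1L
  while (qi <= qn) {
    v <- queue[qi]; order_bfs[qi] <- v; qi <- qi + 1L
    for (k in adj[[v]]) {
      u <- if (ef[k] == v) et[k] else ef[k]
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        parent_cost[u] <- ecost[k]
        qn <- qn + 1L
        queue[qn] <- u
      }
    }
  }

  req <- raw$vertices %in% instance$terminals
  nw <- ifelse(req, 0, instance$weight[raw$vertices])
  cut <- logical(nv)
  # reverse BFS order: children are always handled before their parent,
  # which is exactly the processing-degree-1 discipline
  for (v in rev(order_bfs)) {
    if (v == ri) next
    j <- parent[v]
    if (req[v]) {
      req[j] <- TRUE                    # REQUIRED propagates upward
    } else if (parent_cost[v] > nw[v]) {
      cut[v] <- TRUE                    # removes v and its whole subtree
    } else {
      nw[j] <- nw[j] + nw[v] - parent_cost[v]
    }
  }
  # a vertex survives iff no vertex on its path to the root was cut
  keep <- logical(nv)
  for (v in order_bfs) {
    keep[v] <- !cut[v] && (is.na(parent[v]) || keep[parent[v]])
  }
  kept_edges <- which(!is.na(parent) & keep)
  solution_tree(raw$vertices[keep],
                data.frame(from = raw$vertices[kept_edges],
                           to = raw$vertices[parent[kept_edges]],
                           stringsAsFactors = FALSE))
}

#' Solve a node-weighted Steiner instance
#'
#' Full solving pipeline: optional degree-1 preprocessing, moat growing,
#' strong pruning, and reassembly of the forced edges recorded during
#' preprocessing. The result is a connected acyclic subnetwork containing
#' every compulsory terminal. Deterministic for fixed `seed`.
#'
#' @param instance A connected `nw_instance`.
#' @param s,mu,seed Solver parameters; `NULL` falls back to
#'   `instance$params`.
#' @param preprocess Run the degree-1 reductions first (default `TRUE`).
#' @param reduction_mode Passed to [preprocess_instance()].
#' @return A `solution_tree`.
#' @export
#' @examples
#' fx <- pi3k_mapk_inputs()
#' inst <- build_instance(fx$records, fx$annotation)
#' tr <- nwst_solve(inst)
#' length(tr$vertices)
nwst_solve <- function(instance, s = NULL, mu = NULL, seed = NULL,
                       preprocess = TRUE,
                       reduction_mode = c("fixpoint", "single_pass")) {
  stopifnot(inherits(instance, "nw_instance"))
  reduction_mode <- match.arg(reduction_mode)
  p <- instance$params
  if (is.null(s)) s <- if (is.null(p$s)) 2 else p$s
  if (is.null(mu)) mu <- p$mu          # may stay NULL: resolved in gw_grow
  if (is.null(seed)) seed <- if (is.null(p$seed)) 1L else p$seed

  if (length(instance$terminals) == 0L) {
    warning("instance has no compulsory terminals; returning the empty tree",
            call. = FALSE)
    return(solution_tree(character()))
  }
  led <- empty_ledger()
  work <- instance
  if (isTRUE(preprocess)) {
    red <- preprocess_instance(instance, mode = reduction_mode)
    work <- red$instance
    led <- red$ledger
  }
  raw <- gw_grow(work, s = s, mu = mu)
  pruned <- strong_prune(raw, work, seed = seed)
  out <- reattach_forced(pruned, led)
  if (!all(instance$terminals %in% out$vertices))
    stop("internal error: solution lost a compulsory terminal",
         call. = FALSE)
  out
}
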