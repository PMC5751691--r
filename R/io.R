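# Readers and writers: delimited interaction tables, structured pathway
# annotations, an STP-style instance dialect extended with node weights,
# and delimited result tables.

#' Read an interaction edge list
#'
#' Tab- or comma-delimited text with a header. Column order is irrelevant;
#' columns are located by name: `protein_a`, `protein_b` and `score` (or
#' `con`), plus an optional logical `in_pathway`.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return A data frame with columns `protein_a`, `protein_b`, `con` and,
#'   if present in the file, `in_pathway`.
#' @export
read_interactions <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("interaction file not found: ", path,
                               call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "",
                         quote = "\"")
  names(d) <- tolower(names(d))
  score_col <- intersect(c("score", "con", "confidence"), names(d))[1L]
  if (!all(c("protein_a", "protein_b") %in% names(d)) || is.na(score_col))
    stop("header must name protein_a, protein_b and score/con columns",
         call. = FALSE)
  out <- data.frame(protein_a = as.character(d$protein_a),
                    protein_b = as.character(d$protein_b),
                    con = as.numeric(d[[score_col]]),
                    stringsAsFactors = FALSE)
  if ("in_pathway" %in% names(d)) out$in_pathway <- as.logical(d$in_pathway)
  out
}

#' Write an interaction edge list
#'
#' @param records Data frame as accepted by [build_instance()].
#' @param path Output path; the separator is tab.
#' @export
write_interactions <- function(records, path) {
  d <- records
  names(d)[names(d) == "con"] <- "score"
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway annotation
#'
#' YAML (or JSON, which YAML subsumes) with keys `sources`, `terminals`
#' and optional `pathway_edges` (a list of two-element identifier pairs).
#'
#' @param path File path.
#' @return A [pathway_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  pe <- NULL
  if (!is.null(y$pathway_edges) && length(y$pathway_edges) > 0L) {
    pe <- do.call(rbind, lapply(y$pathway_edges, function(p)
      data.frame(from = as.character(p[[1L]]), to = as.character(p[[2L]]),
                 stringsAsFactors = FALSE)))
  }
  pathway_annotation(unlist(y$sources), unlist(y$terminals), pe)
}

#' Write a pathway annotation
#'
#' @param annotation A [pathway_annotation()].
#' @param path Output path (YAML).
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  pe <- annotation$pathway_edges
  yaml::write_yaml(list(
    sources = as.list(annotation$sources),
    terminals = as.list(annotation$terminals),
    pathway_edges = if (nrow(pe)) lapply(seq_len(nrow(pe)), function(k)
      list(pe$from[k], pe$to[k])) else list()
  ), path)
  invisible(path)
}

# full-precision number formatting so text round-trips are exact
fmt_num <- function(x) sprintf("%.17g", x)

#' Write an instance in the extended STP dialect
#'
#' SteinLib-style STP text with the usual `Graph` and `Terminals` sections,
#' extended with a `NodeWeights` section (`RQ` marks the REQUIRED terminal
#' sentinel), a `Names` section mapping vertex indices to protein
#' identifiers, and a `Parameters` section. Numbers are written at full
#' precision so [read_instance_stp()] round-trips exactly.
#'
#' @param instance An `nw_instance`.
#' @param path Output path.
#' @export
write_instance_stp <- function(instance, path) {
  stopifnot(inherits(instance, "nw_instance"))
  idx <- stats::setNames(seq_along(instance$nodes), instance$nodes)
  p <- instance$params
  lines <- c(
    "33D32945 STP File, STP Format Version 1.0",
    "",
    "SECTION Comment",
    "Name \"node-weighted PPI Steiner instance\"",
    "Creator \"nwsteiner\"",
    "END",
    "",
    "SECTION Parameters",
    paste("P alpha", fmt_num(p$alpha)),
    paste("P beta", fmt_num(p$beta)),
    paste("P gamma", fmt_num(p$gamma)),
    paste("P boost", fmt_num(p$boost)),
    paste("P s", fmt_num(p$s)),
    paste("P mu", if (is.null(p$mu)) "default" else fmt_num(p$mu)),
    paste("P seed", p$seed),
    "END",
    "",
    "SECTION Graph",
    paste("Nodes", length(instance$nodes)),
    paste("Edges", nrow(instance$edges)),
    sprintf("E %d %d %s", idx[instance$edges$from], idx[instance$edges$to],
            fmt_num(instance$edges$cost)),
    "END",
    "",
    "SECTION Terminals",
    paste("Terminals", length(instance$terminals)),
    sprintf("T %d", idx[instance$terminals]),
    "END",
    "",
    "SECTION NodeWeights",
    vapply(seq_along(instance$nodes), function(k) {
      w <- instance$weight[[k]]
      if (is.na(w)) sprintf("NW %d RQ", k)
      else sprintf("NW %d %s", k, fmt_num(w))
    }, character(1L)),
    "END",
    "",
    "SECTION Names",
    sprintf("N %d %s", seq_along(instance$nodes), instance$nodes),
    "END",
    "",
    "EOF")
  writeLines(lines, path)
  invisible(path)
}

#' Read an instance from the extended STP dialect
#'
#' @param path File written by [write_instance_stp()].
#' @return An `nw_instance`.
#' @export
read_instance_stp <- function(path) {
  if (!file.exists(path)) stop("instance file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  grab <- function(prefix) {
    x <- lines[startsWith(lines, paste0(prefix, " "))]
    lapply(strsplit(x, " +"), function(f) f[-1L])
  }
  pars <- grab("P")
  pl <- stats::setNames(lapply(pars, `[`, 2L), vapply(pars, `[`, "", 1L))
  mu <- if (identical(pl$mu, "default")) NULL else as.numeric(pl$mu)
  params <- nw_params(alpha = as.numeric(pl$alpha),
                      beta = as.numeric(pl$beta),
                      gamma = as.numeric(pl$gamma),
                      boost = as.numeric(pl$boost),
                      s = as.numeric(pl$s), mu = mu,
                      seed = as.integer(pl$seed))
  nm <- grab("N")
  nodes <- character(length(nm))
  for (f in nm) nodes[as.integer(f[1L])] <- f[2L]
  ed <- grab("E")
  edges <- data.frame(
    from = nodes[vapply(ed, function(f) as.integer(f[1L]), 1L)],
    to = nodes[vapply(ed, function(f) as.integer(f[2L]), 1L)],
    cost = vapply(ed, function(f) as.numeric(f[3L]), 1.0),
    stringsAsFactors = FALSE)
  term_idx <- vapply(grab("T"), function(f) as.integer(f[1L]), 1L)
  terminals <- sort(nodes[term_idx], method = "radix")
  wlines <- grab("NW")
  weight <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  for (f in wlines) {
    weight[as.integer(f[1L])] <- if (identical(f[2L], "RQ")) NA_real_
                                 else as.numeric(f[2L])
  }
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  new_nw_instance(nodes, edges, weight,
                  stats::setNames(as.integer(deg), nodes),
                  terminals, params)
}

#' Write a solution tree as an edge-list text file
#'
#' One `# vertex:` header line per tree vertex (so single-vertex trees are
#' representable), then a tab-delimited `from`/`to` edge table.
#'
#' @param tree A `solution_tree`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "solution_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vertex: %s", tree$vertices), con)
  writeLines("from\tto", con)
  if (nrow(tree$edges) > 0L)
    writeLines(sprintf("%s\t%s", tree$edges$from, tree$edges$to), con)
  invisible(path)
}

#' Read a solution tree written by [write_tree()]
#'
#' @param path File path.
#' @return A `solution_tree`.
#' @export
read_tree <- function(path) {
  lines <- readLines(path)
  verts <- sub("^# vertex: ", "", lines[startsWith(lines, "# vertex: ")])
  body <- lines[!startsWith(lines, "#")]
  edges <- NULL
  if (length(body) > 1L) {
    f <- strsplit(body[-1L], "\t", fixed = TRUE)
    edges <- data.frame(from = vapply(f, `[`, "", 1L),
                        to = vapply(f, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  }
  solution_tree(verts, edges)
}

#' Write a betweenness report as delimited tables
#'
#' Two tab-delimited tables mirroring the published result layout: one row
#' per protein and per interaction, with the betweenness degree and a
#' `selected` flag.
#'
#' @param report A `betweenness_report` (after [select_important()] if
#'   selection flags are wanted).
#' @param node_path,edge_path Output paths.
#' @export
write_betweenness_report <- function(report, node_path, edge_path) {
  stopifnot(inherits(report, "betweenness_report"))
  nb <- data.frame(protein = names(report$node_B),
                   betweenness = as.integer(report$node_B),
                   selected = names(report$node_B) %in%
                     report$selected_nodes,
                   stringsAsFactors = FALSE)
  nb <- nb[order(-nb$betweenness, nb$protein, method = "radix"), ]
  utils::write.table(nb, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sel_key <- pair_key(report$selected_edges$from, report$selected_edges$to)
  ebd <- report$edge_B
  eb <- data.frame(protein_1 = ebd$from, protein_2 = ebd$to,
                   betweenness = as.integer(ebd$B),
                   selected = pair_key(ebd$from, ebd$to) %in% sel_key,
                   stringsAsFactors = FALSE)
  eb <- eb[order(-eb$betweenness, eb$protein_1, eb$protein_2,
                 method = "radix"), ]
  utils::write.table(eb, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}
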