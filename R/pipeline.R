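# End-to-end orchestration: build -> preprocess -> solve -> metrics, with
# a reproducible run manifest, plus a beta/gamma parameter-sweep harness.

#' Run configuration
#'
#' @param interactions Path to an interaction edge list
#'   (see [read_interactions()]).
#' @param annotation Path to a pathway annotation (see [read_annotation()]).
#' @param out_dir Output directory (created if missing).
#' @param params A [nw_params()].
#' @param threshold `"auto"` or a nonnegative integer, passed to
#'   [select_important()].
#' @param preprocess Run the degree-1 reductions before solving.
#' @param reduction_mode `"fixpoint"` or `"single_pass"`.
#' @param quiet Suppress stage messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(interactions, annotation, out_dir,
                       params = nw_params(), threshold = "auto",
                       preprocess = TRUE,
                       reduction_mode = c("fixpoint", "single_pass"),
                       quiet = FALSE) {
  stopifnot(inherits(params, "nw_params"))
  structure(list(interactions = interactions, annotation = annotation,
                 out_dir = out_dir, params = params, threshold = threshold,
                 preprocess = preprocess,
                 reduction_mode = match.arg(reduction_mode),
                 quiet = isTRUE(quiet)),
            class = "run_config")
}

stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] ...")
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  list(value = res, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full identification pipeline
#'
#' Reads the interaction and annotation inputs, builds the node-weighted
#' instance, reduces it, solves it, scores the identified subnetwork with
#' source-to-terminal betweenness, and writes all artifacts to
#' `config$out_dir`: the instance (`instance.stp`), reduction statistics
#' (`reduction_stats.tsv`), the solution tree (`tree.tsv`), the betweenness
#' tables (`nodes_betweenness.tsv`, `edges_betweenness.tsv`), and a run
#' manifest (`manifest.json`). Inputs are validated before anything is
#' written, so a failing run leaves no partial outputs. Given a fixed seed,
#' the tree and report files are byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory `instance`, `reduced`
#'   instance, `ledger`, `tree`, `report` and the `manifest` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  quiet <- config$quiet
  for (f in c(config$interactions, config$annotation))
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)

  timings <- list()
  st <- stage("read", quiet, {
    list(records = read_interactions(config$interactions),
         annotation = read_annotation(config$annotation))
  }); timings$read <- st$elapsed
  inputs <- st$value

  st <- stage("build", quiet,
              build_instance(inputs$records, inputs$annotation,
                             params = config$params))
  timings$build <- st$elapsed
  instance <- st$value

  if (config$preprocess) {
    st <- stage("preprocess", quiet,
                preprocess_instance(instance, mode = config$reduction_mode))
    timings$preprocess <- st$elapsed
    reduced <- st$value$instance
    ledger <- st$value$ledger
  } else {
    reduced <- instance
    ledger <- empty_ledger()
  }

  st <- stage("solve", quiet, {
    raw <- gw_grow(reduced, s = config$params$s, mu = config$params$mu)
    pruned <- strong_prune(raw, reduced, seed = config$params$seed)
    reattach_forced(pruned, ledger)
  })
  timings$solve <- st$elapsed
  tree <- st$value

  st <- stage("metrics", quiet, {
    rep <- st_betweenness(tree, inputs$annotation$sources,
                          inputs$annotation$terminals)
    select_important(rep, config$threshold)
  })
  timings$metrics <- st$elapsed
  report <- st$value

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write_instance_stp(instance, out("instance.stp"))
  utils::write.table(
    data.frame(stage = c("input", "reduced"),
               vertices = c(length(instance$nodes), length(reduced$nodes)),
               edges = c(nrow(instance$edges), nrow(reduced$edges)),
               terminals = c(length(instance$terminals),
                             length(reduced$terminals))),
    out("reduction_stats.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_tree(tree, out("tree.tsv"))
  write_betweenness_report(report, out("nodes_betweenness.tsv"),
                           out("edges_betweenness.tsv"))
  manifest <- list(
    package = "nwsteiner",
    version = as.character(utils::packageVersion("nwsteiner")),
    r_version = R.version.string,
    inputs = list(interactions = config$interactions,
                  annotation = config$annotation),
    params = unclass(config$params),
    threshold = report$threshold,
    preprocess = config$preprocess,
    reduction_mode = config$reduction_mode,
    sizes = list(input = c(length(instance$nodes), nrow(instance$edges)),
                 reduced = c(length(reduced$nodes), nrow(reduced$edges)),
                 tree = c(length(tree$vertices), nrow(tree$edges))),
    selected = list(proteins = length(report$selected_nodes),
                    interactions = nrow(report$selected_edges)),
    timings = timings)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (!quiet)
    message(sprintf("[done] tree: %d vertices; selected: %d proteins, %d interactions",
                    length(tree$vertices), length(report$selected_nodes),
                    nrow(report$selected_edges)))
  invisible(list(instance = instance, reduced = reduced, ledger = ledger,
                 tree = tree, report = report, manifest = manifest))
}

#' Sweep the cost and weight parameters
#'
#' Reruns the identification for every (beta, gamma) combination and
#' tabulates the percentage of identified proteins that fall inside a
#' reference protein set (for example the annotated pathway members).
#'
#' @param config A [run_config()] providing the inputs and the remaining
#'   parameters (alpha stays fixed).
#' @param beta_values,gamma_values Numeric vectors to sweep.
#' @param reference_set Character vector of reference protein identifiers.
#' @return A data frame with columns `beta`, `gamma`, `n_identified` and
#'   `pct_in_reference`.
#' @export
sweep_parameters <- function(config, beta_values, gamma_values,
                             reference_set) {
  stopifnot(inherits(config, "run_config"))
  records <- read_interactions(config$interactions)
  annotation <- read_annotation(config$annotation)
  reference_set <- unique(as.character(reference_set))
  grid <- expand.grid(beta = beta_values, gamma = gamma_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    p <- config$params
    p$beta <- grid$beta[k]
    p$gamma <- grid$gamma[k]
    inst <- build_instance(records, annotation, params = p)
    tr <- nwst_solve(inst, preprocess = config$preprocess,
                     reduction_mode = config$reduction_mode)
    ident <- tr$vertices
    pct <- if (length(ident) == 0L) NA_real_
           else 100 * sum(ident %in% reference_set) / length(ident)
    data.frame(beta = grid$beta[k], gamma = grid$gamma[k],
               n_identified = length(ident), pct_in_reference = pct)
  })
  do.call(rbind, res)
}
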