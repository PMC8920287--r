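#' Run the full vector-Wasserstein clustering pipeline
#'
#' End-to-end flow: read inputs, harmonise them, and cluster.
#' The harmonisation order is fixed: intersect gene ids across layers, then
#' with the network's nodes, restrict to the largest connected component,
#' and finally intersect sample ids across layers. Each layer is then
#' preprocessed to strictly positive weights, per-sample per-layer
#' stationary measures are computed, the all-pairs vector-valued W1 distance
#' matrix is assembled and cut by hierarchical clustering.
#'
#' The pipeline is deterministic: rerunning the same config reproduces the
#' distance matrix (to write/read rounding) and labels exactly.
#'
#' @param config a `run_config` (or path to a YAML config file).
#' @param workers worker processes for the distance computation.
#' @return List with `distances` (matrix), `assignment`
#'   (`cluster_assignment`), `measures` (per-sample `vector_distribution`s)
#'   and `manifest` (run metadata; also written as JSON when `out_dir` is
#'   set, together with distance TSV, labels TSV and Newick dendrogram).
#' @export
run_pipeline <- function(config, workers = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  graph <- stage("network", {
    if (inherits(config$network, "spatial_graph")) config$network
    else read_edge_list(config$network)
  })
  raw <- stage("omics", lapply(config$omics, function(o) {
    if (!is.null(o$values)) as.matrix(o$values) else read_omics_matrix(o$path)
  }))
  kinds <- vapply(config$omics, `[[`, "", "kind")

  # gene harmonisation: across layers -> network -> largest component
  genes <- Reduce(intersect, lapply(raw, rownames))
  if (length(genes) == 0L) stop("[harmonise] no genes shared by all layers")
  graph <- stage("harmonise", restrict_to_largest_component(graph, genes))
  genes <- graph$nodes

  samples <- Reduce(intersect, lapply(raw, colnames))
  if (length(samples) == 0L) {
    stop("[harmonise] empty sample intersection across layers (",
         paste(vapply(raw, function(m) ncol(m), 0L), collapse = "/"),
         " samples per layer)")
  }
  layers <- stage("preprocess", {
    out <- lapply(names(raw), function(nm) {
      preprocess_layer(raw[[nm]][genes, samples, drop = FALSE],
                       kind = kinds[[nm]], epsilon = config$epsilon)
    })
    names(out) <- names(raw)
    out
  })

  lg <- stage("layer-graph", {
    nm <- names(layers)
    if (length(nm) == 1L) layer_graph(nm)
    else if (!is.null(config$layer_edges)) {
      layer_graph(nm, connections = config$layer_edges)
    } else {
      preset <- config$layer_preset %||%
        (if (length(nm) == 2L) "pair" else "expression-star")
      layer_graph(nm, preset = preset)
    }
  })

  measures <- stage("invariant-measures", invariant_measures(graph, layers, lg))
  D <- stage("distances",
             pairwise_distance_matrix(measures, graph, lg,
                                      gamma = config$gamma,
                                      workers = workers))
  assignment <- stage("clustering",
                      hierarchical_cluster(D, k = config$k,
                                           linkage = config$linkage))

  manifest <- list(
    package = "vwclust",
    version = as.character(packageVersion("vwclust")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    gamma = config$gamma,
    linkage = config$linkage,
    k = config$k,
    epsilon = config$epsilon,
    layers = unname(kinds),
    layer_edges = if (n_edges(lg)) paste(lg$tails, lg$heads, sep = "--")
                  else character(0),
    n_genes_input = length(Reduce(intersect, lapply(raw, rownames))),
    n_genes_component = n_nodes(graph),
    n_edges_component = n_edges(graph),
    n_samples = length(samples)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_distance_matrix(D, file.path(config$out_dir, "distances.tsv"))
    write_labels(assignment, file.path(config$out_dir, "labels.tsv"))
    writeLines(export_dendrogram(assignment),
               file.path(config$out_dir, "dendrogram.nwk"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(distances = D, assignment = assignment, measures = measures,
       manifest = manifest)
}
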