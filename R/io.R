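#' Read a gene-interaction edge list (TSV or SIF)
#'
#' Two tab-separated layouts are accepted, detected by column count:
#' headerless two-column `gene_a <TAB> gene_b`, and SIF
#' (`gene_a <TAB> interaction <TAB> gene_b`, interaction type ignored).
#'
#' @param path file path.
#' @return A `spatial_graph` with unit edge lengths.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    comment.char = "")
  edges <- switch(as.character(ncol(tab)),
    "2" = as.matrix(tab),
    "3" = as.matrix(tab[, c(1L, 3L)]),
    stop("expected 2 (edge list) or 3 (SIF) columns, found ", ncol(tab))
  )
  spatial_graph(edges)
}

#' Write a graph as a two-column TSV edge list
#' @param graph a `spatial_graph`.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  write.table(data.frame(graph$tails, graph$heads), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an omics matrix (genes x samples TSV)
#'
#' First column holds gene ids, the header row sample ids.
#'
#' @param path file path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_omics_matrix <- function(path) {
  if (!file.exists(path)) stop("omics file not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE, quote = "", comment.char = "")
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("omics matrix in ", path, " is not numeric")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (anyNA(m)) stop("missing values in ", path, "; imputation is not done here")
  m
}

#' @rdname read_omics_matrix
#' @param x numeric matrix with dimnames.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x),
                   signif(x, 9), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a symmetric sample distance matrix TSV
#'
#' Sample ids appear both as header row and first column; the full symmetric
#' matrix is written at 9 significant digits.
#'
#' @param path file path.
#' @return Symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE, quote = ""))
  if (!identical(rownames(m), colnames(m))) {
    stop("distance matrix rows and columns disagree in ", path)
  }
  m
}

#' @rdname read_distance_matrix
#' @param D symmetric matrix with sample dimnames.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample = rownames(D), signif(D, 9), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster labels as `sample_id <TAB> cluster`
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @export
write_labels <- function(assignment, path) {
  write.table(data.frame(sample_id = assignment$sample_ids,
                         cluster = unname(assignment$labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognised keys: `network` (edge-list path), `omics` (list of
#' `{kind, path}` entries, optionally named by layer), `layer_preset` or
#' `layer_edges`, `gamma`, `linkage`, `k`, `epsilon`, `seed`, `out_dir`.
#'
#' @param path YAML file.
#' @return A validated `run_config` list (see [run_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  omics <- lapply(y$omics, function(o) list(kind = o$kind, path = o$path))
  if (!is.null(names(y$omics))) names(omics) <- names(y$omics)
  run_config(
    network = y$network,
    omics = omics,
    layer_preset = y$layer_preset,
    layer_edges = y$layer_edges,
    gamma = y$gamma %||% 1,
    linkage = y$linkage %||% "average",
    k = y$k %||% 4,
    epsilon = y$epsilon %||% 1e-6,
    seed = y$seed %||% 1L,
    out_dir = y$out_dir,
    base_dir = dirname(normalizePath(path))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble and validate a pipeline run configuration
#'
#' @param network path to an edge list, or a `spatial_graph`.
#' @param omics list of layers; each element either
#'   `list(kind = , path = )` or `list(kind = , values = <matrix>)`.
#'   Element names become layer names (default: the kinds).
#' @param layer_preset,layer_edges layer topology, see [layer_graph()];
#'   for one layer both may be omitted.
#' @param gamma cross-layer cost, `>= 0`.
#' @param linkage clustering linkage.
#' @param k number of clusters, `>= 2`.
#' @param epsilon positivity floor for preprocessing.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the config drives simulation).
#' @param out_dir optional output directory; created if missing.
#' @param base_dir directory relative paths are resolved against.
#' @return A `run_config` list.
#' @export
run_config <- function(network, omics, layer_preset = NULL,
                       layer_edges = NULL, gamma = 1, linkage = "average",
                       k = 4, epsilon = 1e-6, seed = 1L, out_dir = NULL,
                       base_dir = ".") {
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (is.character(network)) {
    network <- resolve(network)
    if (!file.exists(network)) stop("network file not found: ", network)
  }
  if (length(omics) == 0L) stop("at least one omics layer is required")
  if (is.null(names(omics)) || any(names(omics) == "")) {
    names(omics) <- vapply(omics, `[[`, "", "kind")
  }
  if (anyDuplicated(names(omics))) stop("layer names must be unique")
  for (nm in names(omics)) {
    o <- omics[[nm]]
    if (is.null(o$kind) ||
        !o$kind %in% c("expression", "cnv", "methylation")) {
      stop("layer '", nm, "': kind must be expression, cnv or methylation")
    }
    if (!is.null(o$path)) {
      omics[[nm]]$path <- resolve(o$path)
      if (!file.exists(omics[[nm]]$path)) {
        stop("omics file not found for layer '", nm, "': ", o$path)
      }
    } else if (is.null(o$values)) {
      stop("layer '", nm, "' needs a path or a values matrix")
    }
  }
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0")
  if (!is.numeric(k) || k < 2) stop("k must be >= 2")
  structure(
    list(network = network, omics = omics, layer_preset = layer_preset,
         layer_edges = layer_edges, gamma = gamma, linkage = linkage,
         k = as.integer(k), epsilon = epsilon, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}
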