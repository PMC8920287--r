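#' Configuration for the synthetic multi-omics generator
#'
#' Bundles the parameters of the simulated study: a random connected gene
#' network and, per omics layer, a genes x samples matrix with planted
#' cluster structure. Defaults describe a moderate-size two-layer study with
#' four balanced tumour groups whose cluster-specific gene modules carry a
#' concordant multiplicative effect across layers.
#'
#' @param n_genes number of genes (network nodes), >= 2.
#' @param network_model `"erdos-renyi-connected"`, `"watts-strogatz"` or
#'   `"tree-plus-chords"`.
#' @param n_samples number of samples.
#' @param n_clusters number of planted clusters (`<= n_samples`); sample
#'   labels are balanced up to remainder.
#' @param layers character vector of omics kinds, each one of
#'   `"expression"`, `"cnv"`, `"methylation"` (names may repeat only if made
#'   unique, e.g. `expression` / `cnv`).
#' @param effect_size multiplicative shift applied to a cluster's module
#'   genes in that cluster's samples (1 = null model, no structure).
#' @param noise_sd log-scale standard deviation of the lognormal baseline.
#' @param module_fraction fraction of genes in each cluster's module;
#'   modules are disjoint across clusters, so
#'   `n_clusters * ceiling(module_fraction * n_genes)` must not exceed
#'   `n_genes`.
#' @param concordant if `TRUE` (default) the same module shifts all layers
#'   of a cluster; if `FALSE` each layer gets its own disjoint module,
#'   probing what the vector distance adds over any single layer.
#' @param n_chords extra edges beyond the spanning tree for
#'   `"tree-plus-chords"` (default `n_genes %/% 10`).
#' @param avg_degree target average degree for `"erdos-renyi-connected"`.
#' @param seed integer seed; the same config always yields the same network
#'   and matrices.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200L,
                              network_model = c("erdos-renyi-connected",
                                                "watts-strogatz",
                                                "tree-plus-chords"),
                              n_samples = 60L,
                              n_clusters = 4L,
                              layers = c("expression", "cnv"),
                              effect_size = 3,
                              noise_sd = 0.2,
                              module_fraction = 0.1,
                              concordant = TRUE,
                              n_chords = NULL,
                              avg_degree = 6,
                              seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot(n_genes >= 2L, n_samples >= 1L,
            n_clusters >= 1L, n_clusters <= n_samples,
            effect_size > 0, noise_sd > 0,
            module_fraction > 0, module_fraction <= 1)
  layers <- as.character(layers)
  if (anyDuplicated(layers)) stop("layer kinds must be unique")
  if (!all(layers %in% c("expression", "cnv", "methylation"))) {
    stop("layers must be among expression, cnv, methylation")
  }
  if (is.null(n_chords)) n_chords <- n_genes %/% 10L
  structure(
    list(n_genes = as.integer(n_genes), network_model = network_model,
         n_samples = as.integer(n_samples),
         n_clusters = as.integer(n_clusters), layers = layers,
         effect_size = effect_size, noise_sd = noise_sd,
         module_fraction = module_fraction, concordant = isTRUE(concordant),
         n_chords = as.integer(n_chords), avg_degree = avg_degree,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a random connected gene network
#'
#' Draws a graph under the configured model and retries (up to 100 times,
#' advancing the RNG) until it is connected; Erdos-Renyi uses edge
#' probability `avg_degree / (n - 1)`. Node ids are zero-padded `g0001`,
#' `g0002`, ... so lexicographic node order equals numeric order.
#'
#' @param config a `simulation_config`.
#' @return A connected `spatial_graph` with unit edge lengths, identical for
#'   identical seeds.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  gene_ids <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  withr::with_seed(config$seed, {
    for (try in 1:100) {
      ig <- switch(config$network_model,
        "erdos-renyi-connected" =
          igraph::sample_gnp(n, min(1, config$avg_degree / max(1, n - 1))),
        "watts-strogatz" =
          igraph::sample_smallworld(1, n, nei = 2, p = 0.1),
        "tree-plus-chords" = {
          tr <- igraph::sample_tree(n)
          if (config$n_chords > 0) {
            have <- apply(igraph::as_edgelist(tr), 1, function(e)
              paste(sort(as.integer(e)), collapse = "-"))
            cand <- utils::combn(n, 2)
            keys <- paste(cand[1, ], cand[2, ], sep = "-")
            free <- which(!(keys %in% have))
            pickn <- min(config$n_chords, length(free))
            pick <- sample(free, pickn)
            igraph::add_edges(tr, as.vector(cand[, pick]))
          } else tr
        }
      )
      ig <- igraph::simplify(ig)
      if (igraph::is_connected(ig) && igraph::ecount(ig) > 0) {
        el <- igraph::as_edgelist(ig)
        return(spatial_graph(cbind(gene_ids[as.integer(el[, 1])],
                                   gene_ids[as.integer(el[, 2])])))
      }
    }
    stop("could not generate a connected ", config$network_model,
         " graph in 100 attempts; raise avg_degree or n_chords")
  })
}

#' Generate multi-layer omics matrices with planted clusters
#'
#' Baseline values are lognormal(0, `noise_sd`). Each cluster owns a module
#' of `ceiling(module_fraction * n_genes)` genes, disjoint across clusters;
#' in that cluster's samples the module genes are multiplied by
#' `effect_size`, concordantly in every layer (or in layer-specific modules
#' when `concordant = FALSE`). Layers are then mapped to their native
#' scales, so the preprocessing transforms are genuinely exercised:
#' expression stays positive as generated, CNV is emitted as the natural log
#' of the positive value (a signed score that `preprocess_layer` re-
#' exponentiates), and methylation as `beta = 1/(1 + v)` in (0, 1), which
#' `1 - beta` maps back to an increasing function of the latent value.
#'
#' @param config a `simulation_config`.
#' @param graph the network the data live on, typically from
#'   [generate_network()] (only its node count/ids are used).
#' @return List with `layers` (named list of genes x samples matrices on
#'   native scales), `labels` (named integer vector of planted clusters) and
#'   `modules` (list of module gene ids per cluster and layer).
#' @export
generate_multiomics <- function(config, graph) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(graph, "spatial_graph"))
  genes <- graph$nodes
  n <- length(genes)
  k <- config$n_clusters
  msize <- ceiling(config$module_fraction * n)
  groups_needed <- if (config$concordant) k else k * length(config$layers)
  if (groups_needed * msize > n) {
    stop("disjoint modules need ", groups_needed * msize,
         " genes but only ", n, " are available")
  }
  samples <- sprintf("s%03d", seq_len(config$n_samples))
  labels <- setNames(rep(seq_len(k), length.out = config$n_samples), samples)

  withr::with_seed(config$seed + 104729L, {
    perm <- sample(genes)
    module_of <- function(slot) perm[((slot - 1) * msize + 1):(slot * msize)]
    layers <- list()
    modules <- list()
    for (li in seq_along(config$layers)) {
      kind <- config$layers[li]
      latent <- matrix(rlnorm(n * config$n_samples, 0, config$noise_sd),
                       n, config$n_samples, dimnames = list(genes, samples))
      mods <- vector("list", k)
      for (cc in seq_len(k)) {
        slot <- if (config$concordant) cc else (li - 1) * k + cc
        mod <- module_of(slot)
        mods[[cc]] <- mod
        latent[mod, labels == cc] <- latent[mod, labels == cc] *
          config$effect_size
      }
      native <- switch(kind,
        expression = latent,
        cnv = log(latent),
        methylation = 1 / (1 + latent)
      )
      layers[[kind]] <- native
      modules[[kind]] <- mods
    }
    list(layers = layers, labels = labels, modules = modules)
  })
}

#' Simulate a full dataset (network + omics) from one config
#'
#' @param config a `simulation_config`.
#' @return List with `graph`, `layers`, `labels`, `modules`, `config`.
#' @export
simulate_dataset <- function(config) {
  graph <- generate_network(config)
  omics <- generate_multiomics(config, graph)
  c(list(graph = graph, config = config), omics)
}
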