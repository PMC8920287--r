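#' Scalar W1 (Earth Mover's) distance between two measures on a graph
#'
#' Solves the flow formulation of the W1 distance on an undirected graph with
#' edge lengths as costs:
#' \deqn{\min_u \sum_e \ell_e |u_e| \quad \text{s.t.}\quad \rho_0 - \rho_1 = D u,}
#' where `D` is the signed incidence matrix. The absolute values make this a
#' linear program; it is solved exactly as an uncapacitated minimum-cost flow
#' by successive shortest paths, which is equivalent to the LP with each flux
#' split into nonnegative parts.
#'
#' @param rho0,rho1 nonnegative measures with equal total mass (within
#'   `1e-9`), named by node or given in the graph's node order. They need not
#'   be probability vectors, only balanced; imbalance is an error, never
#'   silently renormalised.
#' @param graph a connected `spatial_graph` (zero-length edges allowed for
#'   super-graphs).
#' @param details if `TRUE`, also return the per-edge signed flux and the
#'   divergence residual.
#' @return The distance (nonnegative scalar), or when `details = TRUE` a list
#'   with `objective`, `flux` (signed, relative to the stored tail->head
#'   orientation) and `residual` (max-norm of `rho0 - rho1 - D u`).
#' @examples
#' g <- spatial_graph(rbind(c("A", "B"), c("B", "C")))
#' w1_graph(c(A = 1, B = 0, C = 0), c(A = 0, B = 0, C = 1), g) # == 2
#' @export
w1_graph <- function(rho0, rho1, graph, details = FALSE) {
  stopifnot(inherits(graph, "spatial_graph"))
  rho0 <- align_node_values(graph, rho0)
  rho1 <- align_node_values(graph, rho1)
  if (any(rho0 < 0) || any(rho1 < 0)) stop("measures must be nonnegative")
  dmass <- sum(rho0) - sum(rho1)
  if (abs(dmass) > 1e-9) {
    stop("total masses differ by ", format(dmass),
         "; refusing to renormalize")
  }
  sol <- .mcf_solve(
    n_nodes(graph),
    match(graph$tails, graph$nodes) - 1L,
    match(graph$heads, graph$nodes) - 1L,
    graph$lengths,
    rho0 - rho1
  )
  if (sol$unmet > 1e-9) {
    stop("transport infeasible: ", format(sol$unmet),
         " mass could not be routed (disconnected graph?)")
  }
  if (!details) return(sol$objective)
  div <- numeric(n_nodes(graph))
  ti <- match(graph$tails, graph$nodes)
  hi <- match(graph$heads, graph$nodes)
  # D u: +flux at tail, -flux at head
  for (e in seq_along(sol$flux)) {
    div[ti[e]] <- div[ti[e]] + sol$flux[e]
    div[hi[e]] <- div[hi[e]] - sol$flux[e]
  }
  list(
    objective = sol$objective,
    flux = setNames(sol$flux, paste0(graph$tails, "--", graph$heads)),
    residual = max(abs((rho0 - rho1) - div))
  )
}

#' Vector-valued W1 distance between two multi-layer distributions
#'
#' Solves the vector-valued transport problem
#' \deqn{\min_{u,w} \sum_{e,j} \ell_e |u_{ej}| + \gamma \sum_{i,f} |w_{if}|
#'   \quad \text{s.t.}\quad \vec\rho_0 - \vec\rho_1 = D_1 u + D_2 w,}
#' where `u` carries mass along gene-network edges within each layer and `w`
#' carries mass between layers at a fixed gene, at cost `gamma` per unit.
#' The problem is exactly the scalar W1 on the weighted super-graph
#' [build_super_graph()], which is how it is solved.
#'
#' With a disconnected layer graph the problem is feasible only when the two
#' distributions carry equal mass on every layer-graph component; this is
#' checked up front and an informative error raised otherwise.
#'
#' @param rho0,rho1 `vector_distribution`s on the same `G` and `F`.
#' @param G a connected `spatial_graph`.
#' @param F a `layer_graph`.
#' @param gamma nonnegative cross-layer cost (default 1).
#' @param details if `TRUE`, return the full flow solution: `u` (spatial flux,
#'   edges x layers), `w` (cross-layer flux, genes x layer-edges),
#'   `objective`, `residual`.
#' @return Nonnegative scalar distance, or the detailed list.
#' @export
w1_vector <- function(rho0, rho1, G, F, gamma = 1, details = FALSE) {
  stopifnot(inherits(G, "spatial_graph"), inherits(F, "layer_graph"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("gamma must be a single nonnegative number")
  }
  check_vd <- function(vd, who) {
    if (!is.matrix(vd)) stop(who, " must be a vector_distribution matrix")
    if (!setequal(rownames(vd), G$nodes)) {
      stop(who, " is not aligned with the spatial graph's nodes")
    }
    if (!identical(colnames(vd), F$layers)) {
      stop(who, " is not aligned with the layer graph's layers")
    }
    if (any(vd < 0)) stop(who, " has negative mass")
    if (abs(sum(vd) - 1) > 1e-9) {
      stop(who, " has total mass ", format(sum(vd)), ", expected 1")
    }
    vd[G$nodes, , drop = FALSE]
  }
  rho0 <- check_vd(rho0, "rho0")
  rho1 <- check_vd(rho1, "rho1")

  comps <- layer_components(F)
  if (length(comps) > 1L) {
    for (cc in comps) {
      d <- sum(rho0[, cc, drop = FALSE]) - sum(rho1[, cc, drop = FALSE])
      if (abs(d) > 1e-9) {
        stop("infeasible: layer component {", paste(cc, collapse = ", "),
             "} carries unequal mass (difference ", format(d),
             ") and no cross-layer path connects it to the rest")
      }
    }
  }

  super <- build_super_graph(G, F, gamma)
  sol <- w1_graph(as_super_marginal(rho0, super),
                  as_super_marginal(rho1, super),
                  super, details = TRUE)
  if (!details) return(sol$objective)

  # unpack super-graph fluxes into u (|E_G| x |V_F|) and w (|V_G| x |E_F|).
  # Flux signs on the super-graph follow its own lexicographic orientation,
  # so re-sign against the (G, F) orientations.
  m <- length(F$layers)
  u <- matrix(0, n_edges(G), m,
              dimnames = list(paste0(G$tails, "--", G$heads), F$layers))
  w <- matrix(0, n_nodes(G), length(F$tails),
              dimnames = list(G$nodes,
                              if (length(F$tails))
                                paste0(F$tails, "--", F$heads)))
  skey <- setNames(seq_along(super$tails),
                   paste(super$tails, super$heads, sep = "\r"))
  pick <- function(a, b) {
    # signed flux a -> b on the super-graph
    k <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    idx <- skey[k]
    sgn <- ifelse(a <= b, 1, -1)
    sgn * sol$flux[idx]
  }
  for (j in seq_len(m)) {
    u[, j] <- pick(paste0(G$tails, "@", F$layers[j]),
                   paste0(G$heads, "@", F$layers[j]))
  }
  for (f in seq_along(F$tails)) {
    w[, f] <- pick(paste0(G$nodes, "@", F$tails[f]),
                   paste0(G$nodes, "@", F$heads[f]))
  }
  list(objective = sol$objective, u = u, w = w, residual = sol$residual)
}

#' All-pairs vector-valued W1 distance matrix
#'
#' Computes the strict upper triangle (n(n-1)/2 transport solves) and mirrors
#' it. The result does not depend on the number of workers or on evaluation
#' order; parallelism only farms out independent solves.
#'
#' @param samples named list of `vector_distribution`s on the same `G`, `F`.
#' @param G,F,gamma as in [w1_vector()].
#' @param workers number of worker processes (forked; default 1, serial).
#' @return Symmetric nonnegative matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
pairwise_distance_matrix <- function(samples, G, F, gamma = 1, workers = 1L) {
  n <- length(samples)
  if (n < 2L) stop("need at least two samples")
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  # the super-graph and the node-order mapping are shared by every pair;
  # build them once and call the flow solver directly per pair
  super <- build_super_graph(G, F, gamma)
  marg <- vapply(samples, as_super_marginal, numeric(n_nodes(super)),
                 super = super)
  if (any(marg < 0)) stop("samples must have nonnegative mass")
  bad <- which(abs(colSums(marg) - 1) > 1e-9)
  if (length(bad)) {
    stop("sample '", ids[bad[1L]], "' has total mass ",
         format(sum(marg[, bad[1L]])), ", expected 1")
  }
  comps <- layer_components(F)
  tails0 <- match(super$tails, super$nodes) - 1L
  heads0 <- match(super$heads, super$nodes) - 1L
  layer_of <- sub("^.*@", "", super$nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  solve_one <- function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    fail <- function(msg) {
      stop("distance solve failed for pair (", ids[i], ", ", ids[j],
           "): ", msg, call. = FALSE)
    }
    if (length(comps) > 1L) {
      for (cc in comps) {
        d <- sum(marg[layer_of %in% cc, i]) - sum(marg[layer_of %in% cc, j])
        if (abs(d) > 1e-9) {
          fail(paste0("layer component {", paste(cc, collapse = ", "),
                      "} carries unequal mass"))
        }
      }
    }
    sol <- .mcf_solve(n_nodes(super), tails0, heads0, super$lengths,
                      marg[, i] - marg[, j])
    if (sol$unmet > 1e-9) fail("transport infeasible")
    sol$objective
  }
  vals <- if (workers > 1L) {
    unlist(parallel::mclapply(seq_len(nrow(pairs)), solve_one,
                              mc.cores = workers))
  } else {
    vapply(seq_len(nrow(pairs)), solve_one, numeric(1))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[pairs] <- vals
  D <- D + t(D)
  D
}
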