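# Bridge to the dense-LP oracle (lp-oracle.py, scipy/HiGHS): an
# implementation-independent solve of the same transport LP, used to verify
# the min-cost-flow path.  Instances are batched into one python call.

# build one oracle instance from package objects
lp_instance <- function(G, F, gamma, rho0, rho1) {
  list(
    nG = n_nodes(G),
    edges = cbind(match(G$tails, G$nodes), match(G$heads, G$nodes)) - 1L,
    lengths = G$lengths,
    m = length(F$layers),
    ledges = if (length(F$tails)) {
      cbind(match(F$tails, F$layers), match(F$heads, F$layers)) - 1L
    } else {
      matrix(integer(0), 0, 2)
    },
    gamma = gamma,
    # layer-major flattening: index = layer*nG + gene
    rho0 = as.vector(rho0[G$nodes, F$layers, drop = FALSE]),
    rho1 = as.vector(rho1[G$nodes, F$layers, drop = FALSE])
  )
}

dense_lp_oracle <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(instances, infile, auto_unbox = TRUE, digits = NA)
  status <- system2("python",
                    c(testthat::test_path("lp-oracle.py"), infile, outfile),
                    stdout = NULL, stderr = NULL)
  if (status != 0L || !file.exists(outfile)) {
    stop("dense LP oracle run failed (status ", status, ")")
  }
  vals <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  as.numeric(vals)
}
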