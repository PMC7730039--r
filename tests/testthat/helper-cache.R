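# Expensive shared objects (35-day toy healing run) are computed once per
# test session and reused across test files.
if (!exists(".oh_cache", envir = globalenv())) {
  assign(".oh_cache", new.env(parent = emptyenv()), envir = globalenv())
}

oh_cached <- function(name, expr) {
  cache <- get(".oh_cache", envir = globalenv())
  if (!exists(name, envir = cache)) {
    assign(name, force(expr), envir = cache)
  }
  get(name, envir = cache)
}

toy_healing_run <- function() {
  oh_cached("toy_run", {
    fx <- make_fixture("single_chamber")
    run_healing(fx$mesh, days = 35)
  })
}

toy_mesh <- function() {
  oh_cached("toy_mesh", make_fixture("single_chamber")$mesh)
}

callus_centroids <- function(mesh) {
  cal <- which(mesh$elements$region == "callus")
  conn <- as.matrix(mesh$elements[cal, c("n1", "n2", "n3", "n4")])
  list(idx = cal,
       r = rowMeans(matrix(mesh$nodes$r[conn], ncol = 4)),
       z = rowMeans(matrix(mesh$nodes$z[conn], ncol = 4)))
}
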