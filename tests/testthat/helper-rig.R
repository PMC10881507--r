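# shared fixtures: a small calibrated rig and scene helpers built in code

test_cage <- function() cage_model()

test_rig <- function(cage = test_cage()) default_rig(cage)

# uniform random interior points away from the walls
random_interior <- function(n, cage = test_cage(), margin = 50) {
  cbind(runif(n, margin, cage$width - margin),
        runif(n, margin, cage$depth - margin),
        runif(n, margin, cage$height - margin))
}

# brute-force connected components of the <= tol distance graph (BFS),
# independent oracle for Euclidean cluster extraction
bfs_components <- function(pts, tol) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts)) <= tol
  lab <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(d[v, ] & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# canonical form of a component labelling for comparison
canon_labels <- function(lab) {
  split(seq_along(lab), lab) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, `[`, integer(1), 1))])()
}
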