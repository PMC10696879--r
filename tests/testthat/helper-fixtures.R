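options(atacscreen.verbose = FALSE)

# small binary matrix with two planted clusters differing on disjoint
# feature blocks; used by LSI / doublet tests
two_cluster_matrix <- function(n_per = 50, p = 60, p_on = 0.9, p_off = 0.05,
                               seed = 1) {
  set.seed(seed)
  half <- p %/% 2
  pr <- rbind(
    matrix(rep(c(p_on, p_off), c(half, p - half)), n_per, p, byrow = TRUE),
    matrix(rep(c(p_off, p_on), c(half, p - half)), n_per, p, byrow = TRUE))
  m <- matrix(as.integer(runif(2 * n_per * p) < pr), 2 * n_per, p)
  # guarantee no all-zero rows or all-one columns
  m[cbind(seq_len(n_per), 1L)] <- 1L
  m[cbind(n_per + seq_len(n_per), half + 1L)] <- 1L
  m[1, p] <- 0L
  dimnames(m) <- list(sprintf("cell%03d", seq_len(2 * n_per)),
                      sprintf("feat%03d", seq_len(p)))
  Matrix::Matrix(m, sparse = TRUE)
}

# hand-built principal graph: path of nodes at given 1-D positions
path_graph <- function(node_pos, assignment) {
  nodes <- matrix(node_pos, ncol = 1)
  n <- length(node_pos)
  g <- igraph::make_graph(rep(seq_len(n - 1), each = 2) + c(0, 1),
                          n = n, directed = FALSE)
  igraph::E(g)$weight <- abs(diff(node_pos))
  structure(list(nodes = nodes, graph = g,
                 edges = data.frame(from = seq_len(n - 1),
                                    to = 2:n,
                                    length = abs(diff(node_pos))),
                 assignment = assignment),
            class = "principal_graph")
}
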