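# Shared fixtures and independent oracles, built in code at test time.

# Erdos-Renyi adjacency matrix with node names
random_adjacency <- function(n, p = 0.15) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  A
}

# wrap an adjacency matrix as a correlation_network (all edges positive r)
network_from_adjacency <- function(A, r = 0.8) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  rho <- diag(nrow(A))
  dimnames(rho) <- dimnames(A)
  rho[idx] <- r
  rho[idx[, 2:1, drop = FALSE]] <- r
  build_network(rho, q_matrix = NULL, edge_r = r / 2)
}

# independent natural-connectivity oracle: plain eigen-decomposition formula
nc_oracle <- function(A) {
  if (all(A == 0)) return(0)
  ev <- eigen(A, symmetric = TRUE)$values
  log(mean(exp(ev)))
}

# brute-force topology oracle: explicit triangle counting and BFS paths
topology_oracle <- function(A) {
  deg <- rowSums(A)
  keep <- deg > 0
  Ak <- A[keep, keep, drop = FALSE]
  V <- nrow(Ak)
  E <- sum(Ak) / 2
  tri <- 0
  if (V >= 3) {
    for (i in 1:(V - 2)) for (j in (i + 1):(V - 1)) for (k in (j + 1):V) {
      if (Ak[i, j] && Ak[j, k] && Ak[i, k]) tri <- tri + 1
    }
  }
  dk <- rowSums(Ak)
  triples <- sum(dk * (dk - 1)) / 2
  bfs_dist <- function(s) {
    d <- rep(Inf, V); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(Ak[v, ] > 0 & is.infinite(d))
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  dists <- if (V > 0) t(vapply(1:V, bfs_dist, numeric(V))) else matrix(0, 0, 0)
  finite_off <- dists[is.finite(dists) & dists > 0]
  list(
    n_edges = E,
    n_vertices = V,
    average_degree = if (V) 2 * E / V else 0,
    average_path_length = if (length(finite_off)) mean(finite_off) else 0,
    clustering_coefficient = if (triples > 0) 3 * tri / triples else 0,
    degree_centralization = if (V > 2) sum(max(dk) - dk) / ((V - 1) * (V - 2)) else 0
  )
}

# logistic-normal composition matrix with optional correlated block
logistic_normal_fracs <- function(n, D, block = NULL, rho = 0, mu = NULL) {
  R <- diag(D)
  if (!is.null(block)) {
    R[block, block] <- rho
    diag(R) <- 1
  }
  y <- matrix(stats::rnorm(n * D), n, D) %*% chol(R)
  if (!is.null(mu)) y <- sweep(y, 2, mu, "+")
  x <- exp(y)
  x / rowSums(x)
}

# brute-force Benjamini-Hochberg oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# small three-sample cohort on disk, for IO tests
write_tiny_cohort <- function(dir) {
  ab <- data.frame(sample_id = c("S1", "S2", "S3"),
                   TaxA = c(0.5, 0.2, 0.1), TaxB = c(0.3, 0.5, 0.4),
                   TaxC = c(0.2, 0.3, 0.5))
  md <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                   subject_id = paste0("P", 1:4),
                   group = c("ASD", "nonASD", "ASD", "nonASD"),
                   age = c(5, 7, 9, 6), sex = c("M", "F", "M", "M"),
                   gi_symptoms = c(1, 0, 0, 1))
  dt <- data.frame(sample_id = c("S1", "S2", "S3"),
                   energy_kcal = c(1500, 1800, 2000),
                   fiber_g = c(10, 15, 20))
  paths <- file.path(dir, c("ab.tsv", "md.tsv", "dt.tsv"))
  write_tsv_table(ab, paths[1]); write_tsv_table(md, paths[2])
  write_tsv_table(dt, paths[3])
  paths
}
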