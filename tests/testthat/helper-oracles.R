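# Independent oracles used across the suite.  These deliberately re-derive
# quantities by routes separate from the package implementation.

# --- dense FE assembly-and-solve oracle (own integration code) -------------
oracle_hex_ke <- function(E, nu, h) {
  C <- matrix(0, 6, 6)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C[1:3, 1:3] <- lam
  diag(C) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  gs <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 24, 24)
  for (gx in gs) for (gy in gs) for (gz in gs) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      sx <- 2 * off[a, 1] - 1; sy <- 2 * off[a, 2] - 1; sz <- 2 * off[a, 3] - 1
      dn <- c(sx * (1 + sy * gy) * (1 + sz * gz),
              sy * (1 + sx * gx) * (1 + sz * gz),
              sz * (1 + sx * gx) * (1 + sy * gy)) / 8 * 2 / h
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dn[1]; B[2, c0 + 2] <- dn[2]; B[3, c0 + 3] <- dn[3]
      B[4, c0 + 1] <- dn[2]; B[4, c0 + 2] <- dn[1]
      B[5, c0 + 2] <- dn[3]; B[5, c0 + 3] <- dn[2]
      B[6, c0 + 1] <- dn[3]; B[6, c0 + 3] <- dn[1]
    }
    K <- K + t(B) %*% C %*% B * (h / 2)^3
  }
  K
}

oracle_dense_solve <- function(model, apparent_strain) {
  ndof <- 3 * model$n_nodes
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(model$n_elements)) {
    Ke <- oracle_hex_ke(model$Et[e], model$poisson, model$h)
    dofs <- model$EN[e, ]
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  uz <- -apparent_strain * model$height
  czd <- 3 * (model$cranial_nodes - 1) + 3
  fixed <- c(3 * (model$caudal_nodes - 1) + 1, 3 * (model$caudal_nodes - 1) + 2,
             3 * (model$caudal_nodes - 1) + 3,
             3 * (model$cranial_nodes - 1) + 1,
             3 * (model$cranial_nodes - 1) + 2, czd)
  up <- numeric(ndof)
  up[czd] <- uz
  free <- setdiff(seq_len(ndof), fixed)
  u <- up
  if (length(free))
    u[free] <- solve(K[free, free],
                     -K[free, fixed, drop = FALSE] %*% up[fixed])
  f <- K %*% u
  # oracle strain field via its own element energies
  eps <- numeric(model$n_elements)
  for (e in seq_len(model$n_elements)) {
    Ke <- oracle_hex_ke(model$Et[e], model$poisson, model$h)
    ue <- u[model$EN[e, ]]
    Ue <- 0.5 * sum(ue * (Ke %*% ue))
    eps[e] <- sqrt(max(0, 2 * Ue / (model$Et[e] * model$h^3)))
  }
  list(u = u, R = abs(sum(f[czd])), eps = eps)
}

# failure load by direct transcription of the count-quantile definition on
# the oracle strain field (linear load scaling)
oracle_failure_load <- function(R, eps, strain_limit = 0.007,
                                volume_fraction = 0.02) {
  s <- sort(eps)
  n <- length(s)
  hh <- (n - 1) * (1 - volume_fraction) + 1
  lo <- floor(hh)
  eps_star <- s[lo] + (hh - lo) * (s[min(lo + 1, n)] - s[lo])
  R * strain_limit / eps_star
}

# --- exhaustive cubical-complex Euler characteristic -----------------------
oracle_euler <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  vs <- es <- fs <- list()
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    vs[[length(vs) + 1]] <- paste(i - 1 + a, j - 1 + b, k - 1 + cc, sep = ",")
  for (b in 0:1) for (cc in 0:1)
    es[[length(es) + 1]] <- paste("x", i, j - 1 + b, k - 1 + cc, sep = ",")
  for (a in 0:1) for (cc in 0:1)
    es[[length(es) + 1]] <- paste("y", i - 1 + a, j, k - 1 + cc, sep = ",")
  for (a in 0:1) for (b in 0:1)
    es[[length(es) + 1]] <- paste("z", i - 1 + a, j - 1 + b, k, sep = ",")
  for (a in 0:1) fs[[length(fs) + 1]] <- paste("fx", i - 1 + a, j, k, sep = ",")
  for (b in 0:1) fs[[length(fs) + 1]] <- paste("fy", i, j - 1 + b, k, sep = ",")
  for (cc in 0:1) fs[[length(fs) + 1]] <- paste("fz", i, j, k - 1 + cc, sep = ",")
  length(unique(unlist(vs))) - length(unique(unlist(es))) +
    length(unique(unlist(fs))) - nrow(idx)
}

# --- brute-force first Betti number of the rod-lattice graph ---------------
oracle_lattice_betti1 <- function(n) {
  n <- rep(n, length.out = 3)
  nodes <- expand.grid(x = 0:n[1], y = 0:n[2], z = 0:n[3])
  key <- function(p) p[, 1] + p[, 2] * (n[1] + 2) + p[, 3] * (n[1] + 2)^2
  id <- key(nodes)
  edges <- NULL
  for (ax in 1:3) {
    from <- nodes[nodes[, ax] < n[ax], ]
    to <- from
    to[, ax] <- to[, ax] + 1
    edges <- rbind(edges, cbind(key(from), key(to)))
  }
  # union-find component count
  parent <- stats::setNames(id, id)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[[as.character(a)]] <- b
  }
  comp <- length(unique(vapply(id, find, 0)))
  nrow(edges) - nrow(nodes) + comp
}

# --- independent transcription of the pipe-bending geometry factor ---------
oracle_pipe_bending_fb <- function(theta) {
  x <- theta / pi
  1 + 6.8 * x^(3 / 2) - 13.6 * x^(5 / 2) + 20.0 * x^(7 / 2)
}

# --- small cohort builders -------------------------------------------------
balanced_cohort <- function(cell_means, n, values = NULL) {
  tab <- expand.grid(
    cana = factor(c("NoCana", "Cana"), levels = c("NoCana", "Cana")),
    group = factor(c("ND-Palm", "T1D-Palm", "T1D-Ins"),
                   levels = c("ND-Palm", "T1D-Palm", "T1D-Ins")),
    rep = seq_len(n))
  ci <- as.integer(interaction(tab$cana, tab$group))
  tab$outcome <- if (is.null(values)) cell_means[ci] else values
  tab
}
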