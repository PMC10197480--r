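# Independent brute-force oracles, deliberately written with scalar loops and
# none of the package's (or igraph's) machinery.

# wrap a bare 0/1 adjacency matrix as a ptn object
make_net <- function(adj, traits = NULL, alpha = 0.05) {
  if (is.null(traits)) traits <- paste0("T", sprintf("%02d", seq_len(nrow(adj))))
  dimnames(adj) <- list(traits, traits)
  structure(list(adjacency = adj, traits = traits, alpha = alpha,
                 adjust = "none", cor = NULL), class = "ptn")
}

oracle_degree <- function(adj) {
  k <- nrow(adj)
  deg <- integer(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) if (i != j && adj[i, j] == 1) deg[i] <- deg[i] + 1L
  }
  deg
}

oracle_edge_count <- function(adj) {
  m <- 0L
  k <- nrow(adj)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) if (adj[i, j] == 1) m <- m + 1L
  m
}

oracle_density <- function(adj) {
  k <- nrow(adj)
  oracle_edge_count(adj) / (k * (k - 1) / 2)
}

# Newman-Girvan Q = sum_c (e_cc - a_c^2), from first principles
oracle_modularity <- function(adj, membership) {
  m <- oracle_edge_count(adj)
  if (m == 0) return(0)
  mods <- unique(membership)
  q <- 0
  for (cm in mods) {
    idx <- which(membership == cm)
    e_cc <- 0
    a_c <- 0
    for (i in idx) for (j in idx) if (i != j && adj[i, j] == 1) e_cc <- e_cc + 1
    e_cc <- e_cc / (2 * m)
    for (i in idx) a_c <- a_c + sum(adj[i, -i] == 1)
    a_c <- a_c / (2 * m)
    q <- q + (e_cc - a_c^2)
  }
  q
}

# all set partitions of 1..n (Bell(6) = 203), for exhaustive modularity search
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (g in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

oracle_best_modularity <- function(adj) {
  best <- -Inf
  for (p in all_partitions(nrow(adj))) {
    q <- oracle_modularity(adj, p)
    if (q > best) best <- q
  }
  best
}

# scalar Pearson r and two-sided p over complete pairs
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

# adjacency matrices of all labelled graphs on k nodes, as integer codes
graph_from_code <- function(code, k) {
  adj <- matrix(0L, k, k)
  pairs <- which(upper.tri(adj))
  bits <- as.integer(intToBits(code))[seq_along(pairs)]
  adj[pairs] <- bits
  adj + t(adj)
}

random_adjacency <- function(k, p_edge = NULL) {
  if (is.null(p_edge)) p_edge <- stats::runif(1, 0.05, 0.95)
  adj <- matrix(0L, k, k)
  up <- which(upper.tri(adj))
  adj[up] <- stats::rbinom(length(up), 1, p_edge)
  adj + t(adj)
}

# Independent Duncan step-down reference: a pair of sorted means is declared
# different iff EVERY range containing it exceeds that range's critical value
# (the containment formulation, dual to the shielding loop in the package).
oracle_duncan_shared <- function(samples, alpha = 0.05) {
  means <- vapply(samples, mean, numeric(1))
  ns <- lengths(samples)
  vars <- vapply(samples, stats::var, numeric(1))
  dfe <- sum(ns - 1)
  mse <- sum((ns - 1) * vars) / dfe
  n_h <- length(samples) / sum(1 / ns)
  ord <- order(-means, names(means))
  m <- means[ord]
  k <- length(m)
  crit <- function(span) {
    stats::qtukey((1 - alpha)^(span - 1), nmeans = span, df = dfe) * sqrt(mse / n_h)
  }
  shared <- diag(TRUE, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      different <- TRUE
      for (a in seq_len(i)) {
        for (b in j:k) {
          if ((m[a] - m[b]) <= crit(b - a + 1)) different <- FALSE
        }
      }
      shared[i, j] <- shared[j, i] <- !different
    }
  }
  dimnames(shared) <- list(names(m), names(m))
  shared
}

# letter-sharing relation from a tidy Duncan table
letters_shared <- function(tab) {
  k <- nrow(tab)
  out <- diag(TRUE, k)
  sets <- strsplit(tab$letters, "")
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- length(intersect(sets[[i]], sets[[j]])) > 0
    }
  }
  dimnames(out) <- list(tab$item, tab$item)
  out
}

random_duncan_problem <- function(k = 5, n_min = 5, n_max = 30) {
  items <- paste0("it", seq_len(k))
  stats::setNames(lapply(seq_len(k), function(i) {
    stats::rnorm(sample(n_min:n_max, 1), mean = stats::runif(1, 0, 3),
                 sd = stats::runif(1, 0.3, 2))
  }), items)
}
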