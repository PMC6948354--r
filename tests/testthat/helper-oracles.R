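# Independent oracles used across the suite. Deliberately naive: plain-R
# breadth-first search and exhaustive path counting, no igraph calls, so they
# share nothing with the implementation they check.

# random simple undirected graph as a named edge list + node set
random_graph_fixture <- function(n, p = 0.2) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

fixture_to_igraph <- function(fx) {
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(fx$nodes)
  if (nrow(fx$edges) > 0) g <- igraph::add_edges(g, t(fx$edges))
  g
}

# adjacency list from a fixture
fixture_adj <- function(fx) {
  adj <- setNames(vector("list", length(fx$nodes)), fx$nodes)
  for (v in fx$nodes) adj[[v]] <- character()
  if (nrow(fx$edges) > 0) {
    for (i in seq_len(nrow(fx$edges))) {
      a <- fx$edges[i, 1]; b <- fx$edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# BFS from src: distances (Inf if unreachable) and shortest-path counts
oracle_bfs <- function(adj, src) {
  nodes <- names(adj)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  sigma <- setNames(rep(0, length(nodes)), nodes)
  dist[src] <- 0; sigma[src] <- 1
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# naive all-pairs-BFS centralities: degree, betweenness (unnormalized,
# endpoints excluded), component-scaled closeness
oracle_centralities <- function(fx) {
  adj <- fixture_adj(fx)
  nodes <- fx$nodes
  n <- length(nodes)
  bfs <- lapply(nodes, function(s) oracle_bfs(adj, s))
  names(bfs) <- nodes
  dc <- vapply(adj, function(a) length(unique(a)), numeric(1))
  bc <- setNames(rep(0, n), nodes)
  if (n >= 3) {
    for (si in seq_len(n - 1)) {
      for (ti in (si + 1):n) {
        s <- nodes[si]; t <- nodes[ti]
        dst <- bfs[[s]]$dist[t]
        if (!is.finite(dst)) next
        tot <- bfs[[s]]$sigma[t]
        for (v in nodes) {
          if (v == s || v == t) next
          if (is.finite(bfs[[s]]$dist[v]) && is.finite(bfs[[t]]$dist[v]) &&
              bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst) {
            bc[v] <- bc[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / tot
          }
        }
      }
    }
  }
  cc <- vapply(nodes, function(v) {
    d <- bfs[[v]]$dist
    d <- d[names(d) != v]
    reach <- d[is.finite(d)]
    if (length(reach) == 0 || n == 1) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, numeric(1))
  list(dc = dc, bc = bc, cc = cc)
}

# Exact-rational hypergeometric upper-tail oracle. Enumerates every
# (N <= nmax, K, n, k) with big-integer combinatorics (Pascal's triangle of
# exact Python ints; the final division of two exact integers is the only
# rounding step) and returns the grid with the oracle p-values.
exact_hypergeom_grid <- function(nmax) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".txt")
  writeLines(c(
    "import sys",
    "nmax = int(sys.argv[1])",
    "C = [[1]]",
    "for i in range(1, nmax + 1):",
    "    row = [1] + [C[-1][j-1] + C[-1][j] for j in range(1, i)] + [1]",
    "    C.append(row)",
    "w = open(sys.argv[2], 'w')",
    "for N in range(1, nmax + 1):",
    "    for K in range(N + 1):",
    "        for n in range(N + 1):",
    "            m = min(K, n)",
    "            den = C[N][n]",
    "            terms = [C[K][i] * C[N-K][n-i] for i in range(m + 1)",
    "                     if 0 <= n - i <= N - K]",
    "            tail = sum(terms)",
    "            for k in range(m + 1):",
    "                w.write('%d %d %d %d %.17g\\n' % (N, K, n, k, tail / den))",
    "                if k <= m - 1 and 0 <= n - k <= N - K:",
    "                    tail -= C[K][k] * C[N-K][n-k]",
    "w.close()"
  ), script)
  status <- system2(py, c(script, nmax, out))
  stopifnot(status == 0)
  grid <- read.table(out, col.names = c("N", "K", "n", "k", "p"))
  unlink(c(script, out))
  grid
}

# deterministic planted-core graph: a clique wired densely into a sparse
# ring periphery, so the clique dominates all three centralities
planted_clique_fixture <- function(core_size = 6, n_periph = 30,
                                   attach_every = 2) {
  core <- sprintf("CORE%d", seq_len(core_size))
  periph <- sprintf("P%02d", seq_len(n_periph))
  edges <- t(combn(core, 2))
  # ring over the periphery
  edges <- rbind(edges, cbind(periph, periph[c(2:n_periph, 1)]))
  # every core node attached to every attach_every-th peripheral node,
  # phase-shifted per core node
  for (i in seq_len(core_size)) {
    hit <- periph[seq(i %% attach_every + 1, n_periph, by = attach_every)]
    edges <- rbind(edges, cbind(core[i], hit))
  }
  list(nodes = c(core, periph), edges = edges, core = core)
}
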