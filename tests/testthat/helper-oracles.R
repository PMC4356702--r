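# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph wherever the package uses
# igraph) so that agreement is a real cross-check.

# quick expression_matrix from CK / RS value matrices (genes x replicates)
make_em <- function(ck, rs, gene_ids = NULL) {
  ck <- as.matrix(ck); rs <- as.matrix(rs)
  v <- cbind(ck, rs)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(v)))
  dimnames(v) <- list(gene_ids,
                      c(sprintf("CK_%d", seq_len(ncol(ck))),
                        sprintf("RS_%d", seq_len(ncol(rs)))))
  expression_matrix(v, rep(c("CK", "RS"), c(ncol(ck), ncol(rs))))
}

# symmetric 0/1 adjacency matrix of a random simple graph
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

adjacency_to_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# connected components by plain union-find over the edge list
oracle_components <- function(a) {
  n <- nrow(a)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && a[i, j] > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(rownames(a), roots)
}

# all-pairs shortest paths by Floyd-Warshall; average over connected pairs
# of the largest component (ties: the one containing the smallest name)
oracle_avg_path_length <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  comps <- oracle_components(a)
  comps <- comps[order(-lengths(comps), vapply(comps, min, character(1)))]
  main <- match(comps[[1]], rownames(a))
  if (length(main) < 2) return(NA_real_)
  dm <- d[main, main]
  vals <- dm[upper.tri(dm)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# local clustering by explicit triangle counting over node triples;
# global = mean over main-component nodes, degree<2 contributing 0
oracle_clustering <- function(a) {
  n <- nrow(a)
  local <- numeric(n)
  deg <- rowSums(a)
  for (v in seq_len(n)) {
    if (deg[v] < 2) { local[v] <- 0; next }
    nb <- which(a[v, ] > 0)
    tri <- 0
    for (x in nb) for (y in nb) if (y > x && a[x, y] > 0) tri <- tri + 1
    local[v] <- 2 * tri / (deg[v] * (deg[v] - 1))
  }
  comps <- oracle_components(a)
  comps <- comps[order(-lengths(comps), vapply(comps, min, character(1)))]
  main <- match(comps[[1]], rownames(a))
  list(global = mean(local[main]), local = local)
}

oracle_degrees <- function(a) rowSums(a > 0)

# naive O(n^3) UPGMA: cluster distance = mean of original pairwise
# distances across the two clusters; returns sorted merge heights
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# fully loop-based SAM q-values with exhaustive label assignments;
# mirrors the published procedure, shares no code with the package
oracle_exhaustive_q <- function(em, s0, pi0 = 1) {
  v <- log2(unclass(em))
  groups <- attr(em, "groups")
  ck <- which(groups == "CK"); rs <- which(groups == "RS")
  dstat <- function(cki, rsi) {
    n1 <- length(cki); n2 <- length(rsi)
    sapply(seq_len(nrow(v)), function(g) {
      x <- v[g, cki]; y <- v[g, rsi]
      s <- sqrt((1 / n1 + 1 / n2) *
                  (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2))
      if (s + s0 > 0) (mean(y) - mean(x)) / (s + s0) else 0
    })
  }
  ad <- abs(dstat(ck, rs))
  combos <- utils::combn(ncol(v), length(ck))
  perm_ad <- apply(combos, 2, function(cki) {
    abs(dstat(cki, setdiff(seq_len(ncol(v)), cki)))
  })
  q <- numeric(length(ad))
  thr <- sort(ad)
  fdr <- sapply(thr, function(t) {
    O <- sum(ad >= t)
    V <- stats::median(apply(perm_ad, 2, function(p) sum(p >= t)))
    min(1, pi0 * V / max(O, 1))
  })
  for (g in seq_along(ad)) {
    q[g] <- min(fdr[thr <= ad[g]])
  }
  names(q) <- rownames(v)
  q
}

# brute-force one-mode projections by double loop over all pairs
oracle_projection <- function(membership, mode) {
  # membership: data.frame gene_id, pathway_id
  if (mode == "gene_gene") {
    items <- unique(membership$gene_id)
    of <- function(g) membership$pathway_id[membership$gene_id == g]
  } else {
    items <- unique(membership$pathway_id)
    of <- function(p) membership$gene_id[membership$pathway_id == p]
  }
  edges <- list()
  if (length(items) >= 2) {
    for (i in seq_len(length(items) - 1)) for (j in (i + 1):length(items)) {
      if (length(intersect(of(items[i]), of(items[j]))) > 0) {
        edges[[length(edges) + 1]] <- sort(c(items[i], items[j]))
      }
    }
  }
  edges
}

# canonical sorted edge representation of an undirected igraph
edge_set <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  sort(apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1,
             paste, collapse = "|"))
}
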