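# Independent oracle implementations used to cross-check the package.
# These are coded from the definitions, not from the package internals.

# ---- Kabsch-Sander style secondary structure ------------------------------

oracle_ss <- function(s) {
  res <- s$residues
  n <- nrow(res)
  if (n < 5) return(rep("C", n))
  coord <- function(i, name) {
    a <- s$atoms[s$atoms$res_idx == i & s$atoms$name == name, ]
    if (nrow(a) == 0) return(c(NA, NA, NA))
    c(a$x[1], a$y[1], a$z[1])
  }
  Nc <- t(vapply(1:n, coord, numeric(3), name = "N"))
  Cc <- t(vapply(1:n, coord, numeric(3), name = "C"))
  Oc <- t(vapply(1:n, coord, numeric(3), name = "O"))
  Hc <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    v <- Cc[i - 1, ] - Oc[i - 1, ]
    if (all(is.finite(v)) && all(is.finite(Nc[i, ])))
      Hc[i, ] <- Nc[i, ] + v / sqrt(sum(v^2))
  }
  hbond <- function(i, j) {
    # CO(i) -> NH(j)
    if (abs(i - j) < 2) return(FALSE)
    pts <- list(Oc[i, ], Nc[j, ], Cc[i, ], Hc[j, ])
    if (any(!is.finite(unlist(pts)))) return(FALSE)
    dd <- function(a, b) sqrt(sum((a - b)^2))
    e <- 0.084 * 332 * (1 / dd(Oc[i, ], Nc[j, ]) + 1 / dd(Cc[i, ], Hc[j, ]) -
                        1 / dd(Oc[i, ], Hc[j, ]) - 1 / dd(Cc[i, ], Nc[j, ]))
    e < -0.5
  }
  hb <- outer(1:n, 1:n, Vectorize(hbond))
  turn <- rep(FALSE, n)
  for (i in 1:n) if (i + 4 <= n) turn[i] <- hb[i, i + 4]
  helix <- rep(FALSE, n)
  for (i in 2:n) if (i + 3 <= n && turn[i - 1] && turn[i])
    helix[i:(i + 3)] <- TRUE
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3) next
    anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
    para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
    if (anti || para) bridge[c(i, j)] <- TRUE
  }
  out <- rep("C", n)
  out[bridge] <- "E"
  out[helix] <- "H"
  out
}

# ---- graph centralities ----------------------------------------------------

# adj: symmetric 0/1 matrix, no self loops
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  clu <- vapply(1:n, function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
  # BFS distances
  dist <- matrix(Inf, n, n)
  for (src in 1:n) {
    d <- rep(Inf, n); d[src] <- 0
    frontier <- src
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in which(adj[u, ] == 1)) {
          if (is.infinite(d[w])) { d[w] <- d[u] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    dist[src, ] <- d
  }
  clo <- vapply(1:n, function(v) {
    reach <- which(is.finite(dist[v, ]) & seq_len(n) != v)
    if (!length(reach)) return(0)
    length(reach) / sum(dist[v, reach])
  }, numeric(1))
  # path counts
  sigma <- matrix(0, n, n)
  for (src in 1:n) {
    sigma[src, src] <- 1
    ord <- order(dist[src, ])
    for (v in ord) {
      if (v == src || is.infinite(dist[src, v])) next
      pred <- which(adj[v, ] == 1 & dist[src, ] == dist[src, v] - 1)
      sigma[src, v] <- sum(sigma[src, pred])
    }
  }
  btw <- vapply(1:n, function(v) {
    tot <- 0
    for (src in 1:n) for (tgt in 1:n) {
      if (src >= tgt || src == v || tgt == v) next
      if (is.infinite(dist[src, tgt])) next
      if (dist[src, v] + dist[v, tgt] == dist[src, tgt])
        tot <- tot + sigma[src, v] * sigma[v, tgt] / sigma[src, tgt]
    }
    tot / ((n - 1) * (n - 2) / 2)
  }, numeric(1))
  data.frame(degree = deg, clustering = clu, closeness = clo,
             betweenness = btw)
}

random_graph_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

# package rin object from an adjacency matrix (all edges typed IAC)
rin_from_adj <- function(adj) {
  n <- nrow(adj)
  keys <- paste0("A/", 1:n)
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(u = keys[idx[, 1]], v = keys[idx[, 2]],
                      etype = rep("IAC", nrow(idx)),
                      distance = rep(1, nrow(idx)),
                      atom_u = rep("CA", nrow(idx)),
                      atom_v = rep("CA", nrow(idx)),
                      stringsAsFactors = FALSE)
  out <- list(nodes = data.frame(key = keys, aa = "ALA",
                                 stringsAsFactors = FALSE),
              edges = edges, pdb_id = "RAND", chain = "A")
  class(out) <- "rin"
  out
}

# ---- global alignment ------------------------------------------------------

# Maximum global alignment score with affine gaps (cost open + extend * L),
# by recursion over (i, j, state of the previous column). Explores the full
# alignment space; memoisation only caches repeated subproblems.
oracle_align_score <- function(a, b, smat, open, extend, memo = TRUE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  cache <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i > m && j > n) return(0)
    key <- paste(i, j, last)
    if (memo && !is.null(cache[[key]])) return(cache[[key]])
    best <- -Inf
    if (i <= m && j <= n)
      best <- max(best, smat[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    if (i <= m)  # gap in B (A residue unmatched)
      best <- max(best,
                  -(if (last == "B") extend else open + extend) +
                  rec(i + 1, j, "B"))
    if (j <= n)  # gap in A
      best <- max(best,
                  -(if (last == "A") extend else open + extend) +
                  rec(i, j + 1, "A"))
    if (memo) cache[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# ---- rank statistics -------------------------------------------------------

oracle_kendall <- function(x, y) {
  n <- length(x)
  cp <- 0; dp <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) cp <- cp + 1
    if (s < 0) dp <- dp + 1
  }
  (cp - dp) / (0.5 * n * (n - 1))
}

# ---- accessibility ---------------------------------------------------------

# Independent ASA estimate: seeded random (not spiral) directions.
oracle_asa <- function(s, probe = 1.4, n_pts = 400, seed = 42) {
  set.seed(seed)
  heavy <- s$atoms[toupper(s$atoms$element) != "H", ]
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  rad <- rinstab:::vdw_radius(heavy$element) + probe
  u <- matrix(rnorm(n_pts * 3), n_pts, 3)
  u <- u / sqrt(rowSums(u^2))
  asa <- numeric(nrow(heavy))
  for (i in seq_len(nrow(heavy))) {
    pts <- sweep(u * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_pts)
    for (j in seq_len(nrow(heavy))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= rad[j]^2
    }
    asa[i] <- mean(acc) * 4 * pi * rad[i]^2
  }
  vapply(seq_len(nrow(s$residues)), function(r)
    sum(asa[heavy$res_idx == r]), numeric(1))
}
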