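## Residue interaction network: nodes are residues, edges are typed
## physico-chemical contacts. The generic contact (IAC) edge follows the
## closest-heavy-atom rule: any atom pair below the cutoff connects the
## two residues. Typed edges (hydrogen bond, salt bridge, pi-pi stack,
## pi-cation) fire on their own geometric rules and can coexist with the
## IAC edge for the same pair.

EDGE_TYPES <- c("HBOND", "IAC", "PIPISTACK", "PICATION", "IONIC")

#' Default geometric thresholds for typed edges
#'
#' Distance cutoffs in Angstrom for each interaction type. The generic
#' contact cutoff (5 A, closest heavy atom) is the one fixed by the
#' network definition; the typed thresholds are standard literature
#' values and freely configurable.
#'
#' @return named list of thresholds.
#' @export
default_rin_params <- function() {
  list(hbond = 3.5, ionic = 4.0, pipistack = 6.5, pication = 6.0)
}

ring_centroid <- function(atoms, aa) {
  ring <- AROMATIC_RING[[aa]]
  if (is.null(ring)) return(NULL)
  sel <- atoms$name %in% ring
  if (sum(sel) < 3) return(NULL)
  colMeans(cbind(atoms$x, atoms$y, atoms$z)[sel, , drop = FALSE])
}

#' Build the residue interaction network
#'
#' @param s an `rin_structure` with at least two residues.
#' @param contact_cutoff closest-heavy-atom distance (A) for the generic
#'   contact (IAC) edge, default 5.
#' @param params typed-edge thresholds, see [default_rin_params()].
#' @param min_separation minimum sequence separation for any edge
#'   (default 2, i.e. i and i+1 are never connected). Separation is
#'   measured on author residue numbering, so chain breaks are respected.
#' @return an object of class `rin`: list with `nodes` (data.frame key,
#'   aa), `edges` (data.frame u, v, etype, distance, atom_u, atom_v) and
#'   `structure` back-reference.
#' @export
build_rin <- function(s, contact_cutoff = 5.0, params = default_rin_params(),
                      min_separation = 2L) {
  if (nrow(s$residues) < 2) stop("empty structure: need >= 2 residues")
  stopifnot(contact_cutoff > 0, all(unlist(params) > 0))
  heavy <- s$atoms[toupper(s$atoms$element) != "H", , drop = FALSE]
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  n <- nrow(s$residues)
  keys <- s$residues$key
  aas <- s$residues$aa

  # precompute charged / polar / cation selections and ring centroids
  polar <- toupper(heavy$element) %in% c("N", "O")
  centroids <- lapply(seq_len(n), function(i)
    ring_centroid(heavy[heavy$res_idx == i, , drop = FALSE], aas[i]))

  max_thr <- max(contact_cutoff, unlist(params))
  edges <- list(); ne <- 0L
  add_edge <- function(i, j, etype, dist, au, av) {
    ne <<- ne + 1L
    edges[[ne]] <<- data.frame(u = keys[i], v = keys[j], etype = etype,
                               distance = dist, atom_u = au, atom_v = av,
                               stringsAsFactors = FALSE)
  }

  idx_by_res <- split(seq_len(nrow(heavy)), heavy$res_idx)
  for (i in seq_len(n - 1)) {
    ai <- idx_by_res[[as.character(i)]]
    if (is.null(ai)) next
    for (j in (i + 1):n) {
      sep <- max(j - i, abs(s$residues$resno[j] - s$residues$resno[i]))
      if (sep < min_separation) next
      aj <- idx_by_res[[as.character(j)]]
      if (is.null(aj)) next
      d2 <- outer(seq_along(ai), seq_along(aj), function(p, q)
        (xyz[ai[p], 1] - xyz[aj[q], 1])^2 +
        (xyz[ai[p], 2] - xyz[aj[q], 2])^2 +
        (xyz[ai[p], 3] - xyz[aj[q], 3])^2)
      dmin <- sqrt(min(d2))
      if (dmin > max_thr + 3) next  # +3 A slack for centroid-based rules
      w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      if (dmin <= contact_cutoff)
        add_edge(i, j, "IAC", dmin, heavy$name[ai[w[1]]], heavy$name[aj[w[2]]])
      # HBOND: N/O heavy-atom pair within threshold
      pi_ <- ai[polar[ai]]; pj <- aj[polar[aj]]
      if (length(pi_) && length(pj)) {
        dh2 <- outer(seq_along(pi_), seq_along(pj), function(p, q)
          (xyz[pi_[p], 1] - xyz[pj[q], 1])^2 +
          (xyz[pi_[p], 2] - xyz[pj[q], 2])^2 +
          (xyz[pi_[p], 3] - xyz[pj[q], 3])^2)
        if (min(dh2) <= params$hbond^2) {
          wh <- which(dh2 == min(dh2), arr.ind = TRUE)[1, ]
          add_edge(i, j, "HBOND", sqrt(min(dh2)),
                   heavy$name[pi_[wh[1]]], heavy$name[pj[wh[2]]])
        }
      }
      # IONIC: charged-group atoms of opposite sign
      ion <- ionic_distance(heavy, ai, aj, aas[i], aas[j], xyz)
      if (!is.null(ion) && ion$d <= params$ionic)
        add_edge(i, j, "IONIC", ion$d, ion$au, ion$av)
      # PIPISTACK: aromatic ring centroids
      if (!is.null(centroids[[i]]) && !is.null(centroids[[j]])) {
        dc <- sqrt(sum((centroids[[i]] - centroids[[j]])^2))
        if (dc <= params$pipistack)
          add_edge(i, j, "PIPISTACK", dc, "RING", "RING")
      }
      # PICATION: ring centroid vs Lys NZ / Arg CZ
      pc <- pication_distance(heavy, ai, aj, aas[i], aas[j], xyz,
                              centroids[[i]], centroids[[j]])
      if (!is.null(pc) && pc$d <= params$pication)
        add_edge(i, j, "PICATION", pc$d, pc$au, pc$av)
    }
  }
  edges <- if (ne) do.call(rbind, edges) else
    data.frame(u = character(), v = character(), etype = character(),
               distance = numeric(), atom_u = character(),
               atom_v = character(), stringsAsFactors = FALSE)
  out <- list(nodes = data.frame(key = keys, aa = aas,
                                 stringsAsFactors = FALSE),
              edges = edges,
              pdb_id = s$pdb_id, chain = s$chain)
  class(out) <- "rin"
  out
}

ionic_distance <- function(heavy, ai, aj, aai, aaj, xyz) {
  pos_i <- CHARGED_POS[[aai]]; neg_i <- CHARGED_NEG[[aai]]
  pos_j <- CHARGED_POS[[aaj]]; neg_j <- CHARGED_NEG[[aaj]]
  pick <- function(idx, names) idx[heavy$name[idx] %in% names]
  best <- NULL
  for (pair in list(list(pick(ai, pos_i), pick(aj, neg_j)),
                    list(pick(ai, neg_i), pick(aj, pos_j)))) {
    a <- pair[[1]]; b <- pair[[2]]
    if (!length(a) || !length(b)) next
    d2 <- outer(a, b, function(p, q)
      (xyz[p, 1] - xyz[q, 1])^2 + (xyz[p, 2] - xyz[q, 2])^2 +
      (xyz[p, 3] - xyz[q, 3])^2)
    w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    cand <- list(d = sqrt(min(d2)), au = heavy$name[a[w[1]]],
                 av = heavy$name[b[w[2]]])
    if (is.null(best) || cand$d < best$d) best <- cand
  }
  best
}

pication_distance <- function(heavy, ai, aj, aai, aaj, xyz, cen_i, cen_j) {
  pick <- function(idx, aa) {
    nm <- CATION_ATOM[[aa]]
    if (is.null(nm)) integer(0) else idx[heavy$name[idx] %in% nm]
  }
  best <- NULL
  for (pair in list(list(cen_i, pick(aj, aaj), "RING", TRUE),
                    list(cen_j, pick(ai, aai), "RING", FALSE))) {
    cen <- pair[[1]]; cat_idx <- pair[[2]]
    if (is.null(cen) || !length(cat_idx)) next
    d <- sqrt((xyz[cat_idx, 1] - cen[1])^2 + (xyz[cat_idx, 2] - cen[2])^2 +
              (xyz[cat_idx, 3] - cen[3])^2)
    w <- which.min(d)
    cand <- if (pair[[4]])
      list(d = d[w], au = "RING", av = heavy$name[cat_idx[w]])
    else
      list(d = d[w], au = heavy$name[cat_idx[w]], av = "RING")
    if (is.null(best) || cand$d < best$d) best <- cand
  }
  best
}

#' @export
print.rin <- function(x, ...) {
  cat(sprintf("<rin> %s chain %s: %d nodes, %d edges (%s)\n",
              x$pdb_id, x$chain, nrow(x$nodes), nrow(x$edges),
              paste(names(table(x$edges$etype)),
                    table(x$edges$etype), sep = ":", collapse = " ")))
  invisible(x)
}

#' Per-bond-type subnetworks
#'
#' Splits a network into one subnetwork per edge type plus an `ALL`
#' subnetwork carrying every edge. All six share the full node set, so
#' isolated nodes are retained.
#'
#' @param rin an `rin` object.
#' @return named list of `rin` objects: HBOND, IAC, PIPISTACK, PICATION,
#'   IONIC, ALL.
#' @export
subnetworks <- function(rin) {
  out <- lapply(EDGE_TYPES, function(et) {
    g <- rin
    g$edges <- rin$edges[rin$edges$etype == et, , drop = FALSE]
    g
  })
  names(out) <- EDGE_TYPES
  out$ALL <- rin
  out
}

rin_igraph <- function(g) {
  # collapse multi-edges between the same pair (etype multiplicity does
  # not affect unweighted topology measures)
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes$key)
  if (nrow(g$edges)) {
    pairs <- unique(data.frame(
      a = pmin(g$edges$u, g$edges$v),
      b = pmax(g$edges$u, g$edges$v), stringsAsFactors = FALSE))
    ig <- igraph::add_edges(ig, rbind(match(pairs$a, g$nodes$key),
                                      match(pairs$b, g$nodes$key)))
  }
  ig
}

#' Node centralities within one subnetwork
#'
#' Computes degree, local clustering coefficient, closeness and
#' betweenness for a node. Conventions for sparse or disconnected
#' graphs: clustering is 0 for degree < 2; closeness is
#' `(n_c - 1) / sum(d)` within the node's connected component of size
#' `n_c`, 0 for isolated nodes; betweenness is normalised by
#' `(n - 1)(n - 2) / 2` over the full node set. Paths are unweighted.
#'
#' @param g an `rin` object (typically one subnetwork).
#' @param node residue key (or vector of keys); defaults to all nodes.
#' @return data.frame with key, degree, clustering, closeness, betweenness.
#' @export
node_centralities <- function(g, node = NULL) {
  keys <- g$nodes$key
  if (is.null(node)) node <- keys
  if (!all(node %in% keys)) stop("unknown node: ",
                                 paste(setdiff(node, keys), collapse = ", "))
  ig <- rin_igraph(g)
  deg <- igraph::degree(ig)
  clu <- igraph::transitivity(ig, type = "local", isolates = "zero")
  clo <- suppressWarnings(igraph::closeness(ig, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  btw <- igraph::betweenness(ig, normalized = TRUE)
  btw[!is.finite(btw)] <- 0
  idx <- match(node, keys)
  data.frame(key = node, degree = as.integer(deg[idx]),
             clustering = as.numeric(clu[idx]),
             closeness = as.numeric(clo[idx]),
             betweenness = as.numeric(btw[idx]),
             stringsAsFactors = FALSE)
}

#' Neighbour amino-acid composition and network size
#'
#' Counts the residues in contact with a node (over all edge types, each
#' neighbour counted once) by amino-acid type.
#'
#' @param rin an `rin` object.
#' @param node residue key.
#' @return list with `composition` (named 20-vector of counts, ordered
#'   alphabetically by three-letter code) and `network_size` (node count).
#' @export
neighbor_composition <- function(rin, node) {
  if (!node %in% rin$nodes$key) stop("unknown node: ", node)
  e <- rin$edges
  nb <- unique(c(e$v[e$u == node], e$u[e$v == node]))
  aa <- rin$nodes$aa[match(nb, rin$nodes$key)]
  comp <- table(factor(aa, levels = AA3))
  list(composition = stats::setNames(as.integer(comp), AA3),
       network_size = nrow(rin$nodes))
}

#' Write node and edge tables
#'
#' Writes TSV tables consumable by network viewers: one row per node
#' (key, aa, ss, rsa and ALL-subnetwork centralities) and one per edge.
#'
#' @param rin an `rin` object.
#' @param s the annotated source structure.
#' @param nodes_path,edges_path output TSV paths.
#' @return invisibly, the node table.
#' @export
write_rin_tables <- function(rin, s, nodes_path, edges_path) {
  cent <- node_centralities(rin)
  nodes <- data.frame(id = rin$nodes$key, aa = rin$nodes$aa,
                      ss = s$residues$ss[match(rin$nodes$key, s$residues$key)],
                      rsa = s$residues$rsa[match(rin$nodes$key, s$residues$key)],
                      cent[match(rin$nodes$key, cent$key),
                           c("degree", "clustering", "closeness", "betweenness")],
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rin$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(nodes)
}
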