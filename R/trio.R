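#' Enumerate all unordered TF triples
#'
#' Deterministic lexicographic enumeration of the C(n, 3) triples.
#'
#' @param tf_ids character vector of at least 3 TF ids.
#' @return character matrix with 3 columns, one row per triple, each row
#'   sorted; rows in lexicographic order.
#' @export
enumerate_trios <- function(tf_ids) {
  tf_ids <- unique(tf_ids)
  if (length(tf_ids) < 3L)
    stop("need at least 3 TFs to form a trio, got ", length(tf_ids))
  tf_ids <- sort(tf_ids)
  t(combn(tf_ids, 3L))
}

neighborhoods <- function(net) {
  adj <- lapply(setNames(net$nodes$id, net$nodes$id), function(i) character())
  for (k in seq_len(nrow(net$edges))) {
    x <- net$edges$x[k]; y <- net$edges$y[k]
    adj[[x]] <- c(adj[[x]], y)
    adj[[y]] <- c(adj[[y]], x)
  }
  adj
}

#' Score one TF trio by network coverage and redundancy
#'
#' Coverage is the number of distinct nodes adjacent to at least one
#' member of the trio (open neighborhoods: a TF does not cover itself);
#' redundancy is the sum of the three pairwise neighborhood-intersection
#' sizes.
#'
#' @param net a `coexpression_network`.
#' @param triplet character vector of 3 distinct TF ids in the network.
#' @return list with `triplet` (sorted), `coverage`, `redundancy`.
#' @export
score_trio <- function(net, triplet) {
  stopifnot(length(triplet) == 3L, !anyDuplicated(triplet))
  missing <- setdiff(triplet, net$nodes$id)
  if (length(missing)) stop("TF absent from network: ", missing[1L])
  adj <- neighborhoods(net)
  score_trio_adj(adj, sort(triplet))
}

score_trio_adj <- function(adj, triplet) {
  na <- adj[[triplet[1L]]]; nb <- adj[[triplet[2L]]]; nc <- adj[[triplet[3L]]]
  list(triplet = triplet,
       coverage = length(unique(c(na, nb, nc))),
       redundancy = length(intersect(na, nb)) + length(intersect(na, nc)) +
         length(intersect(nb, nc)))
}

#' Find the TF trio spanning most of the network with minimum redundancy
#'
#' Exhaustively scores every C(n, 3) triple: the winner maximizes
#' coverage, with ties broken by minimum redundancy and then by
#' lexicographic triplet order. Also returns the trio-centered
#' subnetwork (the trio and its neighborhoods with induced edges).
#'
#' @param net a `coexpression_network`.
#' @param tf_ids candidate TF ids (intersected with the network nodes).
#' @return list with `best` (a [score_trio()] result), `table` (all
#'   trios ranked by the same objective) and `subnetwork` (a
#'   `coexpression_network`).
#' @export
best_trio <- function(net, tf_ids) {
  tf_ids <- intersect(tf_ids, net$nodes$id)
  trios <- enumerate_trios(tf_ids)
  adj <- neighborhoods(net)
  cov <- integer(nrow(trios))
  red <- integer(nrow(trios))
  for (k in seq_len(nrow(trios))) {
    s <- score_trio_adj(adj, trios[k, ])
    cov[k] <- s$coverage
    red[k] <- s$redundancy
  }
  ord <- order(-cov, red, trios[, 1L], trios[, 2L], trios[, 3L])
  tab <- data.frame(tf_a = trios[ord, 1L], tf_b = trios[ord, 2L],
                    tf_c = trios[ord, 3L], coverage = cov[ord],
                    redundancy = red[ord], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  win <- unlist(tab[1L, 1:3], use.names = FALSE)
  sub_ids <- unique(c(win, unlist(adj[win], use.names = FALSE)))
  sub_edges <- net$edges[net$edges$x %in% sub_ids & net$edges$y %in% sub_ids, ,
                         drop = FALSE]
  rownames(sub_edges) <- NULL
  sub_nodes <- net$nodes[net$nodes$id %in% sub_ids, , drop = FALSE]
  deg <- setNames(integer(nrow(sub_nodes)), sub_nodes$id)
  tb <- table(c(sub_edges$x, sub_edges$y))
  deg[names(tb)] <- as.integer(tb)
  sub_nodes$degree <- unname(deg[sub_nodes$id])
  rownames(sub_nodes) <- NULL
  subnet <- structure(list(nodes = sub_nodes, edges = sub_edges),
                      class = "coexpression_network")
  list(best = list(triplet = win, coverage = tab$coverage[1L],
                   redundancy = tab$redundancy[1L]),
       table = tab, subnetwork = subnet)
}
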