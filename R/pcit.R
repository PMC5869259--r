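#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of z:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Vectorized over its arguments.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations in \[-1, 1\].
#' @return the partial correlation(s).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1))
    stop("correlations must lie in [-1, 1]")
  if (any(abs(r_xz) == 1) || any(abs(r_yz) == 1))
    stop("partial correlation undefined: |r_xz| or |r_yz| equals 1")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Prune a correlation matrix with the PCIT trio screen
#'
#' For every trio of nodes the information-theoretic tolerance is the
#' mean ratio of partial to direct correlations; an edge is discarded
#' when some third node makes it non-significant (its absolute
#' correlation falls below the tolerance times both correlations with
#' that third node). See [pcit_network()] for the full pipeline step.
#'
#' @param r symmetric correlation matrix with unit diagonal and node ids
#'   as dimnames.
#' @param guard direct correlations below this magnitude are excluded
#'   from the tolerance mean (default 1e-12).
#' @return logical keep matrix (symmetric, FALSE diagonal): TRUE where
#'   the edge survives.
#' @export
pcit_prune <- function(r, guard = 1e-12) {
  stopifnot(is.matrix(r))
  if (!isSymmetric(unname(r), tol = 1e-12))
    stop("correlation matrix must be symmetric")
  n <- nrow(r)
  if (n < 3L) {
    warning("fewer than 3 nodes: no trio exists, all pairs retained")
    keep <- matrix(TRUE, n, n, dimnames = dimnames(r))
    diag(keep) <- FALSE
    return(keep)
  }
  keep <- pcit_keep_cpp(r, guard)
  dimnames(keep) <- dimnames(r)
  keep
}

new_network <- function(r, keep, is_tf, is_de) {
  ids <- rownames(r)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(x = ids[idx[, 1L]], y = ids[idx[, 2L]],
                      weight = r[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$x, edges$y), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- setNames(integer(length(ids)), ids)
  tab <- table(c(edges$x, edges$y))
  deg[names(tab)] <- as.integer(tab)
  nodes <- data.frame(id = ids, is_tf = ids %in% is_tf,
                      is_de = ids %in% is_de, degree = unname(deg),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build the PCIT co-expression network
#'
#' Computes Pearson correlations between all pairs of the node set
#' (DE genes, significant TFs, and any extra nodes) across all animals
#' of the analysis tissue — both states pooled, as a single network is
#' inferred for the two conditions jointly — then applies the PCIT trio
#' screen. Surviving correlations become undirected weighted edges.
#'
#' @param norm a `normalized_expression` ([extract_normalized()]).
#' @param de_ids DE gene ids.
#' @param tf_ids significant TF ids.
#' @param extra_nodes optional additional gene ids to include.
#' @return a `coexpression_network`: `nodes` (id, is_tf, is_de, degree)
#'   and `edges` (x, y, weight).
#' @export
build_network <- function(norm, de_ids, tf_ids, extra_nodes = character()) {
  stopifnot(inherits(norm, "normalized_expression"))
  ids <- unique(c(de_ids, tf_ids, extra_nodes))
  missing <- setdiff(ids, rownames(norm$values))
  if (length(missing))
    stop("node absent from normalized matrix: ", missing[1L])
  if (length(ids) < 3L)
    stop("need at least 3 nodes (DE genes + significant TFs + extras), got ",
         length(ids))
  r <- stats::cor(t(norm$values[ids, , drop = FALSE]))
  keep <- pcit_prune(r)
  new_network(r, keep, is_tf = tf_ids, is_de = de_ids)
}

#' Write a network as edge list, node attributes and SIF
#'
#' @param net a `coexpression_network`.
#' @param edge_path,node_path,sif_path output file paths (`NULL` to skip).
#' @param interaction SIF interaction type (default `"co"`).
#' @return invisibly, the network.
#' @export
write_network <- function(net, edge_path = NULL, node_path = NULL,
                          sif_path = NULL, interaction = "co") {
  if (!is.null(edge_path)) write_tsv(net$edges, edge_path)
  if (!is.null(node_path)) write_tsv(net$nodes, node_path)
  if (!is.null(sif_path)) {
    lines <- if (nrow(net$edges)) {
      paste(net$edges$x, interaction, net$edges$y)
    } else character()
    isolated <- setdiff(net$nodes$id, c(net$edges$x, net$edges$y))
    writeLines(c(lines, isolated), sif_path)
  }
  invisible(net)
}
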