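# Shared fixtures and independent oracles for the suite.

# Run the normalization front end (counts -> RPKM -> filter -> log2 ->
# REML fit -> per-animal values) on a simulated experiment.
normalize_sim <- function(sim, tissue = "liver", offset = 1, ...) {
  rpkm <- compute_rpkm(sim$counts)
  keep <- filter_expressed(rpkm)$retained
  y <- log2_transform(rpkm[keep, , drop = FALSE], offset)
  fit <- fit_mixed_model(y, sim$design, ...)
  list(fit = fit, norm = extract_normalized(fit, sim$design, tissue))
}

# Memoised small fitted world so several tests can share one REML fit.
.world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.world_cache$w)) {
    cfg <- sim_config(n_genes = 80, n_tf = 10, prop_de = 0.15,
                      n_planted_regulators = 0, seed = 42)
    sim <- simulate_experiment(cfg)
    ns <- normalize_sim(sim)
    .world_cache$w <- list(sim = sim, fit = ns$fit, norm = ns$norm)
  }
  .world_cache$w
}

# Independent brute-force implementation of the PCIT trio screen,
# written as three nested loops straight from the rule definition.
pcit_oracle <- function(r, guard = 1e-12) {
  n <- nrow(r)
  flagged <- matrix(FALSE, n, n)
  for (x in seq_len(n - 2)) for (y in seq((x + 1), n - 1)) {
    for (z in seq((y + 1), n)) {
      pairs <- list(c(x, y, z), c(x, z, y), c(y, z, x))
      ratios <- numeric(0)
      for (p in pairs) {
        den <- (1 - r[p[1], p[3]]^2) * (1 - r[p[2], p[3]]^2)
        direct <- r[p[1], p[2]]
        if (den > 0 && abs(direct) >= guard) {
          partial <- (direct - r[p[1], p[3]] * r[p[2], p[3]]) / sqrt(den)
          ratios <- c(ratios, partial / direct)
        }
      }
      if (!length(ratios)) next
      eps <- mean(ratios)
      for (p in pairs) {
        a <- p[1]; b <- p[2]; k <- p[3]
        if (abs(r[a, b]) <= abs(eps * r[a, k]) &&
            abs(r[a, b]) <= abs(eps * r[b, k]))
          flagged[a, b] <- flagged[b, a] <- TRUE
      }
    }
  }
  keep <- !flagged
  diag(keep) <- FALSE
  keep
}

# Independent set-arithmetic trio scorer working on a plain edge list.
trio_oracle <- function(edges, node_ids, triplet) {
  nb <- function(v) unique(c(edges$y[edges$x == v], edges$x[edges$y == v]))
  na <- nb(triplet[1]); nbb <- nb(triplet[2]); nc <- nb(triplet[3])
  list(coverage = length(unique(c(na, nbb, nc))),
       redundancy = length(intersect(na, nbb)) + length(intersect(na, nc)) +
         length(intersect(nbb, nc)))
}

# Exhaustive oracle for the best trio: enumerate, score, order.
best_trio_oracle <- function(edges, node_ids, tf_ids) {
  trios <- t(combn(sort(tf_ids), 3L))
  sc <- t(apply(trios, 1L, function(tr)
    unlist(trio_oracle(edges, node_ids, tr))))
  ord <- order(-sc[, 1L], sc[, 2L], trios[, 1L], trios[, 2L], trios[, 3L])
  list(triplet = unname(trios[ord[1L], ]),
       coverage = unname(sc[ord[1L], 1L]),
       redundancy = unname(sc[ord[1L], 2L]))
}

# Build a coexpression_network object from an edge data frame, for
# trio-module tests on hand-constructed graphs.
make_net <- function(edges, node_ids, tf_ids = character(),
                     de_ids = character()) {
  deg <- setNames(integer(length(node_ids)), node_ids)
  tab <- table(c(edges$x, edges$y))
  deg[names(tab)] <- as.integer(tab)
  structure(list(
    nodes = data.frame(id = node_ids, is_tf = node_ids %in% tf_ids,
                       is_de = node_ids %in% de_ids, degree = unname(deg),
                       stringsAsFactors = FALSE),
    edges = edges), class = "coexpression_network")
}

# Random correlation matrix from an n_samples x n data matrix.
random_corr <- function(n, n_samples = 12, seed = 1) {
  set.seed(seed)
  r <- stats::cor(matrix(stats::rnorm(n_samples * n), n_samples, n))
  dimnames(r) <- list(sprintf("N%02d", seq_len(n)), sprintf("N%02d", seq_len(n)))
  r
}

# Random undirected simple graph as an edge data frame.
random_graph <- function(n_nodes, p_edge = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("V%02d", seq_len(n_nodes))
  all_pairs <- t(combn(ids, 2L))
  sel <- stats::runif(nrow(all_pairs)) < p_edge
  list(edges = data.frame(x = all_pairs[sel, 1L], y = all_pairs[sel, 2L],
                          weight = 1, stringsAsFactors = FALSE),
       ids = ids)
}

# Minimal normalized_expression constructor for DE-module tests.
make_norm <- function(values, states) {
  pre <- names(states)[states == "pre"]
  post <- names(states)[states == "post"]
  structure(list(values = values, animal_state = states,
                 mean_pre = rowMeans(values[, pre, drop = FALSE]),
                 mean_post = rowMeans(values[, post, drop = FALSE]),
                 tissue = "liver"),
            class = "normalized_expression")
}
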