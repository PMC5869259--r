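test_that("RPKM follows the reads / (depth x length) formula", {
  cm <- count_matrix(matrix(100, 1, 1, dimnames = list("g1", "s1")),
                     exon_length_kb = c(g1 = 2),
                     mapped_reads_millions = c(s1 = 50))
  expect_equal(compute_rpkm(cm)[1, 1], 1.0)
  cm$counts[1, 1] <- 0
  expect_equal(compute_rpkm(cm)[1, 1], 0)

  set.seed(21)
  counts <- matrix(rpois(120, 40), 20, 6,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  len <- setNames(runif(20, 0.5, 5), rownames(counts))
  mm <- setNames(runif(6, 30, 90), colnames(counts))
  rpkm <- compute_rpkm(count_matrix(counts, len, mm))
  for (j in 1:20) for (s in 1:6)
    expect_equal(rpkm[j, s], counts[j, s] / (mm[[s]] * len[[j]]))
})

test_that("count_matrix validates ids, lengths and library sizes", {
  m <- matrix(1, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(count_matrix(m, c(g1 = 1), c(s1 = 1, s2 = 1)),
               "duplicate gene id: g1")
  m2 <- matrix(1, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(count_matrix(m2, c(g1 = 0), c(s1 = 1, s2 = 1)), "g1")
  expect_error(count_matrix(m2, c(g1 = 1), c(s1 = 1, s2 = 0)), "s2")
  expect_error(count_matrix(m2 - 2, c(g1 = 1), c(s1 = 1, s2 = 1)),
               "non-negative")
})

test_that("expressed-gene filter uses an inclusive mean-RPKM boundary", {
  rpkm <- rbind(at_boundary = rep(0.2, 4), silent = rep(0, 4),
                just_below = rep(0.199999, 4), mixed = c(0, 0, 0.5, 0.4))
  colnames(rpkm) <- sprintf("s%d", 1:4)
  fe <- filter_expressed(rpkm, 0.2)
  expect_setequal(fe$retained, c("at_boundary", "mixed"))
  # brute-force scan oracle on a random matrix
  set.seed(8)
  r2 <- matrix(runif(200, 0, 0.5), 20, 10,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  oracle <- rownames(r2)[sapply(seq_len(20), function(j) mean(r2[j, ]) >= 0.2)]
  expect_setequal(filter_expressed(r2, 0.2)$retained, oracle)
})

test_that("log2 transform is offset-shifted and rejects bad input", {
  expect_equal(log2_transform(1, offset = 1), 1.0)
  expect_equal(log2_transform(0, offset = 1), 0.0)
  expect_error(log2_transform(1, offset = 0), "offset")
  expect_error(log2_transform(-0.1), "negative")
  v <- c(0, 0.3, 2, 17)
  expect_equal(log2_transform(v, 0.5), log2(v + 0.5))
})

test_that("RPKM is invariant to splitting a sample into two half-depth halves", {
  set.seed(13)
  counts <- matrix(rpois(30, 1000), 10, 3,
                   dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2", "s3")))
  len <- setNames(runif(10, 0.5, 5), rownames(counts))
  mm <- setNames(c(60, 50, 40), colnames(counts))
  rpkm <- compute_rpkm(count_matrix(counts, len, mm))
  split_counts <- cbind(`s1a` = counts[, 1] / 2, `s1b` = counts[, 1] / 2)
  rpkm_split <- compute_rpkm(count_matrix(
    split_counts, len, c(s1a = mm[[1]] / 2, s1b = mm[[1]] / 2)))
  expect_equal(rowMeans(rpkm_split), rpkm[, 1], tolerance = 1e-12)
})

test_that("constant data yield mu = c with zero effects and variances", {
  w <- small_world()
  y <- matrix(3.7, 10, nrow(w$sim$design),
              dimnames = list(sprintf("g%02d", 1:10), w$sim$design$sample_id))
  fit <- fit_mixed_model(y, w$sim$design)
  expect_true(fit$converged)
  expect_equal(fit$mu, 3.7)
  expect_equal(unname(fit$gene_effects), rep(0, 10))
  expect_true(all(fit$interaction_effects == 0))
  expect_equal(c(fit$var_gene, fit$var_gapt, fit$var_resid), c(0, 0, 0))
})

test_that("EM-REML agrees with the independent lme4 solver", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_genes = 30, n_tf = 0, prop_de = 0, n_tissues = 2,
                    n_animals_per_state = 3, n_libraries = 16,
                    var_gene = 1, var_gapt = 0.5, var_resid = 0.2, seed = 9)
  sim <- simulate_experiment(cfg)
  y <- log2_transform(compute_rpkm(sim$counts))
  fit <- fit_mixed_model(y, sim$design)
  expect_true(fit$converged)

  d <- sim$design
  long <- data.frame(
    y = as.vector(y),
    gene = factor(rep(rownames(y), times = ncol(y))),
    lib = factor(rep(d$library_id, each = nrow(y))),
    combo = factor(rep(paste(d$animal_id, d$tissue, sep = "|"),
                       each = nrow(y))))
  long$gc <- interaction(long$gene, long$combo, drop = TRUE)
  m <- lme4::lmer(y ~ lib + (1 | gene) + (1 | gc), data = long, REML = TRUE,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$var_gene, vc$vcov[vc$grp == "gene"], tolerance = 1e-4)
  expect_equal(fit$var_gapt, vc$vcov[vc$grp == "gc"], tolerance = 1e-4)
  expect_equal(fit$var_resid, vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  re <- lme4::ranef(m)
  expect_equal(unname(fit$gene_effects),
               re$gene[names(fit$gene_effects), 1], tolerance = 1e-4)
  key <- paste0(rep(rownames(y), times = ncol(fit$interaction_effects)), ".",
                rep(colnames(fit$interaction_effects), each = nrow(y)))
  expect_equal(as.vector(fit$interaction_effects), re$gc[key, 1],
               tolerance = 1e-4)
})

test_that("solutions satisfy the Henderson mixed-model equations", {
  cfg <- sim_config(n_genes = 6, n_tf = 0, prop_de = 0, n_tissues = 2,
                    n_animals_per_state = 2, n_libraries = 10, seed = 14)
  sim <- simulate_experiment(cfg)
  y <- log2_transform(compute_rpkm(sim$counts))
  fit <- fit_mixed_model(y, sim$design)
  d <- sim$design
  n_g <- nrow(y); n_s <- ncol(y)
  lib <- factor(d$library_id)
  X1 <- stats::model.matrix(~lib, contrasts.arg = list(lib = "contr.sum"))
  X <- kronecker(X1, rep(1, n_g))            # observations gene-major per sample
  Zg <- kronecker(rep(1, n_s), diag(n_g))
  combo <- factor(paste(d$animal_id, d$tissue, sep = "|"),
                  levels = colnames(fit$interaction_effects))
  Ac <- stats::model.matrix(~ 0 + combo)
  Zw <- kronecker(Ac, diag(n_g))             # gene x combo interaction
  yv <- as.vector(y)                          # gene-major within sample
  lg <- fit$var_resid / fit$var_gene
  lw <- fit$var_resid / fit$var_gapt
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Zg), crossprod(X, Zw)),
    cbind(crossprod(Zg, X), crossprod(Zg) + diag(lg, n_g), crossprod(Zg, Zw)),
    cbind(crossprod(Zw, X), crossprod(Zw, Zg),
          crossprod(Zw) + diag(lw, ncol(Zw))))
  rhs <- c(crossprod(X, yv), crossprod(Zg, yv), crossprod(Zw, yv))
  beta <- c(fit$mu, fit$library_effects[levels(lib)][-nlevels(lib)] /
              1)  # contr.sum coefficients are the first n-1 effects
  sol <- c(beta, unname(fit$gene_effects), as.vector(fit$interaction_effects))
  expect_lt(max(abs(C %*% sol - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("adding a constant shifts mu only", {
  w <- small_world()
  y <- log2_transform(compute_rpkm(w$sim$counts))[1:25, , drop = FALSE]
  f1 <- fit_mixed_model(y, w$sim$design)
  f2 <- fit_mixed_model(y + 2.5, w$sim$design)
  expect_equal(f2$mu, f1$mu + 2.5, tolerance = 1e-8)
  expect_equal(f2$gene_effects, f1$gene_effects, tolerance = 1e-8)
  expect_equal(f2$interaction_effects, f1$interaction_effects, tolerance = 1e-8)
  expect_equal(c(f2$var_gene, f2$var_gapt, f2$var_resid),
               c(f1$var_gene, f1$var_gapt, f1$var_resid), tolerance = 1e-8)
})

test_that("noiseless data are reproduced by the fitted values", {
  cfg <- sim_config(n_genes = 20, n_tf = 0, prop_de = 0, var_resid = 0,
                    seed = 4)
  sim <- simulate_experiment(cfg)
  fit <- suppressWarnings(
    fit_mixed_model(sim$truth$log_expr, sim$design, max_iter = 1500L))
  fv <- fitted_values(fit, sim$design)
  expect_lt(max(abs(fv - sim$truth$log_expr)), 1e-6)
})

test_that("random-effect solutions are centered and extraction is additive", {
  w <- small_world()
  fit <- w$fit
  expect_lt(abs(mean(fit$gene_effects)), 1e-6 * stats::sd(fit$gene_effects))
  expect_lt(abs(mean(fit$interaction_effects)),
            1e-6 * stats::sd(fit$interaction_effects))

  norm <- w$norm
  g <- names(fit$gene_effects)[1L]
  animal <- colnames(norm$values)[1L]
  combo <- paste(animal, "liver", sep = "|")
  expect_equal(norm$values[g, animal],
               fit$mu + fit$gene_effects[[g]] +
                 fit$interaction_effects[g, combo])
  pre <- names(norm$animal_state)[norm$animal_state == "pre"]
  expect_equal(norm$mean_pre,
               rowMeans(norm$values[, pre, drop = FALSE]), tolerance = 1e-10)
  expect_error(extract_normalized(fit, w$sim$design, "kidney"),
               "available.*liver")
})

test_that("a singular design and too few animals are rejected", {
  w <- small_world()
  y <- log2_transform(compute_rpkm(w$sim$counts))[1:5, , drop = FALSE]
  d <- w$sim$design
  d$library_id <- factor(d$library_id, levels = c(unique(d$library_id), "L999"))
  expect_error(fit_mixed_model(y, d), "L999")
  d2 <- w$sim$design[w$sim$design$animal_id %in% c("A01", "A07"), ]
  expect_error(fit_mixed_model(y[, d2$sample_id], d2), "2 animals")
})
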