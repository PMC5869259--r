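test_that("config validation rejects inconsistent worlds", {
  expect_error(sim_config(prop_de = 1.5), "prop_de")
  expect_error(sim_config(var_gene = -1), "variance")
  expect_error(sim_config(n_genes = 10, n_tf = 20), "n_tf")
  expect_error(sim_config(n_genes = 100, n_tf = 60, prop_de = 0.5), "overlap")
  expect_error(sim_config(n_libraries = 10), "n_libraries")
  # both shifted correlations leave [-1, 1]: ambiguous wiring
  expect_error(sim_config(n_tf = 10, prop_de = 0.1, n_planted_regulators = 1,
                          r_pre = 0.5, wiring_shift = 1.6),
               "unachievable")
})

test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(n_genes = 50, n_tf = 5, prop_de = 0.1,
                    n_planted_regulators = 2, seed = 1)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$design, s2$design)
  expect_identical(s1$truth$log_expr, s2$truth$log_expr)
  s3 <- simulate_experiment(sim_config(n_genes = 50, n_tf = 5, prop_de = 0.1,
                                       n_planted_regulators = 2, seed = 2))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("zero-noise world is constant per gene on the log scale", {
  cfg <- sim_config(n_genes = 15, n_tf = 0, prop_de = 0,
                    var_gapt = 0, var_resid = 0, library_sd = 0, seed = 3)
  sim <- simulate_experiment(cfg)
  spread <- apply(sim$truth$log_expr, 1L, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("planted DE genes realize the configured post-state shift", {
  # oracle: sample means over the emitted matrix
  cfg <- sim_config(n_genes = 500, n_tf = 0, prop_de = 0.1, de_effect = 2.0,
                    var_resid = 0.25, seed = 7)
  sim <- simulate_experiment(cfg)
  lg <- log2(compute_rpkm(sim$counts))   # emitted matrix, log scale
  post <- sim$design$sample_id[sim$design$state == "post"]
  pre <- sim$design$sample_id[sim$design$state == "pre"]
  de <- sim$truth$de_genes$gene_id[sim$truth$de_genes$effect != 0]
  expect_length(de, 50L)
  diffs <- rowMeans(lg[de, post]) - rowMeans(lg[de, pre])
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2.0), 3 * se)
  # planted |mean difference| stochastically dominates null genes
  null <- setdiff(rownames(lg), de)
  null_diffs <- abs(rowMeans(lg[null, post]) - rowMeans(lg[null, pre]))
  expect_gt(stats::quantile(abs(diffs), 0.1), stats::quantile(null_diffs, 0.9))
  expect_true(all(sim$truth$de_genes$effect[match(null, sim$truth$de_genes$gene_id)] == 0))
})

test_that("method-of-moments estimates recover the variance components", {
  est <- sapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 500, n_tf = 0, prop_de = 0, library_sd = 0,
                      var_gene = 1.0, var_gapt = 0.5, var_resid = 0.25,
                      seed = 100 + s)
    sim <- simulate_experiment(cfg)
    lg <- sim$truth$log_expr
    d <- sim$design
    # var_gene from the spread of gene means; var_resid from replicate
    # libraries of the same animal x tissue combination
    vg <- stats::var(rowMeans(lg))
    combo <- paste(d$animal_id, d$tissue, sep = "|")
    reps <- names(which(table(combo) == 2L))
    dif <- sapply(reps, function(cb) {
      s2 <- d$sample_id[combo == cb]
      lg[, s2[1L]] - lg[, s2[2L]]
    })
    ve <- mean(apply(dif, 2L, stats::var)) / 2
    c(vg = vg, ve = ve)
  })
  m <- rowMeans(est)
  expect_lt(abs(m[["vg"]] - 1.0) / 1.0, 0.2)
  expect_lt(abs(m[["ve"]] - 0.25) / 0.25, 0.2)
})

test_that("planted wiring realizes r_pre and the wiring shift exactly at the latent level", {
  cfg <- sim_config(n_genes = 60, n_tf = 6, prop_de = 0.2, de_effect = 1,
                    var_resid = 0, library_sd = 0, r_pre = 0.9,
                    wiring_shift = 1.0, n_planted_regulators = 2, seed = 11)
  sim <- simulate_experiment(cfg)
  lg <- sim$truth$log_expr
  d <- sim$design
  liver_pre <- d$sample_id[d$tissue == "liver" & d$state == "pre"]
  liver_post <- d$sample_id[d$tissue == "liver" & d$state == "post"]
  for (rg in sim$truth$regulators) {
    tgt <- sim$truth$regulator_targets[[rg]]
    r1 <- stats::cor(lg[rg, liver_pre], t(lg[tgt, liver_pre, drop = FALSE]))
    r2 <- stats::cor(lg[rg, liver_post], t(lg[tgt, liver_post, drop = FALSE]))
    expect_equal(as.vector(r1), rep(0.9, length(tgt)), tolerance = 1e-8)
    expect_equal(as.vector(r1 - r2), rep(1.0, length(tgt)), tolerance = 1e-8)
  }
  expect_equal(sim$truth$r_post, -0.1)
})

test_that("fixture bundle round-trips through the pipeline readers", {
  cfg <- sim_config(n_genes = 40, n_tf = 5, prop_de = 0.1,
                    n_planted_regulators = 1, seed = 5)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim, dir)
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  expect_identical(length(readLines(paths[["counts"]])), 41L)  # header + genes
  design <- read_design(paths[["design"]])
  cm <- read_counts(paths[["counts"]], design)
  expect_equal(cm$counts, sim$counts$counts)
  expect_equal(unname(cm$exon_length_kb), unname(sim$counts$exon_length_kb),
               tolerance = 1e-12)
  expect_identical(read_tf_list(paths[["tf_list"]]), sim$tf_list)
  expect_equal(design$mapped_reads_millions, sim$design$mapped_reads_millions,
               tolerance = 1e-12)
  sim$counts$counts <- sim$counts$counts[0, , drop = FALSE]
  expect_error(write_fixture_bundle(sim, dir), "empty gene set")
})
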