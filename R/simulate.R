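#' Simulation configuration for a two-state multi-tissue RNA-seq design
#'
#' Describes the synthetic world the generator emulates: a balanced
#' two-state design (default 6 + 6 animals), several tissues per animal,
#' one sequencing library per animal x tissue combination plus optional
#' replicate libraries, and log2-RPKM expression drawn from the additive
#' mixed model
#' \deqn{Y = \mu + L_i + G_j + GAPT_{jkpt} + e}
#' with a fixed library effect \eqn{L_i}, a random gene effect \eqn{G_j}
#' (variance `var_gene`), a random gene x animal x state x tissue effect
#' (variance `var_gapt`) and a residual (variance `var_resid`).
#'
#' Differentially expressed (DE) genes receive an additive `de_effect`
#' shift in their post-state interaction terms. Planted regulators are
#' transcription factors whose interaction-level signal is mixed into a
#' disjoint block of DE target genes so that the regulator-target
#' correlation is `r_pre` in the pre state and `r_pre - wiring_shift`
#' (or `r_pre + wiring_shift` when the former leaves \[-1, 1\]) in the
#' post state.
#'
#' @param n_genes number of genes.
#' @param n_tf number of genes labelled as transcription factors (the
#'   last `n_tf` gene ids).
#' @param n_animals_per_state animals per physiological state (default 6,
#'   i.e. 12 animals total).
#' @param n_tissues tissues sampled per animal (default 5).
#' @param n_libraries total sequencing libraries; must be at least
#'   animals x tissues, surplus libraries become replicate libraries of
#'   the first combinations (default 72 for the 12 x 5 design).
#' @param var_gene variance of the gene effect (log2 scale).
#' @param var_gapt variance of the gene x animal x state x tissue effect.
#' @param var_resid residual variance.
#' @param library_sd standard deviation of the fixed library effects.
#' @param prop_de proportion of genes that are differentially expressed.
#' @param de_effect log2-scale shift added to DE genes post-state.
#' @param n_planted_regulators number of TFs with planted differential
#'   wiring to DE targets.
#' @param r_pre regulator-target correlation in the pre state.
#' @param wiring_shift change in regulator-target correlation between
#'   states, in \[0, 2\].
#' @param mean_log_expr grand mean of log2 RPKM.
#' @param seed master seed; all random streams are derived from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_tf = 100,
                       n_animals_per_state = 6,
                       n_tissues = 5,
                       n_libraries = NULL,
                       var_gene = 1.0,
                       var_gapt = 0.5,
                       var_resid = 0.1,
                       library_sd = 0.1,
                       prop_de = 0.05,
                       de_effect = 2.0,
                       n_planted_regulators = 0,
                       r_pre = 0.95,
                       wiring_shift = 1.0,
                       mean_log_expr = 5.0,
                       seed = 1L) {
  n_combos <- 2L * n_animals_per_state * n_tissues
  if (is.null(n_libraries)) {
    # default world: 72 libraries over the 12 x 5 = 60 combos
    n_libraries <- if (n_animals_per_state == 6L && n_tissues == 5L) 72L else n_combos
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_tf = as.integer(n_tf),
    n_animals_per_state = as.integer(n_animals_per_state),
    n_tissues = as.integer(n_tissues), n_libraries = as.integer(n_libraries),
    var_gene = var_gene, var_gapt = var_gapt, var_resid = var_resid,
    library_sd = library_sd, prop_de = prop_de, de_effect = de_effect,
    n_planted_regulators = as.integer(n_planted_regulators),
    r_pre = r_pre, wiring_shift = wiring_shift,
    mean_log_expr = mean_log_expr, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_tf >= 0L, cfg$n_tf <= cfg$n_genes,
            cfg$n_planted_regulators <= cfg$n_tf,
            cfg$n_animals_per_state >= 1L, cfg$n_tissues >= 1L)
  if (any(c(cfg$var_gene, cfg$var_gapt, cfg$var_resid) < 0))
    stop("variance components must be >= 0")
  if (cfg$prop_de < 0 || cfg$prop_de > 1) stop("prop_de must lie in [0, 1]")
  if (cfg$wiring_shift < 0 || cfg$wiring_shift > 2)
    stop("wiring_shift must lie in [0, 2]")
  if (abs(cfg$r_pre) > 1) stop("r_pre must lie in [-1, 1]")
  n_combos <- 2L * cfg$n_animals_per_state * cfg$n_tissues
  if (cfg$n_libraries < n_combos)
    stop("n_libraries (", cfg$n_libraries, ") must be >= animals x tissues (",
         n_combos, ")")
  n_de <- round(cfg$prop_de * cfg$n_genes)
  if (n_de + cfg$n_tf > cfg$n_genes)
    stop("DE genes (", n_de, ") and TFs (", cfg$n_tf,
         ") overlap: need prop_de * n_genes + n_tf <= n_genes")
  if (cfg$n_planted_regulators > 0) {
    # post-state correlation must be reachable without clamping, else the
    # planted wiring change would be ambiguous
    r_dn <- cfg$r_pre - cfg$wiring_shift
    r_up <- cfg$r_pre + cfg$wiring_shift
    if (r_dn < -1 && r_up > 1)
      stop("wiring_shift ", cfg$wiring_shift, " unachievable from r_pre ",
           cfg$r_pre, ": both shifted correlations leave [-1, 1]")
    if (n_de < cfg$n_planted_regulators)
      stop("need at least one DE target per planted regulator")
  }
  invisible(cfg)
}

# stream offsets of the master seed; documented splitting scheme so that
# every sub-draw is reproducible independently of vector lengths elsewhere
.sim_streams <- c(lengths = 101L, libsize = 202L, library = 303L,
                  gene = 404L, gapt = 505L, resid = 606L)

sim_seed <- function(cfg, stream) {
  (cfg$seed + .sim_streams[[stream]]) %% .Machine$integer.max
}

#' Simulate a two-state multi-tissue RNA-seq experiment
#'
#' Draws log2-RPKM expression under the additive mixed model described in
#' [sim_config()], plants DE genes and differentially wired regulators,
#' and back-computes integer read counts by inverting the RPKM formula
#' (rounding half to even) with log-uniform gene lengths (0.2-20 kb) and
#' library sizes (40-80 million mapped reads).
#'
#' @param cfg a [sim_config()] object.
#' @return a list of class `sim_experiment` with elements
#'   * `counts`: a [count_matrix()] (genes x libraries),
#'   * `design`: the sample design data frame (sample_id, animal_id,
#'     state, tissue, library_id, mapped_reads_millions),
#'   * `tf_list`: character vector of TF gene ids,
#'   * `truth`: ground truth (DE genes with signed effects, regulators
#'     with their targets and wiring change, variance components, and the
#'     latent log2 expression matrix before count rounding).
#' @export
simulate_experiment <- function(cfg) {
  validate_sim_config(cfg)
  n_animals <- 2L * cfg$n_animals_per_state
  n_combos <- n_animals * cfg$n_tissues

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  tf_ids <- if (cfg$n_tf > 0) gene_ids[(cfg$n_genes - cfg$n_tf + 1L):cfg$n_genes] else character()
  n_de <- round(cfg$prop_de * cfg$n_genes)
  de_ids <- gene_ids[seq_len(n_de)]

  animal_ids <- sprintf("A%02d", seq_len(n_animals))
  states <- rep(c("pre", "post"), each = cfg$n_animals_per_state)
  names(states) <- animal_ids
  tissue_ids <- if (cfg$n_tissues == 5L) {
    c("liver", "hypothalamus", "pituitary", "ovary", "uterus")
  } else sprintf("tissue%02d", seq_len(cfg$n_tissues))

  # combos: animal x tissue; libraries assigned one per combo, surplus
  # round-robin as replicate libraries of the first combos
  combos <- expand.grid(animal_id = animal_ids, tissue = tissue_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- combos[order(combos$tissue, combos$animal_id), , drop = FALSE]
  rownames(combos) <- NULL
  extra <- cfg$n_libraries - n_combos
  combo_of_lib <- c(seq_len(n_combos), seq_len(n_combos)[seq_len(extra)])
  design <- data.frame(
    sample_id = sprintf("S%03d", seq_along(combo_of_lib)),
    animal_id = combos$animal_id[combo_of_lib],
    state = states[combos$animal_id[combo_of_lib]],
    tissue = combos$tissue[combo_of_lib],
    library_id = sprintf("L%03d", seq_along(combo_of_lib)),
    stringsAsFactors = FALSE
  )
  rownames(design) <- NULL

  set.seed(sim_seed(cfg, "lengths"))
  exon_length_kb <- exp(runif(cfg$n_genes, log(0.2), log(20)))
  set.seed(sim_seed(cfg, "libsize"))
  mapped_reads_millions <- exp(runif(cfg$n_libraries, log(40), log(80)))
  design$mapped_reads_millions <- mapped_reads_millions

  set.seed(sim_seed(cfg, "library"))
  lib_eff <- rnorm(cfg$n_libraries, 0, cfg$library_sd)
  set.seed(sim_seed(cfg, "gene"))
  gene_eff <- rnorm(cfg$n_genes, 0, sqrt(cfg$var_gene))

  # interaction effects on unit scale first so regulator-target wiring can
  # be planted as exact latent correlations, then scaled by sqrt(var_gapt)
  set.seed(sim_seed(cfg, "gapt"))
  u <- matrix(rnorm(cfg$n_genes * n_combos), cfg$n_genes, n_combos,
              dimnames = list(gene_ids, NULL))
  regulators <- character(0)
  reg_targets <- list()
  r_post <- cfg$r_pre
  if (cfg$n_planted_regulators > 0) {
    r_post <- cfg$r_pre - cfg$wiring_shift
    if (r_post < -1) r_post <- cfg$r_pre + cfg$wiring_shift
    regulators <- tf_ids[seq_len(cfg$n_planted_regulators)]
    block <- rep(seq_len(cfg$n_planted_regulators), length.out = n_de)
    combo_state <- states[combos$animal_id]
    r_combo <- ifelse(combo_state == "pre", cfg$r_pre, r_post)
    # combos of one tissue in one state form a group of exchangeable
    # animals; wiring is planted as the exact empirical correlation
    # within each group so the realized (not just expected) regulator-
    # target correlation equals r_pre / r_post at the latent level.
    # With no wiring change the states are merged so that pooled
    # (both-state) correlations are exact as well.
    group <- if (r_post == cfg$r_pre) combos$tissue else
      paste(combo_state, combos$tissue, sep = "|")
    std_within <- function(v, g) {
      stats::ave(v, g, FUN = function(x) {
        s <- stats::sd(x)
        if (s == 0) x * 0 else (x - mean(x)) / s
      })
    }
    for (i in seq_len(cfg$n_planted_regulators)) {
      tgt <- de_ids[block == i]
      reg_targets[[regulators[i]]] <- tgt
      z_std <- std_within(u[regulators[i], ], group)
      for (g in tgt) {
        # residualize the target's own latent against z within each
        # group, then restandardize, so cor(target, z | group) is exact
        eps <- u[g, ]
        for (gr in unique(group)) {
          idx <- group == gr
          zi <- z_std[idx]
          ei <- eps[idx] - mean(eps[idx])
          if (sum(zi^2) > 0) ei <- ei - sum(ei * zi) / sum(zi^2) * zi
          s <- stats::sd(ei)
          eps[idx] <- if (s == 0) ei else ei / s
        }
        u[g, ] <- r_combo * z_std + sqrt(1 - r_combo^2) * eps
      }
    }
  }
  gapt <- sqrt(cfg$var_gapt) * u
  if (n_de > 0) {
    post_combo <- states[combos$animal_id] == "post"
    gapt[de_ids, post_combo] <- gapt[de_ids, post_combo] + cfg$de_effect
  }

  set.seed(sim_seed(cfg, "resid"))
  resid <- matrix(rnorm(cfg$n_genes * cfg$n_libraries, 0, sqrt(cfg$var_resid)),
                  cfg$n_genes, cfg$n_libraries)

  y <- cfg$mean_log_expr +
    matrix(lib_eff, cfg$n_genes, cfg$n_libraries, byrow = TRUE) +
    gene_eff + gapt[, combo_of_lib, drop = FALSE] + resid
  dimnames(y) <- list(gene_ids, design$sample_id)

  rpkm <- 2^y
  counts <- round(rpkm *
                    matrix(mapped_reads_millions, cfg$n_genes, cfg$n_libraries,
                           byrow = TRUE) *
                    exon_length_kb)  # round() is half-to-even in R
  storage.mode(counts) <- "double"
  dimnames(counts) <- dimnames(y)

  cm <- count_matrix(counts, exon_length_kb = setNames(exon_length_kb, gene_ids),
                     mapped_reads_millions = setNames(mapped_reads_millions,
                                                      design$sample_id))
  truth <- list(
    de_genes = data.frame(gene_id = gene_ids,
                          effect = ifelse(gene_ids %in% de_ids, cfg$de_effect, 0),
                          stringsAsFactors = FALSE),
    regulators = regulators,
    regulator_targets = reg_targets,
    r_pre = cfg$r_pre, r_post = r_post,
    variance_components = c(var_gene = cfg$var_gene, var_gapt = cfg$var_gapt,
                            var_resid = cfg$var_resid),
    log_expr = y
  )
  structure(list(counts = cm, design = design, tf_list = tf_ids,
                 truth = truth, config = cfg),
            class = "sim_experiment")
}

#' Write a simulated experiment as a plain-text fixture bundle
#'
#' Emits the four tab-delimited files consumed by the pipeline readers:
#' `counts.tsv` (gene_id, exon_length_kb, one column per sample),
#' `design.tsv` (sample_id, animal_id, state, tissue, library_id,
#' mapped_reads_millions), `tf_list.txt` (one id per line) and
#' `ground_truth.tsv` (gene_id, planted effect, regulator flag).
#'
#' @param sim a `sim_experiment` from [simulate_experiment()].
#' @param dir output directory, created if missing.
#' @return invisibly, named character vector of the four file paths.
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (nrow(sim$counts$counts) == 0L) stop("empty gene set: nothing to write")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             tf_list = file.path(dir, "tf_list.txt"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_counts(sim$counts, paths[["counts"]])
  write_design(sim$design, paths[["design"]])
  writeLines(sim$tf_list, paths[["tf_list"]])
  gt <- sim$truth$de_genes
  gt$is_regulator <- gt$gene_id %in% sim$truth$regulators
  write_tsv(gt, paths[["ground_truth"]])
  invisible(paths)
}
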