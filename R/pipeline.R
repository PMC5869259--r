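#' Pipeline configuration
#'
#' Collects paths, thresholds and solver settings for [run_pipeline()].
#' Defaults follow the classical analysis: expressed-gene threshold
#' RPKM >= 0.2, nominal DE p < 0.05, top genes at |FC| >= 3 and
#' p <= 0.01, RIF significance at |z| >= 1.96.
#'
#' @param counts,design,tf_list input file paths (see [read_counts()],
#'   [read_design()], [read_tf_list()]).
#' @param out_dir output directory.
#' @param tissue tissue of interest analyzed downstream of the joint fit.
#' @param rpkm_expressed expressed-gene mean-RPKM threshold.
#' @param de_p nominal DE p-value threshold.
#' @param top_fc,top_p top-gene thresholds.
#' @param rif_z RIF |z| significance threshold.
#' @param log_offset offset of the log2 transform.
#' @param tolerance,max_iter EM-REML solver settings.
#' @param extra_nodes optional extra network nodes.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic given its inputs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, tf_list, out_dir,
                            tissue = "liver", rpkm_expressed = 0.2,
                            de_p = 0.05, top_fc = 3, top_p = 0.01,
                            rif_z = 1.96, log_offset = 1,
                            tolerance = 1e-6, max_iter = 500L,
                            extra_nodes = character(), seed = 1L) {
  cfg <- list(counts = counts, design = design, tf_list = tf_list,
              out_dir = out_dir, tissue = tissue,
              rpkm_expressed = rpkm_expressed, de_p = de_p,
              top_fc = top_fc, top_p = top_p, rif_z = rif_z,
              log_offset = log_offset, tolerance = tolerance,
              max_iter = as.integer(max_iter), extra_nodes = extra_nodes,
              seed = as.integer(seed))
  if (any(unlist(cfg[c("rpkm_expressed", "de_p", "top_fc", "top_p",
                       "rif_z", "log_offset", "tolerance")]) <= 0) &&
      cfg$rpkm_expressed < 0)
    stop("thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes normalize -> differential expression -> RIF -> PCIT network
#' -> trio selection, writing every stage's tables under
#' `cfg$out_dir` together with a YAML run manifest (stage row counts,
#' resolved configuration, wall time). Re-running with identical inputs
#' and configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stages <- list()

  # stage 1: normalization
  design <- read_design(cfg$design)
  cm <- read_counts(cfg$counts, design)
  tf_all <- read_tf_list(cfg$tf_list)
  rpkm <- compute_rpkm(cm)
  expressed <- filter_expressed(rpkm, cfg$rpkm_expressed)
  y <- log2_transform(rpkm[expressed$retained, , drop = FALSE],
                      cfg$log_offset)
  fit <- fit_mixed_model(y, design, tol = cfg$tolerance,
                         max_iter = cfg$max_iter)
  norm <- extract_normalized(fit, design, cfg$tissue)
  write_tsv(data.frame(gene_id = rownames(norm$values), norm$values,
                       check.names = FALSE), out("normalized.tsv"))
  write_tsv(data.frame(gene_id = rownames(norm$values),
                       mean_pre = unname(norm$mean_pre),
                       mean_post = unname(norm$mean_post)),
            out("state_means.tsv"))
  yaml::write_yaml(list(var_gene = fit$var_gene, var_gapt = fit$var_gapt,
                        var_resid = fit$var_resid, mu = fit$mu,
                        converged = fit$converged,
                        n_iterations = fit$n_iterations),
                   out("fit_report.yaml"))
  stages$normalize <- list(genes_in = nrow(rpkm),
                           genes_expressed = length(expressed$retained),
                           converged = fit$converged)

  # stage 2: differential expression
  de <- build_de_table(norm, p_threshold = cfg$de_p, fc_top = cfg$top_fc,
                       p_top = cfg$top_p)
  write_tsv(de, out("de_table.tsv"))
  top <- de[de$is_top, , drop = FALSE]
  top <- top[order(-top$fc), , drop = FALSE]
  write_tsv(top, out("top_genes.tsv"))
  write_tsv(volcano_table(de), out("volcano.tsv"))
  stages$de <- list(n_de = sum(de$is_de), n_up = attr(de, "n_up"),
                    n_down = attr(de, "n_down"), n_top = nrow(top))

  # stage 3: RIF
  tf_expressed <- intersect(tf_all, rownames(norm$values))
  rif <- rif_analysis(norm, tf_expressed, de, z_threshold = cfg$rif_z)
  write_tsv(rif, out("rif_table.tsv"))
  key_tfs <- suppressMessages(select_key_regulators(rif, cfg$rif_z))
  # trio selection needs >= 3 TFs; on small inputs fewer may reach the z
  # threshold, so fall back to the top-|z| TFs and record the fallback
  tf_fallback <- length(key_tfs) < 3L
  if (tf_fallback) {
    ord <- order(-pmax(abs(rif$z1), abs(rif$z2)))
    key_tfs <- rif$tf_id[ord][seq_len(min(3L, nrow(rif)))]
    warning("fewer than 3 TFs reached |z| >= ", cfg$rif_z,
            "; using the ", length(key_tfs), " top-ranked TFs instead")
  }
  stages$rif <- list(tf_in = length(tf_all), tf_expressed = length(tf_expressed),
                     tf_significant = sum(rif$significant),
                     tf_used = length(key_tfs), tf_fallback = tf_fallback)

  # stage 4: PCIT network
  de_ids <- de$gene_id[de$is_de]
  net <- build_network(norm, de_ids, key_tfs, cfg$extra_nodes)
  write_network(net, out("network_edges.tsv"), out("network_nodes.tsv"),
                out("network.sif"))
  stages$network <- list(nodes = nrow(net$nodes), edges = nrow(net$edges))

  # stage 5: trio selection
  tf_in_net <- intersect(key_tfs, net$nodes$id)
  bt <- best_trio(net, tf_in_net)
  write_tsv(bt$table, out("trio_table.tsv"))
  write_network(bt$subnetwork, out("subnetwork_edges.tsv"), NULL,
                out("subnetwork.sif"))
  stages$trio <- list(tf_in_network = length(tf_in_net),
                      trios_enumerated = nrow(bt$table),
                      best = unname(bt$best$triplet),
                      coverage = bt$best$coverage,
                      redundancy = bt$best$redundancy)

  manifest <- list(
    package = "rifnet",
    version = as.character(utils::packageVersion("rifnet")),
    config = unclass(cfg),
    stages = stages,
    n_stages_completed = length(stages),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  yaml::write_yaml(unclass(cfg), out("config_resolved.yaml"))
  invisible(manifest)
}
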