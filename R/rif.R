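#' Within-state TF-to-DE-gene correlations
#'
#' Pearson correlation between each transcription factor and each DE
#' gene across the animals of each physiological state separately.
#' Zero-variance vectors yield r = 0 and are flagged.
#'
#' @param norm a `normalized_expression` from [extract_normalized()].
#' @param tf_ids transcription-factor gene ids (rows of the matrix).
#' @param de_ids DE gene ids (rows of the matrix).
#' @return list with `r1` (pre) and `r2` (post) TF x DE correlation
#'   matrices and `degenerate`, a logical matrix marking pairs where a
#'   zero-variance vector forced r = 0.
#' @export
condition_correlations <- function(norm, tf_ids, de_ids) {
  stopifnot(inherits(norm, "normalized_expression"))
  missing <- setdiff(c(tf_ids, de_ids), rownames(norm$values))
  if (length(missing))
    stop("id absent from normalized matrix: ", missing[1L])
  pre <- names(norm$animal_state)[norm$animal_state == "pre"]
  post <- names(norm$animal_state)[norm$animal_state == "post"]
  if (length(pre) < 3L || length(post) < 3L)
    stop("need at least 3 animals per state for correlations")
  one_state <- function(animals) {
    tf <- t(norm$values[tf_ids, animals, drop = FALSE])
    de <- t(norm$values[de_ids, animals, drop = FALSE])
    zv_tf <- apply(tf, 2L, stats::sd) == 0
    zv_de <- apply(de, 2L, stats::sd) == 0
    r <- matrix(0, length(tf_ids), length(de_ids),
                dimnames = list(tf_ids, de_ids))
    if (any(!zv_tf) && any(!zv_de))
      r[!zv_tf, !zv_de] <- stats::cor(tf[, !zv_tf, drop = FALSE],
                                      de[, !zv_de, drop = FALSE])
    list(r = r, degenerate = outer(zv_tf, zv_de, `|`))
  }
  s1 <- one_state(pre)
  s2 <- one_state(post)
  list(r1 = s1$r, r2 = s2$r, degenerate = s1$degenerate | s2$degenerate)
}

#' Regulatory impact factor scores
#'
#' For DE gene j with mean normalized expression `e1_j` (pre) and `e2_j`
#' (post), average abundance `a_j = (e1_j + e2_j)/2`, differential
#' expression `d_j = e2_j - e1_j` and phenotypic impact factor
#' `PIF_j = a_j * d_j`, and TF-to-gene correlations `r1_ij` (pre) and
#' `r2_ij` (post) with differential wiring `dw_ij = r1_ij - r2_ij`:
#' \deqn{RIF1_i = \frac{1}{n_{de}} \sum_j PIF_j \, dw_{ij}^2}
#' \deqn{RIF2_i = \frac{1}{n_{de}} \sum_j (e1_j r1_{ij})^2 - (e2_j r2_{ij})^2}
#' Each score is z-standardized across TFs; a TF is significant when
#' either |z| reaches the threshold (default 1.96, two-sided 5%).
#'
#' @param e1,e2 named numeric vectors of per-state DE-gene means.
#' @param r1,r2 TF x DE correlation matrices ([condition_correlations()]).
#' @param z_threshold significance threshold on |z| (default 1.96).
#' @param standardize if `FALSE`, return raw scores with `z1`, `z2` and
#'   `significant` set to `NA` (useful when the scores have no spread).
#' @return data frame of class `rif_table`: `tf_id`, `rif1`, `rif2`,
#'   `z1`, `z2`, `significant`.
#' @export
compute_rif <- function(e1, e2, r1, r2, z_threshold = 1.96,
                        standardize = TRUE) {
  stopifnot(is.matrix(r1), is.matrix(r2), all(dim(r1) == dim(r2)),
            length(e1) == ncol(r1), length(e2) == ncol(r1))
  if (nrow(r1) < 2L) stop("need at least 2 TFs to standardize RIF scores")
  if (ncol(r1) < 1L) stop("need at least 1 DE gene")
  a <- (e1 + e2) / 2
  d <- e2 - e1
  pif <- a * d
  dw <- r1 - r2
  rif1 <- as.vector(dw^2 %*% pif) / ncol(r1)
  rif2 <- rowMeans(sweep(r1^2, 2L, e1^2, `*`) - sweep(r2^2, 2L, e2^2, `*`))
  if (standardize) {
    zstd <- function(x) {
      s <- stats::sd(x)
      if (s == 0) stop("RIF score has zero spread across TFs; ",
                       "z-scores undefined (degenerate input)")
      (x - mean(x)) / s
    }
    z1 <- zstd(rif1)
    z2 <- zstd(rif2)
    significant <- abs(z1) >= z_threshold | abs(z2) >= z_threshold
  } else {
    z1 <- z2 <- rep(NA_real_, length(rif1))
    significant <- NA
  }
  out <- data.frame(tf_id = rownames(r1), rif1 = rif1, rif2 = rif2,
                    z1 = z1, z2 = z2, significant = significant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rif_table", "data.frame")
  out
}

#' Run the full RIF analysis on normalized expression
#'
#' Convenience wrapper: computes within-state correlations and the RIF
#' table for the given TF and DE gene sets.
#'
#' @inheritParams condition_correlations
#' @param de a `de_table`; its DE genes (`is_de`) are the targets.
#' @param z_threshold significance threshold on |z|.
#' @return a `rif_table` (see [compute_rif()]).
#' @export
rif_analysis <- function(norm, tf_ids, de, z_threshold = 1.96) {
  de_ids <- de$gene_id[de$is_de]
  if (length(de_ids) == 0L) stop("no DE genes: RIF targets undefined")
  tf_ids <- intersect(tf_ids, rownames(norm$values))
  if (length(tf_ids) < 2L) stop("need at least 2 expressed TFs")
  cc <- condition_correlations(norm, tf_ids, de_ids)
  e1 <- norm$mean_pre[de_ids]
  e2 <- norm$mean_post[de_ids]
  compute_rif(e1, e2, cc$r1, cc$r2, z_threshold = z_threshold)
}

#' Select significant (key regulator) TFs
#'
#' @param rif a `rif_table`.
#' @param threshold |z| threshold (default 1.96).
#' @return character vector of significant TF ids.
#' @export
select_key_regulators <- function(rif, threshold = 1.96) {
  sel <- rif$tf_id[abs(rif$z1) >= threshold | abs(rif$z2) >= threshold]
  message(length(sel), " of ", nrow(rif), " TFs flagged as key regulators")
  sel
}
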