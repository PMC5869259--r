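#' Two-sample pooled-variance t-test for one gene
#'
#' Fold change is the post minus pre difference of means on the
#' normalized (log2) scale; the test is the classical pooled-variance
#' Student t with `n1 + n2 - 2` degrees of freedom, two-sided.
#'
#' @param values_pre numeric vector of per-animal normalized values, pre.
#' @param values_post numeric vector, post.
#' @return list with `fc`, `t_stat`, `p_value`.
#' @export
test_gene <- function(values_pre, values_post) {
  n1 <- length(values_pre)
  n2 <- length(values_post)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per state")
  fc <- mean(values_post) - mean(values_pre)
  sp2 <- ((n1 - 1) * stats::var(values_pre) +
            (n2 - 1) * stats::var(values_post)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    if (fc == 0) return(list(fc = 0, t_stat = 0, p_value = 1))
    warning("zero pooled variance with unequal means: p = 0")
    return(list(fc = fc, t_stat = sign(fc) * Inf, p_value = 0))
  }
  t_stat <- fc / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  list(fc = fc, t_stat = t_stat, p_value = p)
}

#' Build the differential-expression table
#'
#' One row per gene: state means, fold change (post minus pre on the
#' normalized scale), pooled t statistic, two-sided p-value, DE flag at
#' `p_threshold`, top-gene flag at `|fc| >= fc_top & p <= p_top`, and
#' direction of change.
#'
#' @param norm a `normalized_expression` from [extract_normalized()].
#' @param p_threshold nominal DE p-value cutoff (default 0.05).
#' @param fc_top absolute fold-change cutoff for top genes (default 3).
#' @param p_top p-value cutoff for top genes (default 0.01).
#' @return data frame of class `de_table`, sorted as the input genes;
#'   attribute `n_up` / `n_down` carry the DE direction counts.
#' @export
build_de_table <- function(norm, p_threshold = 0.05, fc_top = 3,
                           p_top = 0.01) {
  stopifnot(inherits(norm, "normalized_expression"))
  pre <- names(norm$animal_state)[norm$animal_state == "pre"]
  post <- names(norm$animal_state)[norm$animal_state == "post"]
  xp <- norm$values[, pre, drop = FALSE]
  xq <- norm$values[, post, drop = FALSE]
  res <- lapply(seq_len(nrow(norm$values)), function(j)
    test_gene(xp[j, ], xq[j, ]))
  de <- data.frame(
    gene_id = rownames(norm$values),
    mean_pre = unname(norm$mean_pre),
    mean_post = unname(norm$mean_post),
    fc = vapply(res, `[[`, numeric(1), "fc"),
    t_stat = vapply(res, `[[`, numeric(1), "t_stat"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  de <- flag_de_table(de, p_threshold = p_threshold, fc_top = fc_top,
                      p_top = p_top)
  attr(de, "n_up") <- sum(de$is_de & de$direction == "up")
  attr(de, "n_down") <- sum(de$is_de & de$direction == "down")
  class(de) <- c("de_table", "data.frame")
  de
}

#' Flag DE and top genes on a fold-change / p-value table
#'
#' Applies the nominal DE rule (`p < p_threshold`) and the top-gene rule
#' (`|fc| >= fc_top` and `p <= p_top`) to any table carrying `fc` and
#' `p_value` columns, e.g. one assembled from published state means.
#'
#' @param de data frame with columns `fc` and `p_value`.
#' @inheritParams build_de_table
#' @return the input with `is_de`, `is_top` and `direction` columns.
#' @export
flag_de_table <- function(de, p_threshold = 0.05, fc_top = 3, p_top = 0.01) {
  stopifnot(all(c("fc", "p_value") %in% names(de)))
  de$is_de <- de$p_value < p_threshold
  de$is_top <- abs(de$fc) >= fc_top & de$p_value <= p_top
  de$direction <- ifelse(de$fc > 0, "up", "down")
  de
}

#' Volcano-plot table
#'
#' x = fold change, y = -log10(p), flag = DE status. Zero p-values are
#' capped at `p_cap` before the log so the ordinate stays finite.
#'
#' @param de a `de_table`.
#' @param p_cap smallest representable p-value (default 1e-300).
#' @return data frame with `gene_id`, `fc`, `neg_log10_p`, `is_de`.
#' @export
volcano_table <- function(de, p_cap = 1e-300) {
  stopifnot(nrow(de) > 0L)
  data.frame(gene_id = de$gene_id, fc = de$fc,
             neg_log10_p = -log10(pmax(de$p_value, p_cap)),
             is_de = de$is_de, stringsAsFactors = FALSE)
}
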