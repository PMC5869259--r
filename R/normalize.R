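#' Compute RPKM from read counts
#'
#' Reads per kilobase of exon per million mapped reads:
#' `RPKM[j, s] = counts[j, s] / (mapped_reads_millions[s] * exon_length_kb[j])`.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of RPKM values, same dimnames as the counts.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  len <- cm$exon_length_kb
  mm <- cm$mapped_reads_millions
  if (any(len <= 0)) stop("non-positive exon length for gene: ",
                          names(len)[len <= 0][1L])
  if (any(mm <= 0)) stop("non-positive mapped reads for sample: ",
                         names(mm)[mm <= 0][1L])
  cm$counts / outer(len, mm)
}

#' Filter expressed genes by mean RPKM
#'
#' A gene is called expressed when its mean RPKM across all samples is at
#' least `threshold` (inclusive boundary).
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param threshold non-negative expression threshold (default 0.2).
#' @return list with `retained` (character vector of gene ids) and
#'   `report` (data frame: gene_id, mean_rpkm, retained).
#' @export
filter_expressed <- function(rpkm, threshold = 0.2) {
  stopifnot(is.matrix(rpkm), threshold >= 0)
  m <- rowMeans(rpkm)
  keep <- m >= threshold
  list(retained = rownames(rpkm)[keep],
       report = data.frame(gene_id = rownames(rpkm), mean_rpkm = unname(m),
                           retained = unname(keep), stringsAsFactors = FALSE))
}

#' Log2-transform RPKM with a positive offset
#'
#' `y = log2(rpkm + offset)`. The default offset of 1 keeps zero RPKM at
#' exactly 0 and is monotone.
#'
#' @param rpkm non-negative RPKM matrix or vector.
#' @param offset positive pseudo-value added before the log.
#' @return matrix or vector of log2 values.
#' @export
log2_transform <- function(rpkm, offset = 1) {
  if (offset <= 0) stop("offset must be > 0")
  if (any(rpkm < 0)) stop("negative RPKM values are not allowed")
  log2(rpkm + offset)
}

# Build the fixed-effect design (intercept + sum-to-zero library
# contrasts) and the sample -> animal:tissue combo incidence.
build_design_matrices <- function(design) {
  validate_design(design)
  lib <- if (is.factor(design$library_id)) design$library_id else
    factor(design$library_id)
  empty <- setdiff(levels(lib), unique(as.character(lib)))
  if (length(empty))
    stop("singular design: library spans no samples: ", empty[1L])
  n_lib <- nlevels(lib)
  X <- if (n_lib > 1L) {
    stats::model.matrix(~lib, contrasts.arg = list(lib = "contr.sum"))
  } else {
    matrix(1, nrow(design), 1L)
  }
  combo_key <- paste(design$animal_id, design$tissue, sep = "|")
  combo <- factor(combo_key, levels = unique(combo_key))
  A <- stats::model.matrix(~ 0 + combo)
  combo_map <- unique(data.frame(combo_key = combo_key,
                                 animal_id = design$animal_id,
                                 state = design$state,
                                 tissue = design$tissue,
                                 stringsAsFactors = FALSE))
  combo_map <- combo_map[match(levels(combo), combo_map$combo_key), ,
                         drop = FALSE]
  rownames(combo_map) <- NULL
  list(X = X, A = A, lib = lib, combo_map = combo_map)
}

#' Fit the additive mixed model to log-scale expression
#'
#' Fits `Y = mu + L_i + G_j + GAPT_jkpt + e` by exact REML, where `L_i`
#' is the fixed effect of library `i`, `G_j` the random gene effect
#' (variance `var_gene`) and `GAPT_jkpt` the random gene x animal x state
#' x tissue effect (variance `var_gapt`). Because every gene is observed
#' in every sample and genes are conditionally independent, the
#' per-gene covariance collapses to the `n_samples x n_samples` matrix
#' `Sigma = var_gene J + var_gapt A A' + var_resid I`, and EM-REML
#' iterates on that small matrix; solutions are the exact BLUE/BLUP of
#' the full Henderson system.
#'
#' Identifiability: fixed library effects are constrained to sum to
#' zero; the gene + interaction solutions used downstream are invariant
#' to this choice. Separating `var_gapt` from `var_resid` requires
#' replicate libraries within at least one animal x tissue combination;
#' without replication a warning is issued and the two are confounded.
#'
#' @param y numeric matrix of log2 expression, genes x samples.
#' @param design sample design data frame ([read_design()] columns).
#' @param tol convergence tolerance on the relative change of each
#'   variance component (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class `mixed_model_fit` with components `mu`,
#'   `library_effects`, `gene_effects`, `interaction_effects` (genes x
#'   combos), `var_gene`, `var_gapt`, `var_resid`, `converged`,
#'   `n_iterations`, and the `combo_map` used downstream.
#' @export
fit_mixed_model <- function(y, design, tol = 1e-6, max_iter = 500L) {
  stopifnot(is.matrix(y), nrow(y) >= 2L)
  if (!all(colnames(y) == design$sample_id))
    y <- y[, design$sample_id, drop = FALSE]
  n_per_state <- table(unique(design[, c("animal_id", "state")])$state)
  if (length(n_per_state) < 2L || any(n_per_state < 2L))
    stop("need at least 2 animals in each state")
  dm <- build_design_matrices(design)
  X <- dm$X
  A <- dm$A
  n_s <- ncol(y)
  n_g <- nrow(y)
  n_c <- ncol(A)
  if (max(colSums(A)) < 2L)
    warning("no replicate libraries within any animal x tissue combination: ",
            "var_gapt and var_resid are confounded")

  Yt <- t(y)                               # samples x genes
  ybar <- rowMeans(Yt)

  # constant data: nothing to estimate
  if (stats::var(as.vector(y)) < 1e-24) {
    beta <- qr.coef(qr(X), ybar)
    return(new_mixed_model_fit(beta, X, dm, n_g,
                               gene_effects = setNames(numeric(n_g), rownames(y)),
                               interaction_effects =
                                 matrix(0, n_g, n_c,
                                        dimnames = list(rownames(y),
                                                        dm$combo_map$combo_key)),
                               vc = c(0, 0, 0), converged = TRUE, iter = 0L))
  }

  AAt <- tcrossprod(A)
  J <- matrix(1, n_s, n_s)
  # moment-based starting values
  gm <- rowMeans(y)
  resid0 <- y - gm - rep(colMeans(y - gm), each = n_g)
  v0 <- stats::var(as.vector(resid0))
  vg <- max(stats::var(gm), 1e-4)
  vw <- max(v0 / 2, 1e-4)
  ve <- max(v0 / 2, 1e-4)

  floor_ve <- 1e-8
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Sigma <- vg * J + vw * AAt + diag(max(ve, floor_ve), n_s)
    W <- solve(Sigma)
    WX <- W %*% X
    XtWX <- crossprod(X, WX)
    XtWX_inv <- solve(XtWX)
    beta <- XtWX_inv %*% crossprod(WX, ybar)
    R <- Yt - as.vector(X %*% beta)        # samples x genes
    WR <- W %*% R

    one_t_WR <- colSums(WR)                # 1'W r_j per gene
    AtWR <- crossprod(A, WR)               # combos x genes
    g_hat <- vg * one_t_WR
    w_hat <- vw * AtWR
    e_hat <- ve * WR

    w1 <- W %*% rep(1, n_s)
    XtW1 <- crossprod(X, w1)
    tr_g <- n_g * sum(w1) - drop(crossprod(XtW1, XtWX_inv %*% XtW1))
    WA <- W %*% A
    XtWA <- crossprod(X, WA)
    tr_w <- n_g * sum(A * WA) - sum(XtWA * (XtWX_inv %*% XtWA))
    XtW2X <- crossprod(WX)
    tr_e <- n_g * sum(diag(W)) - sum(XtWX_inv * XtW2X)

    vg_new <- if (vg > 0) (sum(g_hat^2) + vg * n_g - vg^2 * tr_g) / n_g else 0
    vw_new <- if (vw > 0)
      (sum(w_hat^2) + vw * n_g * n_c - vw^2 * tr_w) / (n_g * n_c) else 0
    ve_new <- (sum(e_hat^2) + ve * n_g * n_s - ve^2 * tr_e) / (n_g * n_s)
    vg_new <- max(vg_new, 0); vw_new <- max(vw_new, 0); ve_new <- max(ve_new, 0)

    denom <- pmax(c(vg, vw, ve), 1e-12)
    delta <- max(abs(c(vg_new, vw_new, ve_new) - c(vg, vw, ve)) / denom)
    vg <- vg_new; vw <- vw_new; ve <- ve_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter, " iterations")

  # final solutions at the converged variance components
  Sigma <- vg * J + vw * AAt + diag(max(ve, floor_ve), n_s)
  W <- solve(Sigma)
  WX <- W %*% X
  XtWX_inv <- solve(crossprod(X, WX))
  beta <- XtWX_inv %*% crossprod(WX, ybar)
  R <- Yt - as.vector(X %*% beta)
  WR <- W %*% R
  gene_effects <- setNames(vg * colSums(WR), rownames(y))
  interaction_effects <- t(vw * crossprod(A, WR))
  dimnames(interaction_effects) <- list(rownames(y), dm$combo_map$combo_key)

  new_mixed_model_fit(drop(beta), X, dm, n_g, gene_effects,
                      interaction_effects, c(vg, vw, ve), converged, iter)
}

new_mixed_model_fit <- function(beta, X, dm, n_g, gene_effects,
                                interaction_effects, vc, converged, iter) {
  n_lib <- nlevels(dm$lib)
  mu <- beta[1L]
  lib_eff <- if (n_lib > 1L) {
    ce <- stats::contr.sum(n_lib) %*% beta[-1L]
    setNames(drop(ce), levels(dm$lib))
  } else setNames(0, levels(dm$lib))
  structure(list(mu = unname(mu), library_effects = lib_eff,
                 gene_effects = gene_effects,
                 interaction_effects = interaction_effects,
                 var_gene = vc[1L], var_gapt = vc[2L], var_resid = vc[3L],
                 converged = converged, n_iterations = iter,
                 combo_map = dm$combo_map),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("mixed_model_fit:", length(x$gene_effects), "genes,",
      ncol(x$interaction_effects), "animal x tissue combinations\n")
  cat(sprintf("  var_gene = %.4g, var_gapt = %.4g, var_resid = %.4g\n",
              x$var_gene, x$var_gapt, x$var_resid))
  cat("  converged:", x$converged, "after", x$n_iterations, "iterations\n")
  invisible(x)
}

#' Fitted values of a mixed-model fit
#'
#' `mu + L_library + G_gene + GAPT_combo` per gene and sample.
#'
#' @param object a `mixed_model_fit`.
#' @param design the design the model was fitted to.
#' @param ... unused.
#' @return genes x samples matrix.
#' @export
fitted_values <- function(object, design, ...) {
  combo_key <- paste(design$animal_id, design$tissue, sep = "|")
  fe <- object$mu + object$library_effects[design$library_id]
  object$interaction_effects[, combo_key, drop = FALSE] +
    object$gene_effects +
    matrix(fe, length(object$gene_effects), nrow(design), byrow = TRUE)
}

#' Extract normalized expression for one tissue
#'
#' The normalized per-animal value of gene j is the sum of the model
#' solutions `G_j + GAPT_jkpt` for the requested tissue, reported on the
#' abundance scale by adding the grand mean `mu` (library effects sum to
#' zero, so `mu` is the overall log2 level; fold changes, t-tests and
#' correlations are invariant to this shift, while the RIF abundance
#' weights require it). Per-state means are arithmetic means over the
#' animals of each state.
#'
#' @param fit a `mixed_model_fit`.
#' @param design the design the model was fitted to.
#' @param tissue tissue of interest (must appear in the design).
#' @return object of class `normalized_expression`: `values` (genes x
#'   animals matrix), `animal_state` (named character vector),
#'   `mean_pre` / `mean_post` (named numeric vectors), `tissue`.
#' @export
extract_normalized <- function(fit, design, tissue) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  cm <- fit$combo_map
  sel <- cm[cm$tissue == tissue, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("unknown tissue '", tissue, "'; available: ",
         paste(unique(cm$tissue), collapse = ", "))
  x <- fit$mu + fit$interaction_effects[, sel$combo_key, drop = FALSE] +
    fit$gene_effects
  colnames(x) <- sel$animal_id
  states <- setNames(sel$state, sel$animal_id)
  pre <- names(states)[states == "pre"]
  post <- names(states)[states == "post"]
  structure(list(values = x, animal_state = states,
                 mean_pre = rowMeans(x[, pre, drop = FALSE]),
                 mean_post = rowMeans(x[, post, drop = FALSE]),
                 tissue = tissue),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("normalized_expression:", nrow(x$values), "genes x",
      ncol(x$values), "animals, tissue:", x$tissue, "\n")
  invisible(x)
}
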