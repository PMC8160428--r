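#' Correlation-matrix PCA of community-weighted trait means
#'
#' Principal component analysis of the quadrat x variable CWM matrix after
#' standardizing each variable to zero mean and unit variance (PCA on the
#' correlation matrix), computed by singular value decomposition.  Quadrats
#' with any undefined CWM are dropped with a warning rather than imputed.
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param summaries a `community_summary` data.frame (or any data.frame
#'   with `block_id`, `n_level` and `cwm_*` columns).
#' @param variables the CWM variable names to include; defaults to the 23
#'   community trait variables.
#' @return object of class `cwm_pca`: `variable_names`, `loadings`
#'   (variables x components, orthonormal columns), `scores` (quadrats x
#'   components), `variance_explained` (proportions summing to 1), and the
#'   retained `block_id` / `n_level` labels.
#' @export
pca_cwm <- function(summaries, variables = paste0("cwm_", cwm_variables())) {
  miss <- setdiff(variables, names(summaries))
  if (length(miss) > 0)
    stop("summaries lack variable(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(summaries[, variables])
  complete <- !apply(X, 1, anyNA)
  if (!all(complete))
    warning(sprintf("dropping %d quadrat(s) with undefined CWMs",
                    sum(!complete)))
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete quadrats")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero variance in variable(s): ",
         paste(variables[sds == 0], collapse = ", "))

  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(
    variable_names = variables,
    loadings = rot,
    scores = scores,
    variance_explained = pc$sdev^2 / sum(pc$sdev^2),
    block_id = summaries$block_id[complete],
    n_level = summaries$n_level[complete]
  ), class = "cwm_pca")
}

#' @export
print.cwm_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("correlation-matrix PCA: %d variables, %d quadrats\n",
              length(x$variable_names), nrow(x$scores)))
  cat(sprintf("  PC1 %.2f%%, PC2 %.2f%% (first two: %.2f%%)\n",
              100 * ve[1], 100 * ve[2], 100 * sum(ve[1:2])))
  invisible(x)
}
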