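#' Tidy an ANOVA + Tukey result
#'
#' @param x An [anova_tukey()] object.
#' @param ... Unused.
#' @return The pairwise Tukey table joined with the letter display:
#'   one row per group pair (`pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @rdname tidy.anova_tukey
#' @return For `glance()`: a one-row tibble with the ANOVA `statistic`,
#'   `p_value`, degrees of freedom and number of groups.
#' @export
glance.anova_tukey <- function(x, ...) {
  dplyr::mutate(x$anova, n_groups = nrow(x$letters), alpha = x$alpha)
}

#' Tidy a trait PCA
#'
#' @param x A [pca_traits()] object.
#' @param matrix `"scores"`, `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in long form for the requested matrix.
#' @export
tidy.trait_pca <- function(x, matrix = c("scores", "loadings",
                                         "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(component = seq_along(x$var_explained),
                  variance = x$sdev[seq_along(x$var_explained)]^2,
                  var_explained = x$var_explained,
                  cumulative = cumsum(x$var_explained)))
  }
  m <- x[[matrix]]
  df <- as.data.frame(as.table(m))
  names(df) <- c(if (matrix == "scores") "row" else "trait",
                 "component", "value")
  as_tibble(df)
}

#' @rdname tidy.trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         var_explained_total = sum(x$var_explained),
         n_imputed = sum(x$imputed),
         n_dropped = length(x$dropped))
}

#' Tidy a Ward clustering
#'
#' @param x A [ward_cluster()] object.
#' @param ... Unused.
#' @return A tibble of row-cluster memberships (`row`, `cluster`).
#' @export
tidy.ward_cluster <- function(x, ...) {
  tibble(row = names(x$row_clusters),
         cluster = unname(x$row_clusters))
}

#' @rdname tidy.ward_cluster
#' @export
glance.ward_cluster <- function(x, ...) {
  tibble(n_rows = nrow(x$matrix),
         n_row_clusters = length(unique(x$row_clusters)),
         n_col_clusters = if (is.null(x$col_clusters)) NA_integer_
                          else length(unique(x$col_clusters)),
         max_merge_height = max(x$row_hclust$height))
}
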