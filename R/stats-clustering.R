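#' One-way ANOVA with Tukey HSD letters
#'
#' Fits a one-way ANOVA, runs Tukey's honestly-significant-difference
#' test on all group pairs, and summarises the pairwise results as a
#' compact letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @param alpha Significance level for the letter display.
#' @return A list of class `anova_tukey`: `anova` (one-row tibble with
#'   `df_between`, `df_within`, `statistic`, `p_value`), `tukey`
#'   (tibble `pair`, `diff`, `lwr`, `upr`, `p_adj`), `letters` (tibble
#'   `group`, `letter`), `alpha`.
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  v <- data[[value]]; g <- factor(data[[group]])
  keep <- is.finite(v)
  v <- v[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort("group(s) with fewer than 2 observations: ",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  df <- data.frame(v = v, g = g)
  fit <- aov(v ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- tibble(pair = rownames(tk), diff = tk[, "diff"],
                  lwr = tk[, "lwr"], upr = tk[, "upr"],
                  p_adj = tk[, "p adj"])
  letters <- cld_letters(levels(g), pairs, alpha)
  structure(list(
    anova = tibble(df_between = an$Df[1], df_within = an$Df[2],
                   statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1]),
    tukey = pairs, letters = letters, alpha = alpha),
    class = "anova_tukey")
}

# compact letter display by the insert-and-absorb algorithm
cld_letters <- function(groups, pairs, alpha) {
  k <- length(groups)
  # significance matrix
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    gg <- strsplit(pairs$pair[i], "-", fixed = TRUE)[[1]]
    if (length(gg) == 2 && isTRUE(pairs$p_adj[i] < alpha)) {
      sig[gg[1], gg[2]] <- sig[gg[2], gg[1]] <- TRUE
    }
  }
  cols <- list(rep(TRUE, k)) # letter columns: membership vectors
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && sig[i, j]) {
      for (ci in seq_along(cols)) {
        cc <- cols[[ci]]
        if (cc[i] && cc[j]) { # split the offending column
          c1 <- cc; c1[j] <- FALSE
          c2 <- cc; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb duplicates/subsets
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]])) {
          keep[a] <- FALSE
        } else if (a < b && keep[a] && keep[b] &&
                   identical(cols[[a]], cols[[b]])) {
          keep[b] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  lab <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  tibble(group = groups, letter = lab)
}

#' Mann-Whitney U test with continuity correction
#'
#' Two-sided rank-sum test.  The default normal approximation uses the
#' tie-corrected variance and a 0.5 continuity correction; for small
#' samples an exact mode enumerates all group labelings of the pooled
#' values (valid under ties as well).
#'
#' @param x,y Numeric samples; both non-empty.
#' @param exact `TRUE` to enumerate all `choose(n1+n2, n1)` labelings;
#'   `NULL` (default) switches to exact when both groups have <= 8
#'   observations.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation.
#' @return A one-row tibble: `statistic` (U for the first sample),
#'   `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL, continuity = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    p <- mw_exact_p(pooled, n1)
    return(tibble(statistic = u, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(tibble(statistic = u, p_value = 1, method = "normal"))
  }
  z <- u - mu
  if (continuity) z <- sign(z) * max(0, abs(z) - 0.5)
  p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
  tibble(statistic = u, p_value = p, method = "normal")
}

# exact two-sided p by exhaustive enumeration of group labelings;
# extremeness measured by |U - n1 n2 / 2|
mw_exact_p <- function(pooled, n1) {
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  combs <- combn(n, n1)
  us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= obs - 1e-9)
}

#' Standardise trait columns to z-scores
#'
#' Centres each column to mean 0 and scales to sample (n-1) standard
#' deviation 1.
#'
#' @param mat Numeric matrix or data frame of traits (columns).
#' @return A matrix of the same shape.  A zero-variance column is an
#'   error.
#' @export
standardize_traits <- function(mat) {
  m <- as.matrix(mat)
  s <- apply(m, 2, sd)
  if (any(!is.finite(s)) || any(s < 1e-12)) {
    bad <- colnames(m)[!is.finite(s) | s < 1e-12]
    abort("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  scale(m, center = TRUE, scale = s)[, , drop = FALSE]
}

#' PCA of a trait matrix
#'
#' Principal components of the column-standardised matrix.  Missing
#' values are imputed by the trait (column) mean and flagged;
#' zero-variance columns are dropped with a warning.
#'
#' @param mat Numeric matrix/data frame, observations x traits.
#' @param n_components Number of components to keep (default all).
#' @return A list of class `trait_pca`: `scores`, `loadings`
#'   (columns = components), `var_explained` (fractions, non-increasing),
#'   `imputed` (logical matrix flag), `dropped` (names of zero-variance
#'   columns).
#' @export
pca_traits <- function(mat, n_components = NULL) {
  m <- as.matrix(mat)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 rows and 2 columns")
  imputed <- !is.finite(m)
  if (any(imputed)) {
    for (j in seq_len(ncol(m))) {
      mj <- m[, j]
      mj[!is.finite(mj)] <- mean(mj[is.finite(mj)])
      m[, j] <- mj
    }
  }
  s <- apply(m, 2, sd)
  dropped <- colnames(m)[s < 1e-12]
  if (length(dropped) > 0) {
    warn(paste("dropping zero-variance column(s):",
               paste(dropped, collapse = ", ")))
    m <- m[, s >= 1e-12, drop = FALSE]
  }
  z <- standardize_traits(m)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components %||% ncol(z), ncol(pc$rotation))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 sdev = pc$sdev,
                 standardized = z,
                 imputed = imputed, dropped = dropped),
            class = "trait_pca")
}

#' Ward hierarchical clustering of a trait matrix
#'
#' Agglomerative clustering with the Ward minimum-variance criterion
#' (on Euclidean distances, `hclust` method `"ward.D2"`), over the rows
#' and independently over the columns of a standardised matrix.
#'
#' @param mat Numeric matrix (typically [standardize_traits()] output)
#'   with row and column names.
#' @param k_rows,k_cols Numbers of clusters at which to cut the two
#'   trees.
#' @param cluster_cols Also cluster columns (traits)?
#' @return A list of class `ward_cluster`: `row_hclust`, `col_hclust`
#'   (or `NULL`), `row_clusters`, `col_clusters` (named integer
#'   vectors), `matrix`.
#' @export
ward_cluster <- function(mat, k_rows = 3, k_cols = 2, cluster_cols = TRUE) {
  m <- as.matrix(mat)
  if (nrow(m) < 2) abort("need at least 2 rows to cluster")
  hr <- hclust(dist(m), method = "ward.D2")
  rc <- cutree(hr, k = min(k_rows, nrow(m)))
  hc <- NULL; cc <- NULL
  if (cluster_cols && ncol(m) >= 2) {
    hc <- hclust(dist(t(m)), method = "ward.D2")
    cc <- cutree(hc, k = min(k_cols, ncol(m)))
  }
  structure(list(row_hclust = hr, col_hclust = hc,
                 row_clusters = rc, col_clusters = cc, matrix = m),
            class = "ward_cluster")
}

#' Accession-level trait heatmap matrix with Ward clustering
#'
#' Builds the accession x trait matrix used to relate photosynthetic
#' responses to salinity tolerance: the eight ChlF traits (`FvFm`,
#' `FvpFmp`, `PhiP`, `qP`, `PhiNO`, `PhiNPQ`, `qN`, `NPQ`) at the final
#' day's highest-irradiance state, expressed as salt relative to
#' control, joined with `siit1` and `siit2`; per-trait z-scored and
#' Ward-clustered both ways (default cut: 3 accession clusters, 2 trait
#' clusters).
#'
#' @param traits Long data frame: `accession`, `treatment`, `day`,
#'   `state`, `trait`, `value` (replicates already present are averaged).
#' @param siit_table A [siit()] result (columns `accession`, `siit1`,
#'   `siit2`), averaged per accession here.
#' @param day Final measurement day to use.
#' @param state State to use (highest irradiance, e.g. `"L4"`).
#' @param chlf_traits The trait names to include.
#' @param na_action `"error"` (default), `"impute"` (trait mean, flagged)
#'   or `"drop"` (exclude incomplete accessions).
#' @param k_rows,k_cols Cluster counts for the two cuts.
#' @return A list of class `cluster_report`: `matrix` (standardised
#'   accession x trait), `raw` (pre-standardisation), `clustering`
#'   (a [ward_cluster()]), plus the cut memberships `row_clusters`,
#'   `col_clusters`.
#' @export
early_late_cluster_report <- function(traits, siit_table, day, state = "L4",
                                      chlf_traits = c("FvFm", "FvpFmp",
                                                      "PhiP", "qP", "PhiNO",
                                                      "PhiNPQ", "qN", "NPQ"),
                                      na_action = c("error", "impute", "drop"),
                                      k_rows = 3, k_cols = 2) {
  na_action <- match.arg(na_action)
  need <- c("accession", "treatment", "state", "trait", "value", "day")
  if (!all(need %in% names(traits))) {
    abort("`traits` needs columns ", paste(need, collapse = ", "))
  }
  # FvFm is measured dark-adapted; other traits at the requested state
  sel <- traits |>
    dplyr::filter(.data$day == .env$day, .data$trait %in% chlf_traits,
                  .data$state == .env$state |
                    (.data$trait == "FvFm" & .data$state == "dark")) |>
    dplyr::group_by(.data$accession, .data$treatment, .data$trait) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "value")
  if (!all(c("control", "salt") %in% names(sel))) {
    abort("`traits` must contain both control and salt treatments")
  }
  rel <- sel |>
    dplyr::mutate(value = .data$salt / .data$control) |>
    dplyr::select("accession", "trait", "value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")

  si <- siit_table |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(siit1 = mean(.data$siit1, na.rm = TRUE),
                     siit2 = mean(.data$siit2, na.rm = TRUE),
                     .groups = "drop")
  wide <- dplyr::inner_join(rel, si, by = "accession")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$accession
  m <- m[, c(intersect(chlf_traits, colnames(m)), "siit1", "siit2"),
         drop = FALSE]

  if (anyNA(m)) {
    if (na_action == "error") {
      abort("missing trait values for accession(s): ",
            paste(rownames(m)[rowSums(is.na(m)) > 0], collapse = ", "),
            "; set na_action to \"impute\" or \"drop\"")
    } else if (na_action == "drop") {
      m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(m))) {
        mj <- m[, j]; mj[is.na(mj)] <- mean(mj, na.rm = TRUE); m[, j] <- mj
      }
    }
  }
  z <- standardize_traits(m)
  cl <- ward_cluster(z, k_rows = k_rows, k_cols = k_cols)
  structure(list(matrix = z, raw = m, clustering = cl,
                 row_clusters = cl$row_clusters,
                 col_clusters = cl$col_clusters),
            class = "cluster_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
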