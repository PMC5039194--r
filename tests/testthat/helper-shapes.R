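# analytic raster shapes used across morphometrics / rgb tests

raster_disk <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

raster_ellipse <- function(a, b, pad = 4) {
  # semi-axes a (columns) x b (rows)
  nr <- 2 * b + 2 * pad + 1
  nc <- 2 * a + 2 * pad + 1
  outer(seq_len(nr), seq_len(nc), function(i, j) {
    ((j - (a + pad + 1)) / a)^2 + ((i - (b + pad + 1)) / b)^2 <= 1
  })
}

plus_pentomino <- function() {
  m <- matrix(FALSE, 5, 5)
  m[2:4, 3] <- TRUE
  m[3, 2:4] <- TRUE
  m
}

small_design <- function(n_acc = 2, n_rep = 3, days = 0:7, seed = 1) {
  generate_design(n_acc, 2, n_rep, days = days, seed = seed)
}

# euclidean distance between two RGB palettes after matching rows by
# nearest neighbour
palette_match_dist <- function(got, truth) {
  d <- sqrt(outer(rowSums(got^2), rep(1, nrow(truth))) -
              2 * got %*% t(truth) + outer(rep(1, nrow(got)), rowSums(truth^2)))
  apply(d, 2, min)
}

# do two cluster labelings define the same partition?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sum(tab > 0) == max(length(unique(a)), length(unique(b)))
}
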