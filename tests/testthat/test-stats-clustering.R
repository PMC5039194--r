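test_that("ANOVA + Tukey letters separate and join groups correctly", {
  df <- data.frame(v = c(1, 1.02, 0.98, 9, 9.02, 8.98, 1.01, 0.97, 1.03),
                   g = rep(c("a", "b", "c"), each = 3))
  at <- anova_tukey(df, "v", "g")
  lt <- setNames(at$letters$letter, at$letters$group)
  expect_true(lt[["a"]] == lt[["c"]])   # a and c share a letter
  expect_false(lt[["b"]] == lt[["a"]])  # b is distinct
  expect_lt(at$anova$p_value, 1e-6)

  # equal means: one shared letter, F ~ 0
  df2 <- data.frame(v = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"), each = 3))
  at2 <- anova_tukey(df2, "v", "g")
  expect_equal(length(unique(at2$letters$letter)), 1)
  expect_lt(at2$anova$statistic, 1e-10)

  expect_error(anova_tukey(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")),
                           "v", "g"), "fewer than 2")
})

test_that("two-group Tukey p equals the studentised-range t equivalence", {
  set.seed(42)
  df <- data.frame(v = c(rnorm(6, 0), rnorm(7, 1)),
                   g = rep(c("a", "b"), c(6, 7)))
  at <- anova_tukey(df, "v", "g")
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  p_range <- 1 - ptukey(abs(tt$statistic) * sqrt(2), nmeans = 2, df = 11)
  expect_equal(at$tukey$p_adj, unname(p_range), tolerance = 1e-9)
})

test_that("Mann-Whitney exact p matches enumeration and symmetry holds", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)           # 2/20 labelings as extreme
  expect_equal(r$statistic, 0)
  # identical multisets: U = n1 n2 / 2
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 4.5)
  # swap symmetry
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(mann_whitney(a, b, exact = FALSE)$p_value,
               mann_whitney(b, a, exact = FALSE)$p_value)
})

test_that("Mann-Whitney approximation matches wilcox.test and exact p", {
  set.seed(7)
  for (n1 in c(4, 6, 8)) {
    for (rep in 1:3) {
      x <- round(rnorm(n1, 0, 2), 1)
      y <- round(rnorm(n1 + 1, 0.8, 2), 1)
      ours <- mann_whitney(x, y, exact = FALSE)
      ref <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
      expect_equal(ours$statistic, unname(ref$statistic))
      ex <- mann_whitney(x, y, exact = TRUE)
      expect_lt(abs(ours$p_value - ex$p_value), 0.05)
    }
  }
})

test_that("z-scoring gives sample-SD units, mean 0, and is idempotent", {
  z <- standardize_traits(cbind(a = c(1, 3)))
  expect_equal(as.vector(z), c(-0.7071068, 0.7071068), tolerance = 1e-6)
  set.seed(3)
  m <- matrix(rnorm(60, 5, 3), 20)
  z2 <- standardize_traits(m)
  expect_lt(max(abs(colMeans(z2))), 1e-12)
  expect_equal(apply(z2, 2, sd), rep(1, 3))
  expect_equal(unclass(standardize_traits(z2))[, ], unclass(z2)[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_traits(cbind(a = c(2, 2, 2))), "zero-variance")
})

test_that("PCA finds rank, centring, and reconstructs the matrix", {
  m <- cbind(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4))
  p <- pca_traits(m)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)

  set.seed(11)
  m2 <- matrix(rnorm(2000), 1000, 2)
  p2 <- pca_traits(m2)
  expect_equal(p2$var_explained[1], 0.5, tolerance = 0.05)
  expect_lt(max(abs(colMeans(p2$scores))), 1e-12)
  expect_true(all(diff(p2$var_explained) <= 1e-12))

  # full reconstruction of the standardised matrix
  recon <- p2$scores %*% t(p2$loadings)
  expect_lt(max(abs(recon - p2$standardized)), 1e-8)

  # zero-variance column dropped with warning; NA imputed
  m3 <- cbind(m2[1:10, ], z = rep(1, 10))
  expect_warning(pca_traits(m3), "zero-variance")
  m4 <- m2[1:10, ]; m4[3, 1] <- NA
  p4 <- pca_traits(m4)
  expect_equal(sum(p4$imputed), 1)
})

test_that("Ward merge order matches brute-force objective minimisation", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(rnorm(8), 4, 2)
    rownames(m) <- letters[1:4]
    w <- ward_cluster(m, k_rows = 2, cluster_cols = FALSE)
    bf <- ward_bruteforce(m)
    # compare the member sets of each merge step
    hcl_members <- list()
    merged <- list()
    for (i in seq_len(nrow(w$row_hclust$merge))) {
      mr <- w$row_hclust$merge[i, ]
      mem <- c()
      for (v in mr) mem <- c(mem, if (v < 0) -v else merged[[v]])
      merged[[i]] <- mem
      hcl_members[[i]] <- sort(mem)
    }
    expect_equal(hcl_members[1:2], lapply(bf[1:2], `[[`, "members"))
  }
})

test_that("Ward heights are monotone and duplicates merge at 0", {
  set.seed(9)
  m <- matrix(rnorm(40), 10, 4)
  w <- ward_cluster(m)
  expect_true(all(diff(w$row_hclust$height) >= -1e-12))
  m2 <- rbind(m, m[1, ])
  rownames(m2) <- c(sprintf("r%d", 1:10), "dup")
  w2 <- ward_cluster(m2)
  expect_equal(min(w2$row_hclust$height), 0, tolerance = 1e-12)
  # tight pairs merge first
  tp <- matrix(c(0, 0, 0.05, 0, 10, 10, 10.05, 10), 4, 2, byrow = TRUE)
  rownames(tp) <- letters[1:4]
  w3 <- ward_cluster(tp, k_rows = 2, cluster_cols = FALSE)
  expect_true(same_partition(w3$row_clusters, c(1, 1, 2, 2)))
  expect_error(ward_cluster(m[1, , drop = FALSE]), "2 rows")
})

test_that("archetype accessions are recovered by the 2-cut; outlier isolates", {
  sim <- simulate_archetype_traits(8, noise_sd = 0.08, seed = 1)
  z <- standardize_traits(sim$matrix)
  w <- ward_cluster(z, k_rows = 2)
  expect_true(same_partition(w$row_clusters, sim$archetype))

  # an outlier row isolates at the 3-cut
  m <- sim$matrix
  m["acc08", ] <- m["acc08", ] + 5
  w3 <- ward_cluster(standardize_traits(m), k_rows = 3)
  expect_equal(sum(w3$row_clusters == w3$row_clusters[["acc08"]]), 1)
})

test_that("trait clusters split the quenching from the photochemical block", {
  # archetypes differ only in the quenching block; an independent
  # accession vigor axis drives the photochemical block, so each block
  # is internally correlated but the blocks are mutually unrelated
  set.seed(17)
  n <- 8
  arch <- rep(c(0, 1), each = 4)
  vigor <- rnorm(n, 0, 0.15)
  quench <- c("NPQ", "PhiNPQ", "qN", "PhiNO")
  photo <- c("FvFm", "FvpFmp", "PhiP", "qP")
  m <- cbind(
    sapply(photo, function(t) 1 + vigor + rnorm(n, 0, 0.02)),
    sapply(quench, function(t) 1 + 0.5 * arch + rnorm(n, 0, 0.02)),
    siit1 = 0.9 - 0.3 * arch + rnorm(n, 0, 0.02),
    siit2 = 0.8 - 0.4 * arch + rnorm(n, 0, 0.02))
  rownames(m) <- sprintf("acc%02d", 1:n)
  w <- ward_cluster(standardize_traits(m), k_rows = 2, k_cols = 2)
  expect_true(same_partition(w$col_clusters[c(quench, photo)],
                             rep(c(1, 2), each = 4)))
})

test_that("cluster report builds the 10-trait matrix and memberships", {
  # synthetic long table: 4 accessions from 2 archetypes
  sim <- simulate_archetype_traits(4, noise_sd = 0.02, seed = 2)
  traits <- tidyr::expand_grid(accession = rownames(sim$matrix),
                               treatment = c("control", "salt"),
                               trait = colnames(sim$matrix)[1:8])
  traits$state <- ifelse(traits$trait == "FvFm", "dark", "L4")
  traits$day <- 7
  traits$value <- ifelse(traits$treatment == "control", 1,
                         sim$matrix[cbind(traits$accession, traits$trait)])
  siit_tbl <- tibble::tibble(accession = rownames(sim$matrix),
                             siit1 = sim$matrix[, "siit1"],
                             siit2 = sim$matrix[, "siit2"])
  rep <- early_late_cluster_report(traits, siit_tbl, day = 7, state = "L4",
                                   k_rows = 2)
  expect_equal(dim(rep$matrix), c(4, 10))
  expect_true(same_partition(rep$row_clusters, sim$archetype))
  expect_lt(max(abs(colMeans(rep$matrix))), 1e-12)
})
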