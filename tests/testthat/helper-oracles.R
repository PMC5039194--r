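# brute-force greedy Ward: at each step merge the pair whose union
# minimises the increase in total within-cluster sum of squares
ward_bruteforce <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  ess <- function(ix) {
    x <- m[ix, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a < b) {
        cost <- ess(c(clusters[[a]], clusters[[b]])) -
          ess(clusters[[a]]) - ess(clusters[[b]])
        if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(a, b) }
      }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           cost = best_cost)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}
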