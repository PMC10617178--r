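# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: brute-force enumeration, closed forms, and
# textbook formulas.

# closed-form pooled two-sample t (equal-variance)
pooled_two_sample_t <- function(y, g) {
  y1 <- y[g == 1]; y0 <- y[g == 0]
  n1 <- length(y1); n0 <- length(y0)
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)) / (n1 + n0 - 2)
  (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# exact hypergeometric upper tail by direct summation over the support
hyper_upper_sum <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# literal enumeration over all C(N, n) draws of size n from the universe
hyper_upper_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)   # pathway = compounds 1..K
}

# naive betweenness: count shortest paths through each node by breadth-first
# enumeration of all shortest paths between every ordered pair
naive_betweenness <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) unique(c(edges[edges[, 1] == v, 2],
                                            edges[edges[, 2] == v, 1])))
  names(adj) <- nodes
  all_shortest_paths <- function(s, t) {
    if (s == t) return(list())
    paths <- list(s)
    found <- list()
    visited_depth <- stats::setNames(rep(Inf, length(nodes)), nodes)
    visited_depth[s] <- 0
    depth <- 0
    while (length(paths) > 0 && length(found) == 0) {
      depth <- depth + 1
      nxt <- list()
      for (p in paths) {
        for (nb in adj[[p[length(p)]]]) {
          if (visited_depth[nb] < depth) next
          visited_depth[nb] <- depth
          q <- c(p, nb)
          if (nb == t) found[[length(found) + 1]] <- q
          else nxt[[length(nxt) + 1]] <- q
        }
      }
      paths <- nxt
    }
    found
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s >= t) next
    sp <- all_shortest_paths(s, t)
    if (length(sp) == 0) next
    for (p in sp) {
      interior <- p[-c(1, length(p))]
      for (v in interior) btw[v] <- btw[v] + 1 / length(sp)
    }
  }
  btw
}

# small complete cohort with a design, shared by several files
make_toy_cohort <- function(n_per_group = c(40, 40), m = 30, n_sub = 5,
                            frac_nonnull = 0.2, effect = 1, rho = 0.3,
                            seed = 42) {
  cfg <- sim_config(n_per_group = n_per_group, n_metabolites = m,
                    n_subclasses = n_sub, within_subclass_correlation = rho,
                    frac_nonnull = frac_nonnull, effect_size_log_sd = effect,
                    lod_missing_frac = 0, seed = seed)
  coh <- generate_cohort(cfg)
  coh$design <- build_design(
    coh$covariates,
    model_spec("toy", c("age", "sex", "bmi", "coffee", "svi", "smoking", "batch")))
  coh$log_matrix <- impute_scale_log(coh$matrix)
  coh
}
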