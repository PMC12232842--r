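options(nichecomm.verbose = FALSE)

# small random count gem
make_gem <- function(n_genes = 6, n_cells = 8, seed = 1, lambda = 3,
                     gene_prefix = "g", cell_prefix = "c") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda),
      nrow = n_genes,
      dimnames = list(
        sprintf("%s%02d", gene_prefix, seq_len(n_genes)),
        sprintf("%s%02d", cell_prefix, seq_len(n_cells))
      )
    )
    gem(m)
  })
}

# adjusted Rand index between two labelings over the same elements
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force Jaccard of two binary columns via explicit set operations
jaccard_sets <- function(p, a, b) {
  sa <- rownames(p)[p[, a] > 0]
  sb <- rownames(p)[p[, b] > 0]
  u <- union(sa, sb)
  if (length(u) == 0) return(0)
  length(intersect(sa, sb)) / length(u)
}

# exhaustive minimum-cost oracle over capacity-feasible assignments
brute_force_assignment <- function(cost, capacities) {
  n <- nrow(cost)
  expand <- rep(seq_along(capacities), times = capacities)
  cols <- seq_along(expand)
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  cmb <- combn(cols, n)
  for (k in seq_len(ncol(cmb))) {
    for (p in perms(cmb[, k])) {
      tc <- sum(cost[cbind(seq_len(n), expand[p])])
      best <- min(best, tc)
    }
  }
  best
}

# tiny low-noise three-region mapping scenario
low_noise_config <- function(seed = 7) {
  synthetic_config(
    type_names = c("A", "B", "C"), cells_per_type = 100, focal_type = "A",
    grid = c(8, 9),
    regions = list(
      R1 = list(rows = c(1, 8), cols = c(1, 3), weights = c(A = 1)),
      R2 = list(rows = c(1, 8), cols = c(4, 6), weights = c(B = 1)),
      R3 = list(rows = c(1, 8), cols = c(7, 9), weights = c(C = 1))
    ),
    nb_dispersion = 50, signature_strength = 2.5, noise_rate = 0,
    n_lr_decoys = 0, seed = seed
  )
}
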