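test_that("cosine distances match the closed form on simple vectors", {
  expr <- cbind(
    a1 = c(1, 0), a2 = c(1, 0), # identical
    b1 = c(0, 1), # orthogonal to a*
    c1 = c(1, 1) # 45 degrees from a*
  )
  rownames(expr) <- c("g1", "g2")
  labels <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  dc <- pairwise_cosine_distances(expr, labels, list(
    within_A = "A", A_B = c("A", "B"), A_C = c("A", "C")
  ))
  expect_equal(dc$samples$within_A, 0)
  expect_equal(dc$samples$A_B, c(1, 1))
  expect_equal(dc$samples$A_C, rep(1 - 1 / sqrt(2), 2), tolerance = 1e-12)
})

test_that("zero vectors are excluded and pair counts are combinatorial", {
  withr::with_seed(2, {
    expr <- matrix(rpois(10 * 9, 3), 10, 9,
      dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:9))
    )
    expr[, 9] <- 0
    labels <- c(rep("A", 4), rep("B", 4), "A")
    names(labels) <- colnames(expr)
    expect_warning(
      dc <- pairwise_cosine_distances(
        expr, labels, list(w = "A", b = c("A", "B"))
      ),
      "zero vectors"
    )
    expect_length(dc$samples$w, choose(4, 2)) # zero-vector cell dropped
    expect_length(dc$samples$b, 4 * 4)
  })
  expect_error(
    pairwise_cosine_distances(
      matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2"))),
      c(c1 = "A", c2 = "B"), list(w = "A")
    ),
    "fewer than 2"
  )
})

test_that("within-type profiles are closer than cross-type profiles", {
  ds <- generate_dataset(scenario_preset("node_like", seed = 4))
  m <- suppressWarnings(normalize_log(ds$cells))
  labels <- setNames(ds$annotation$cell_type, ds$annotation$cell_id)
  dc <- pairwise_cosine_distances(m, labels, list(
    within = "Fibro", cross = c("Fibro", "aCM")
  ))
  expect_lt(dc$medians[["within"]], dc$medians[["cross"]])
})

test_that("KS statistic matches a brute-force ECDF supremum", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))[c("D", "p")], list(D = 0, p = 1))
  expect_equal(ks_compare(1:5, 6:10)$D, 1) # fully separated supports
  withr::with_seed(6, {
    for (i in 1:20) {
      a <- round(rnorm(sample(5:40, 1)), 1) # rounding forces ties
      b <- round(rnorm(sample(5:40, 1), 0.3), 1)
      grid <- sort(unique(c(a, b)))
      brute <- max(abs(
        vapply(grid, function(t) mean(a <= t), 1) -
          vapply(grid, function(t) mean(b <= t), 1)
      ))
      expect_equal(ks_compare(a, b)$D, brute, tolerance = 1e-12)
    }
  })
  expect_warning(out <- ks_compare(1, c(1, 2)), "unreliable")
  expect_false(out$reliable)
})

test_that("Wilcoxon p-values agree with the reference implementation", {
  withr::with_seed(12, {
    x <- matrix(rpois(150 * 24, 2), 150, 24,
      dimnames = list(sprintf("g%03d", 1:150), sprintf("c%02d", 1:24))
    )
    grp <- setNames(rep(c("a", "b"), each = 12), colnames(x))
    ln <- log1p(x)
    d <- deg_wilcoxon(ln, grp)
    ref <- apply(ln, 1, function(v) {
      suppressWarnings(
        wilcox.test(v[1:12], v[13:24], exact = FALSE, correct = FALSE)$p.value
      )
    })
    expect_equal(d$pval, unname(ref), tolerance = 1e-12)
  })
})

test_that("Wilcoxon results are invariant to cell and gene order", {
  sim <- simulate_two_group_counts(80, 30, n_planted = 5, log2fc = 2, seed = 4)
  m <- normalize_log(sim$m)
  d1 <- deg_wilcoxon(m, sim$groups)
  withr::with_seed(5, {
    cp <- sample(ncol(m$norm))
    gp <- sample(nrow(m$norm))
  })
  m2 <- m
  m2$counts <- m$counts[gp, cp]
  m2$norm <- m$norm[gp, cp]
  d2 <- deg_wilcoxon(m2, sim$groups)
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d1$log2fc, d2$log2fc)
  expect_equal(d1$padj, d2$padj)
})

test_that("the fold-change gate blocks significant but small shifts", {
  # a modest shift with many well-expressed cells: tiny p, linear FC < 1.5
  sim <- simulate_two_group_counts(200, 300,
    n_planted = 1, log2fc = log2(1.2),
    nb_dispersion = 50, base_meanlog = log(20), base_sdlog = 0.3, seed = 9
  )
  m <- normalize_log(sim$m)
  d <- deg_wilcoxon(m, sim$groups)
  row <- d[d$gene == sim$planted, ]
  expect_lt(row$padj, 0.05)
  expect_lt(2^abs(row$log2fc), 1.5)
  expect_false(row$significant)
})

test_that("planted strong DEGs are flagged by the Wilcoxon branch", {
  sim <- simulate_two_group_counts(300, 100,
    n_planted = 10, log2fc = 2,
    nb_dispersion = 20, seed = 10
  )
  m <- normalize_log(sim$m)
  d <- deg_wilcoxon(m, sim$groups)
  expect_true(all(d$significant[d$gene %in% sim$planted]))
})

test_that("BH adjustment matches a brute-force implementation", {
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  withr::with_seed(13, {
    for (i in 1:5) {
      p <- runif(200)^2
      expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
    }
  })
  # adjusted p never falls below raw p in any deg table
  sim <- simulate_two_group_counts(100, 20, seed = 14)
  d <- deg_wilcoxon(normalize_log(sim$m), sim$groups)
  expect_true(all(d$padj >= d$pval))
})

test_that("pseudobulk partitioning is balanced, conservative, seeded", {
  m <- make_gem(12, 18, seed = 15)
  grp <- setNames(rep(c("A", "B"), each = 9), cell_ids(m))
  pb <- make_pseudobulk(m, grp, n_reps = 3, seed = 2)
  expect_equal(
    as.integer(table(sub("_rep.*", "", colnames(pb$counts)))), c(3L, 3L)
  )
  expect_true(all(table(pb$partition) == 3)) # 9 cells -> 3 x 3
  # conservation: replicate sums equal group totals
  for (g in c("A", "B")) {
    expect_equal(
      rowSums(pb$counts[, pb$group == g]),
      rowSums(m$counts[, names(grp)[grp == g]])
    )
  }
  pb2 <- make_pseudobulk(m, grp, n_reps = 3, seed = 2)
  expect_identical(pb$partition, pb2$partition)
  expect_error(make_pseudobulk(m, grp, n_reps = 10), "fewer than 10")
})

test_that("pseudobulk Wald flags planted DEGs and reports zero LFC exactly", {
  sim <- simulate_two_group_counts(400, 200,
    n_planted = 15, log2fc = 3,
    seed = 16
  )
  pb <- make_pseudobulk(sim$m, sim$groups, seed = 17)
  d <- pseudobulk_deg(pb)
  expect_true(all(d$significant[d$gene %in% sim$planted]))
  expect_true(all(d$padj >= d$pval, na.rm = TRUE))

  # equal size factors and identical group means give LFC exactly 0
  cts <- matrix(rep(c(5, 9), each = 6), 2, 6, byrow = TRUE,
    dimnames = list(c("gA", "gB"), sprintf("r%d", 1:6))
  )
  pb0 <- list(
    counts = cts,
    group = factor(rep(c("A", "B"), each = 3)),
    partition = setNames(colnames(cts), colnames(cts))
  )
  class(pb0) <- "pseudobulk"
  d0 <- pseudobulk_deg(pb0)
  expect_equal(d0$log2fc, c(0, 0), tolerance = 1e-8)

  bad <- pb0
  bad$counts[, bad$group == "A"] <- 0
  expect_error(pseudobulk_deg(bad), "degenerate")
})
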