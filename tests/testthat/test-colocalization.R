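test_that("presence is binary over the full spot universe", {
  a <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    spot_id = c("s1", "s1", "s1", "s1", "s1", "s2")
  )
  ann <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    cell_type = c("A", "A", "A", "A", "A", "B"),
    group = c("A@1", "A@1", "A@1", NA, NA, NA)
  )
  P <- build_presence_matrix(a, ann, c("s1", "s2", "s3"))
  expect_setequal(colnames(P), c("A", "A@1", "B"))
  expect_equal(P["s1", "A@1"], 1L) # five cells still score 1
  expect_equal(P["s1", "A"], 1L) # ungrouped focal cells keep their type
  expect_equal(unname(P["s3", ]), c(0L, 0L, 0L)) # empty spot row kept
  expect_true(all(P %in% 0:1))
  expect_error(
    build_presence_matrix(
      a, ann[-1, ], c("s1", "s2")
    ),
    "missing from annotation"
  )
})

test_that("Jaccard values follow set arithmetic", {
  P <- matrix(0L, 4, 3, dimnames = list(
    sprintf("s%d", 1:4), c("A", "B", "C")
  ))
  P[c("s1", "s2", "s3"), "A"] <- 1L
  P[c("s2", "s3", "s4"), "B"] <- 1L
  J <- jaccard_matrix(P)
  expect_equal(J["A", "B"], 2 / 4)
  expect_equal(J["A", "A"], 1)
  expect_equal(J["A", "C"], 0) # C empty
  expect_equal(J["C", "C"], 0) # empty vs empty defined as 0
  expect_false(is.null(attr(J, "empty_pairs")))
})

test_that("Jaccard equals brute-force set computation on random matrices", {
  withr::with_seed(31, {
    for (i in 1:100) {
      P <- matrix(rbinom(sample(4:20, 1) * 6, 1, runif(1, 0.1, 0.7)),
        ncol = 6
      )
      dimnames(P) <- list(
        sprintf("s%02d", seq_len(nrow(P))), sprintf("T%d", 1:6)
      )
      J <- jaccard_matrix(P)
      for (a in 1:5) {
        for (b in (a + 1):6) {
          expect_identical(
            J[a, b], jaccard_sets(P, colnames(P)[a], colnames(P)[b])
          )
        }
      }
    }
  })
})

test_that("Jaccard is invariant to spot and type permutations", {
  withr::with_seed(32, {
    P <- matrix(rbinom(15 * 4, 1, 0.4), 15, 4,
      dimnames = list(sprintf("s%02d", 1:15), c("A", "B", "C", "D"))
    )
    J <- jaccard_matrix(P)
    sp <- sample(nrow(P))
    tp <- sample(ncol(P))
    J2 <- jaccard_matrix(P[sp, tp])
    expect_equal(J2[colnames(P), colnames(P)], J)
  })
})

test_that("spot sharing fraction counts co-occupied focal spots", {
  P <- matrix(0L, 5, 2, dimnames = list(sprintf("s%d", 1:5), c("F", "O")))
  P[1:4, "F"] <- 1L
  expect_equal(spot_sharing_fraction(P, "F"), 0) # alone everywhere
  P[1, "O"] <- 1L
  expect_equal(spot_sharing_fraction(P, "F"), 0.25)
  P[1:4, "O"] <- 1L
  expect_equal(spot_sharing_fraction(P, "F"), 1)
  P[, "F"] <- 0L
  expect_error(spot_sharing_fraction(P, "F"), "all-zero")
  expect_error(spot_sharing_fraction(P, "Z"), "not present")
})

test_that("Spearman rho matches a brute-force average-rank computation", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  avg_rank <- function(x) {
    vapply(x, function(v) {
      sum(x < v) + (1 + sum(x == v)) / 2
    }, numeric(1))
  }
  withr::with_seed(33, {
    for (i in 1:25) {
      n <- sample(4:15, 1)
      x <- sample(1:5, n, replace = TRUE) # heavy ties
      y <- sample(1:4, n, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      rx <- avg_rank(x)
      ry <- avg_rank(y)
      brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
      sp <- spearman_cor(x, y)
      expect_equal(sp$rho, brute, tolerance = 1e-12)
      expect_equal(sp$rho, suppressWarnings(cor(x, y, method = "spearman")),
        tolerance = 1e-12
      )
    }
  })
  flat <- spearman_cor(rep(1, 4), 1:4)
  expect_false(flat$defined)
  expect_error(spearman_cor(1:3, 1:4), "length mismatch")
})

test_that("concordance is exact for rank-aligned inputs and transform-invariant", {
  coloc <- matrix(0, 5, 5, dimnames = list(
    c("F", "A", "B", "C", "D"), c("F", "A", "B", "C", "D")
  ))
  coloc["F", c("A", "B", "C", "D")] <- c(0.4, 0.3, 0.2, 0.1)
  coloc[c("A", "B", "C", "D"), "F"] <- c(0.4, 0.3, 0.2, 0.1)
  counts <- data.frame(
    focal = "F", partner = c("A", "B", "C", "D"),
    count = c(9, 5, 4, 1)
  )
  rep1 <- concordance(counts, coloc, "F")
  expect_equal(rep1$F$rho, 1)

  # any strictly monotone transform of either vector keeps rho
  counts2 <- counts
  counts2$count <- exp(counts$count)
  coloc2 <- coloc
  coloc2[] <- coloc^3
  rep2 <- concordance(counts2, coloc2, "F")
  expect_equal(rep2$F$rho, rep1$F$rho)

  expect_error(
    concordance(counts[1:2, ], coloc[1:3, 1:3], "F"),
    "fewer than 3"
  )
})

test_that("subsampling equalizes group sizes and yields distinct datasets", {
  withr::with_seed(34, {
    groups <- setNames(
      rep(c("g1", "g2"), c(100, 40)),
      sprintf("c%03d", 1:140)
    )
    sets <- subsample_equalize(groups, n_datasets = 10, seed = 3)
    expect_length(sets, 10)
    for (s in sets) {
      expect_equal(as.integer(table(s)), c(40L, 40L))
      expect_true(all(names(s) %in% names(groups)))
    }
    sigs <- vapply(sets, function(s) paste(sort(names(s)), collapse = ","), "")
    expect_equal(anyDuplicated(sigs), 0L)

    # equal groups: no subsampling possible, datasets are the full labeling
    eq <- setNames(rep(c("a", "b"), each = 5), sprintf("c%02d", 1:10))
    sets_eq <- subsample_equalize(eq, n_datasets = 3, seed = 1)
    expect_true(all(vapply(
      sets_eq, function(s) length(s) == 10, logical(1)
    )))
  })
  expect_error(subsample_equalize(c(c1 = "a")), "at least 2")
})
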