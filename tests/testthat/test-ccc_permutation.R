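# tiny labeled expression fixture: 2 groups x 3 cells, 1 interaction
tiny_ccc_fixture <- function(seed = 1) {
  withr::with_seed(seed, {
    expr <- matrix(runif(2 * 6, 0.2, 3), 2, 6,
      dimnames = list(c("LG", "RC"), sprintf("c%d", 1:6))
    )
    groups <- setNames(rep(c("A", "B"), each = 3), colnames(expr))
    lr <- lr_database("I1", "LG", "RC")
    list(expr = expr, groups = groups, lr = lr)
  })
}

test_that("complex value is the minimum component mean, with a gate", {
  expr <- rbind(
    hi = c(2, 2, 2, 2), lo = c(0.5, 0.5, 0.5, 0.5),
    off = c(0, 0, 0, 0)
  )
  colnames(expr) <- sprintf("c%d", 1:4)
  cells <- colnames(expr)
  two <- group_mean_expression(expr, cells, c("hi", "lo"))
  expect_equal(two$value, 0.5)
  expect_true(two$gate)

  silent <- group_mean_expression(expr, cells, "off")
  expect_equal(silent$value, 0)
  expect_false(silent$gate)

  expect_warning(
    absent <- group_mean_expression(expr, cells, "nope"),
    "absent"
  )
  expect_equal(absent$value, 0)
  expect_false(absent$gate)
  expect_error(group_mean_expression(expr, cells, character()), "non-empty")
})

test_that("interaction scores average the two sides and keep autocrine pairs", {
  expr <- rbind(
    LG = c(1, 1, 1, 3, 3, 3),
    RC = c(3, 3, 3, 1, 1, 1)
  )
  colnames(expr) <- sprintf("c%d", 1:6)
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(expr))
  lr <- lr_database("I1", "LG", "RC")
  sc <- score_interactions(expr, groups, lr, min_cells = 1)
  get <- function(s, r) sc$score[sc$sender == s & sc$receiver == r]
  expect_equal(get("A", "B"), (1 + 1) / 2)
  expect_equal(get("B", "A"), (3 + 3) / 2)
  expect_equal(get("A", "A"), (1 + 3) / 2) # autocrine included
  expect_true(all(sc$gate))
})

test_that("small groups are excluded with a warning", {
  fx <- tiny_ccc_fixture()
  grp <- fx$groups
  grp[1:2] <- "C" # leaves a 1-cell A group
  expect_warning(
    sc <- score_interactions(fx$expr, grp, fx$lr, min_cells = 2),
    "below min_cells"
  )
  expect_false("A" %in% sc$sender)
})

test_that("exhaustive permutation p equals direct enumeration", {
  fx <- tiny_ccc_fixture(seed = 3)
  res <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1,
    expr_prop = 0, mode = "exhaustive"
  )
  # independent oracle: enumerate the 20 arrangements directly
  score_of <- function(lab) {
    (mean(fx$expr["LG", lab == "A"]) + mean(fx$expr["RC", lab == "B"])) / 2
  }
  obs <- score_of(fx$groups)
  sets <- combn(6, 3)
  perm_scores <- apply(sets, 2, function(idx) {
    lab <- rep("B", 6)
    lab[idx] <- "A"
    score_of(lab)
  })
  expect_equal(ncol(sets), 20)
  p_oracle <- mean(perm_scores >= obs)
  got <- res$pval[res$sender == "A" & res$receiver == "B"]
  expect_equal(got, p_oracle, tolerance = 1e-12)
})

test_that("sampled permutation p agrees with exhaustive within binomial error", {
  fx <- tiny_ccc_fixture(seed = 4)
  ex <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1,
    expr_prop = 0, mode = "exhaustive"
  )
  sa <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1,
    expr_prop = 0, n_perm = 10000, seed = 5
  )
  for (i in seq_len(nrow(ex))) {
    p <- ex$pval[i]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(sa$pval[i] - p), 4 * se + 2e-3)
  }
})

test_that("p-values are deterministic given the seed and never zero", {
  fx <- tiny_ccc_fixture(seed = 6)
  a <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1, n_perm = 200, seed = 9
  )
  b <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1, n_perm = 200, seed = 9
  )
  expect_identical(a$pval, b$pval)
  expect_true(all(a$pval > 0 & a$pval <= 1))

  # invariant to cell order
  perm <- c(4, 1, 6, 2, 5, 3)
  c_ <- permutation_pvalues(
    fx$expr[, perm], fx$groups[perm], fx$lr,
    min_cells = 1, n_perm = 200, seed = 9
  )
  expect_identical(a$pval, c_$pval)
})

test_that("raising the observed score never raises the permutation p", {
  fx <- tiny_ccc_fixture(seed = 7)
  boosted <- fx$expr
  boosted["LG", fx$groups == "A"] <- boosted["LG", fx$groups == "A"] + 2
  base <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1, expr_prop = 0, mode = "exhaustive"
  )
  up <- permutation_pvalues(boosted, fx$groups, fx$lr,
    min_cells = 1, expr_prop = 0, mode = "exhaustive"
  )
  i <- base$sender == "A" & base$receiver == "B"
  expect_lte(up$pval[i], base$pval[i])
})

test_that("gated-out triples carry p = 1 and are never significant", {
  expr <- rbind(
    LG = c(2, 2, 2, 2, 2, 2),
    RC = c(0, 0, 0, 0, 0, 0) # receptor never expressed
  )
  colnames(expr) <- sprintf("c%d", 1:6)
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(expr))
  lr <- lr_database("I1", "LG", "RC")
  res <- permutation_pvalues(expr, groups, lr, min_cells = 1, n_perm = 50)
  expect_true(all(res$pval == 1))
  expect_false(any(res$significant))
})

test_that("significant counts aggregate by direction mode", {
  ccc <- data.frame(
    sender = c("F", "F", "F", "X", "Y", "F"),
    receiver = c("X", "X", "Y", "F", "F", "X"),
    interaction_id = sprintf("I%d", 1:6),
    score = 1, gate = TRUE, pval = 0.01,
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  class(ccc) <- c("ccc_result", "data.frame")
  both <- count_significant(ccc, "F")
  expect_equal(both$count[both$partner == "X"], 2 + 1)
  expect_equal(both$count[both$partner == "Y"], 1 + 1)
  snd <- count_significant(ccc, "F", direction_mode = "sender_only")
  expect_equal(snd$count[snd$partner == "X"], 2)
  rcv <- count_significant(ccc, "F", direction_mode = "receiver_only")
  expect_equal(rcv$count[rcv$partner == "Y"], 1)
  none <- ccc
  none$significant <- FALSE
  expect_true(all(count_significant(none, "F")$count == 0))
  expect_error(count_significant(ccc, "Z"), "unknown focal")
})

test_that("external CCC tables ingest, reject duplicates and round-trip", {
  dir <- withr::local_tempdir()
  writeLines(
    c("source\ttarget\tinteraction\tp", "A\tB\tI1\t0.01"),
    file.path(dir, "one.tsv")
  )
  one <- ingest_external_ccc(file.path(dir, "one.tsv"))
  expect_equal(nrow(one), 1)
  expect_true(one$significant)

  writeLines(
    c(
      "source\ttarget\tinteraction\tp",
      "A\tB\tI1\t0.01", "A\tB\tI1\t0.20"
    ),
    file.path(dir, "dup.tsv")
  )
  expect_error(ingest_external_ccc(file.path(dir, "dup.tsv")), "duplicate")

  # export own result, re-ingest, counts identical
  fx <- tiny_ccc_fixture(seed = 8)
  res <- permutation_pvalues(fx$expr, fx$groups, fx$lr,
    min_cells = 1, n_perm = 100, seed = 2
  )
  out <- file.path(dir, "own.tsv")
  write.table(
    data.frame(
      source = res$sender, target = res$receiver,
      interaction = res$interaction_id, p = res$pval
    ),
    out,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  back <- ingest_external_ccc(out)
  expect_equal(
    count_significant(back, "A")$count,
    count_significant(res, "A")$count
  )
})
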