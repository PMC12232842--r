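#' Differential expression between two groups by Wilcoxon rank-sum
#'
#' Per gene, a two-sided rank-sum test on normalized values with the normal
#' approximation and tie correction; BH correction over all tested genes.
#' The fold change is computed on the linear scale of the normalized layer:
#' `log2FC = log2((mean expm1 group1 + eps) / (mean expm1 group2 + eps))`
#' with `eps = 1e-9`.  A gene is flagged significant when its absolute
#' linear fold change exceeds `fc_threshold` and its adjusted p-value is
#' below `alpha`.
#'
#' @param expr Genes x cells matrix of normalized (log) expression, or a
#'   [gem] with a `norm` layer.
#' @param groups Named factor/character vector (cell id -> group) with
#'   exactly two levels among the matrix columns; each group needs at least
#'   3 cells.
#' @param fc_threshold Linear fold-change gate (default 1.5).
#' @param alpha Adjusted-p gate (default 0.05).
#' @return Data frame of class `deg_table`: `gene`, `log2fc`, `pval`,
#'   `padj`, `significant`, with attributes `method`, `fc_threshold`,
#'   `alpha`.  The first group in sorted level order is the fold-change
#'   numerator.
#' @export
deg_wilcoxon <- function(expr, groups, fc_threshold = 1.5, alpha = 0.05) {
  if (inherits(expr, "gem")) {
    if (is.null(expr$norm)) stop_nc("gem input needs a norm layer")
    expr <- expr$norm
  }
  groups <- groups[!is.na(groups)]
  common <- intersect(colnames(expr), names(groups))
  expr <- expr[, common, drop = FALSE]
  groups <- factor(as.character(groups[common]))
  if (nlevels(groups) != 2) stop_nc("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 3) stop_nc("each group needs at least 3 cells")
  g1 <- groups == levels(groups)[1]

  # vectorized rank-sum z with tie correction (two-sided normal approx.)
  n <- n1 + n2
  pvals <- apply(expr, 1, function(x) {
    r <- rank(x)
    W <- sum(r[g1]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of group 1
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
    if (s2 <= 0) return(1)
    z <- (W - n1 * n2 / 2) / sqrt(s2)
    2 * pnorm(-abs(z))
  })

  eps <- 1e-9
  lin <- expm1(expr)
  m1 <- rowMeans(lin[, g1, drop = FALSE])
  m2 <- rowMeans(lin[, !g1, drop = FALSE])
  log2fc <- log2((m1 + eps) / (m2 + eps))
  padj <- p.adjust(pvals, method = "BH")
  out <- data.frame(
    gene = rownames(expr), log2fc = log2fc, pval = pvals, padj = padj,
    significant = 2^abs(log2fc) > fc_threshold & padj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "method") <- "wilcoxon"
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Aggregate raw counts into pseudobulk replicates
#'
#' Cells of each group are randomly partitioned (seeded) into `n_reps`
#' near-equal subsets; raw counts are summed per subset.
#'
#' @param m A [gem] with raw counts.
#' @param groups Named vector (cell id -> group) with two levels; each group
#'   needs at least `n_reps` cells.
#' @param n_reps Replicates per group (default 3).
#' @param seed Integer seed for the partition.
#' @return A list of class `pseudobulk`: `counts` (genes x replicates),
#'   `group` (factor per replicate), `partition` (cell id -> replicate name).
#' @export
make_pseudobulk <- function(m, groups, n_reps = 3, seed = 1) {
  groups <- groups[!is.na(groups)]
  common <- intersect(cell_ids(m), names(groups))
  groups <- factor(as.character(groups[common]))
  names(groups) <- common
  lv <- levels(groups)
  if (length(lv) != 2) stop_nc("exactly two groups required")
  partition <- character(0)
  with_seed_(seed, {
    for (g in lv) {
      cells <- names(groups)[groups == g]
      if (length(cells) < n_reps) {
        stop_nc(sprintf("group %s has fewer than %d cells", g, n_reps))
      }
      shuffled <- sample(cells)
      rep_id <- rep(seq_len(n_reps), length.out = length(cells))
      partition[shuffled] <- sprintf("%s_rep%d", g, rep_id)
    }
  })
  pb_counts <- t(rowsum(t(m$counts[, names(partition), drop = FALSE]),
    group = partition
  ))
  rep_group <- factor(sub("_rep[0-9]+$", "", colnames(pb_counts)),
    levels = lv
  )
  structure(
    list(
      counts = pb_counts, group = rep_group,
      partition = setNames(partition, names(partition))
    ),
    class = "pseudobulk"
  )
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf(
    "<pseudobulk> %d genes x %d replicates (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s: %d", levels(x$group), table(x$group)), collapse = ", ")
  ))
  invisible(x)
}

# median-of-ratios size factors with a total-count fallback when almost all
# gene-wise geometric means are zero
size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  usable <- is.finite(loggeo)
  if (mean(!usable) > 0.9) {
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  sf <- apply(counts, 2, function(x) {
    exp(median((log(x) - loggeo)[usable & x > 0]))
  })
  sf
}

#' Pseudobulk differential expression by a negative-binomial Wald test
#'
#' A deliberately simple two-group NB Wald test on pseudobulk counts:
#' size factors by median-of-ratios (total-count ratio fallback), per-gene
#' dispersion by method of moments on size-factor-normalized counts (floored
#' at 1e-8), a two-group NB log-link fit, and a Wald z on the group log fold
#' change; BH correction.  No dispersion or fold-change shrinkage and no
#' independent filtering are applied.  A gene is flagged significant when
#' `|log2FC| > lfc_threshold` (log2 scale) and adjusted p < `alpha`.
#'
#' @param pb A [make_pseudobulk()] result with at least 2 replicates per
#'   group.
#' @param lfc_threshold Log2 fold-change gate (default 1.5).
#' @param alpha Adjusted-p gate (default 0.05).
#' @return A `deg_table` data frame (see [deg_wilcoxon()]); genes with all
#'   zero counts carry `NA` p-values and are never flagged.
#' @export
pseudobulk_deg <- function(pb, lfc_threshold = 1.5, alpha = 0.05) {
  counts <- pb$counts
  group <- pb$group
  if (any(table(group) < 2)) stop_nc("at least 2 replicates per group")
  g1 <- group == levels(group)[1]
  if (all(colSums(counts[, g1, drop = FALSE]) == 0) ||
    all(colSums(counts[, !g1, drop = FALSE]) == 0)) {
    stop_nc("degenerate design: a group with all-zero totals")
  }
  sf <- size_factors(counts)
  normed <- sweep(counts, 2, sf, `/`)

  # method-of-moments dispersion alpha (var = mu + alpha mu^2), pooled
  # within groups, floored
  mu_g <- cbind(
    rowMeans(normed[, g1, drop = FALSE]),
    rowMeans(normed[, !g1, drop = FALSE])
  )
  resid2 <- (normed - mu_g[, (!g1) + 1L])^2
  v <- rowSums(resid2) / (ncol(counts) - 2)
  mu_bar <- rowMeans(normed)
  disp <- pmax((v - mu_bar) / pmax(mu_bar^2, 1e-12), 1e-8)

  off <- log(sf)
  x2 <- as.numeric(!g1) # indicator of group 2
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0)) return(c(NA_real_, NA_real_))
    fit <- tryCatch(
      suppressWarnings(glm(y ~ x2,
        family = MASS::negative.binomial(theta = 1 / disp[i]),
        offset = off
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2) return(c(NA_real_, NA_real_))
    # coefficient is log(group2/group1); report group1 over group2 in log2
    lfc <- -sm[2, 1] / log(2)
    z <- sm[2, 1] / sm[2, 2]
    c(lfc, 2 * pnorm(-abs(z)))
  }, numeric(2)))
  lfc <- res[, 1]
  pval <- res[, 2]
  padj <- rep(NA_real_, length(pval))
  tested <- !is.na(pval)
  padj[tested] <- p.adjust(pval[tested], method = "BH")
  out <- data.frame(
    gene = rownames(counts), log2fc = lfc, pval = pval, padj = padj,
    significant = !is.na(padj) & abs(lfc) > lfc_threshold & padj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "method") <- "pseudobulk"
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @rdname deg_wilcoxon
#' @param deg A `deg_table`.
#' @param path Output TSV path.
#' @export
write_deg_table <- function(deg, path) {
  write.table(as.data.frame(deg), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
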