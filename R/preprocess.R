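#' Library-size normalization with log transform
#'
#' Scales each cell to `target_sum` total counts and applies `log(1 + x)`
#' in the requested base.  Cells with zero total counts are left as all-zero
#' columns and reported with a warning (they can be dropped with
#' `drop_zero_cells = TRUE`).
#'
#' @param m A [gem] with counts.
#' @param target_sum Per-cell total after scaling (default 1e4,
#'   counts-per-10,000).
#' @param base Log base, `"e"` (natural, default) or `"2"`.
#' @param drop_zero_cells Drop zero-total cells instead of keeping them.
#' @return The [gem] with its `norm` layer set.
#' @export
normalize_log <- function(m, target_sum = 1e4, base = c("e", "2"),
                          drop_zero_cells = FALSE) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (!is.numeric(target_sum) || target_sum <= 0) {
    stop_nc("target_sum must be positive")
  }
  totals <- colSums(m$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf(
      "%d cells with zero total counts left as all-zero norm columns",
      sum(zero)
    ), call. = FALSE)
    if (drop_zero_cells) {
      m <- gem_subset(m, cells = which(!zero))
      totals <- totals[!zero]
      zero <- logical(length(totals))
    }
  }
  scale_fac <- ifelse(zero, 0, target_sum / pmax(totals, 1e-300))
  scaled <- sweep(m$counts, 2, scale_fac, `*`)
  norm <- log1p(scaled)
  if (base == "2") norm <- norm / log(2)
  m$norm <- norm
  m
}

#' Quality-control filtering of spatial spots and genes
#'
#' Removes spots whose total counts fall outside the open interval
#' `(min_counts, max_counts)` or whose mitochondrial-count percentage
#' exceeds `max_mito_pct`; then removes genes detected in fewer than
#' `min_spots_per_gene` of the remaining spots.  Spot and gene order is
#' preserved.
#'
#' @param m A [gem] over spots.
#' @param min_counts,max_counts Open count window per spot (defaults 5000
#'   and 35000).
#' @param max_mito_pct Maximum allowed mitochondrial percentage (default 20).
#' @param min_spots_per_gene Minimum number of spots a gene must be detected
#'   in (default 10).
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return The filtered [gem].
#' @export
qc_filter_spots <- function(m, min_counts = 5000, max_counts = 35000,
                            max_mito_pct = 20, min_spots_per_gene = 10,
                            mito_prefix = "MT-") {
  stopifnot(min_counts > 0, max_counts > min_counts, max_mito_pct > 0,
            min_spots_per_gene >= 1)
  totals <- colSums(m$counts)
  mito <- startsWith(gene_ids(m), mito_prefix)
  mito_pct <- if (any(mito)) {
    100 * colSums(m$counts[mito, , drop = FALSE]) / pmax(totals, 1)
  } else {
    numeric(ncol(m$counts))
  }
  keep_count <- totals > min_counts & totals < max_counts
  keep_mito <- mito_pct <= max_mito_pct
  keep_spot <- keep_count & keep_mito
  if (!any(keep_spot)) {
    binding <- if (!any(keep_count)) "total-count window" else "mitochondrial percentage"
    stop_nc(sprintf("all spots removed by QC (%s)", binding))
  }
  m <- gem_subset(m, cells = which(keep_spot))
  detected <- rowSums(m$counts > 0)
  keep_gene <- detected >= min_spots_per_gene
  m <- gem_subset(m, genes = which(keep_gene))
  nc_msg(sprintf(
    "qc_filter_spots: kept %d/%d spots, %d/%d genes",
    sum(keep_spot), length(keep_spot), sum(keep_gene), length(keep_gene)
  ))
  m
}

#' Select highly variable genes by normalized dispersion
#'
#' Computes, per gene, the dispersion (variance/mean) of `expm1(norm)`
#' values, standardizes dispersions within bins of mean expression
#' (z-score per bin), and returns the `n` genes with the largest
#' standardized dispersion.  Ties at the cutoff are broken by
#' lexicographically smaller gene id.
#'
#' @param m A [gem] with a `norm` layer.
#' @param n Number of genes to return (default 2000); if `n` is at least
#'   the gene count, all genes are returned.
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of gene ids, ranked.
#' @export
select_hvg <- function(m, n = 2000, n_bins = 20) {
  if (is.null(m$norm)) stop_nc("select_hvg requires a norm layer")
  if (n < 1) stop_nc("n must be at least 1")
  x <- expm1(m$norm)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins of mean expression; z-score dispersion within bin
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  zs <- disp
  for (b in levels(bin)) {
    idx <- which(bin == b)
    mb <- mean(disp[idx])
    sb <- sd(disp[idx])
    zs[idx] <- if (is.na(sb) || sb == 0) 0 else (disp[idx] - mb) / sb
  }
  ids <- gene_ids(m)
  ord <- order(-zs, ids)
  if (n >= length(ids)) return(ids[ord])
  ids[ord][seq_len(n)]
}
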