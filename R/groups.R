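#' Stratify a focal cell type by the region label of its spot
#'
#' Each focal-type cell inherits the region label of the spot it is assigned
#' to.  Cells on unlabeled spots are excluded with a warning.
#'
#' @param a Assignment data frame (`cell_id`, `spot_id`).
#' @param sl A [slide] whose coordinate table has a `region` column.
#' @param annotation Annotation data frame (`cell_id`, `cell_type`).
#' @param focal_type The cell type to stratify.
#' @return Named character vector: focal cell id -> group (region) name.
#' @export
split_by_region <- function(a, sl, annotation, focal_type) {
  regions <- spot_regions(sl)
  focal_cells <- annotation$cell_id[annotation$cell_type == focal_type]
  a_f <- a[a$cell_id %in% focal_cells, , drop = FALSE]
  grp <- regions[a_f$spot_id]
  keep <- !is.na(grp)
  if (any(!keep)) {
    warning(sprintf(
      "%d focal cells on unlabeled spots excluded", sum(!keep)
    ), call. = FALSE)
  }
  if (!any(keep)) stop_nc("no focal cells in any labeled region")
  setNames(as.character(grp[keep]), a_f$cell_id[keep])
}

#' Spatially weighted gene-gene correlation
#'
#' Builds a Gaussian kernel `K_ij = exp(-d_ij^2 / (2 sigma^2))` on the
#' Euclidean distances between focal cells, row-normalizes it, smooths each
#' gene's expression vector (`S = K x`), and returns the Pearson correlation
#' matrix of the smoothed gene vectors.  As `sigma -> 0` the kernel tends to
#' the identity and the result to the plain per-cell correlation (passing
#' `sigma = 0` uses the identity kernel exactly).  Genes that are constant
#' after smoothing get zero correlations and are flagged in the
#' `"constant_genes"` attribute.
#'
#' @param expr Genes x cells matrix of normalized expression (or a [gem]
#'   with a `norm` layer).
#' @param coords Cells x 2 coordinate matrix (rows aligned with columns of
#'   `expr`).
#' @param sigma Kernel bandwidth in slide units; `NULL` (default) uses the
#'   median pairwise distance between the cells.
#' @return Symmetric gene x gene correlation matrix with unit diagonal for
#'   non-constant genes; attributes `sigma` and `constant_genes`.
#' @export
spatially_weighted_correlation <- function(expr, coords, sigma = NULL) {
  if (inherits(expr, "gem")) {
    if (is.null(expr$norm)) stop_nc("gem input needs a norm layer")
    expr <- expr$norm
  }
  n <- ncol(expr)
  if (n < 10) stop_nc("at least 10 focal cells required")
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  stopifnot(nrow(coords) == n)
  d <- as.matrix(dist(coords))
  if (is.null(sigma)) sigma <- median(d[upper.tri(d)])
  if (sigma < 0) stop_nc("sigma must be non-negative")
  K <- if (sigma == 0) diag(n) else exp(-d^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  S <- expr %*% t(K) # smoothed expression, genes x cells
  sds <- apply(S, 1, sd)
  # relative tolerance: an input-constant gene smoothed by row-normalized
  # weights carries only rounding noise
  const <- !is.finite(sds) | sds < 1e-10 * pmax(1, abs(rowMeans(S)))
  cc <- matrix(0, nrow(expr), nrow(expr),
    dimnames = list(rownames(expr), rownames(expr))
  )
  if (any(!const)) {
    cc[!const, !const] <- cor(t(S[!const, , drop = FALSE]))
  }
  diag(cc)[!const] <- 1
  attr(cc, "sigma") <- sigma
  attr(cc, "constant_genes") <- rownames(expr)[const]
  if (any(const)) {
    nc_msg(sprintf(
      "spatially_weighted_correlation: %d constant genes flagged", sum(const)
    ))
  }
  cc
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering on the distance `1 - correlation`,
#' cut into `k` clusters; clusters smaller than `min_size` are dropped.
#'
#' @param corr Gene x gene correlation matrix.
#' @param k Number of clusters to cut (default 3).
#' @param min_size Minimum module size (default 10).
#' @return Named list (module name -> gene id vector).
#' @export
detect_modules <- function(corr, k = 3, min_size = 10) {
  stopifnot(k >= 1)
  hc <- hclust(as.dist(1 - corr), method = "average")
  cl <- cutree(hc, k = k)
  mods <- split(names(cl), cl)
  keep <- lengths(mods) >= min_size
  if (!any(keep)) stop_nc("all clusters fall below min_size")
  mods <- mods[keep]
  names(mods) <- sprintf("M%d", seq_along(mods))
  mods
}

#' Per-cell module activity scores with bin-matched control genes
#'
#' For each module, the score of a cell is the mean normalized expression of
#' the module genes minus the mean over a control pool: for every module
#' gene, `n_controls` genes are drawn (seeded, without replacement) from the
#' same average-expression bin among `n_bins` equal-frequency bins of all
#' genes.
#'
#' @param expr Genes x cells matrix of normalized expression (or [gem] with
#'   `norm`).
#' @param modules Named list of gene id vectors.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_controls Control genes drawn per module gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return Cells x modules numeric matrix of scores.
#' @export
score_modules <- function(expr, modules, n_bins = 24, n_controls = 100,
                          seed = 1) {
  if (inherits(expr, "gem")) {
    if (is.null(expr$norm)) stop_nc("gem input needs a norm layer")
    expr <- expr$norm
  }
  avg <- rowMeans(expr)
  n_genes <- nrow(expr)
  bin <- setNames(
    ceiling(rank(avg, ties.method = "first") / (n_genes / n_bins)),
    rownames(expr)
  )
  scores <- matrix(0, ncol(expr), length(modules),
    dimnames = list(colnames(expr), names(modules))
  )
  with_seed_(seed, {
    for (mi in seq_along(modules)) {
      genes <- intersect(modules[[mi]], rownames(expr))
      if (length(genes) == 0) {
        stop_nc(sprintf(
          "module %s empty after intersection with the matrix",
          names(modules)[mi]
        ))
      }
      ctrl <- unlist(lapply(genes, function(g) {
        pool <- setdiff(rownames(expr)[bin == bin[g]], g)
        if (length(pool) == 0) return(character(0))
        sample(pool, min(n_controls, length(pool)))
      }))
      ctrl <- unique(ctrl)
      mod_mean <- colMeans(expr[genes, , drop = FALSE])
      ctrl_mean <- if (length(ctrl)) {
        colMeans(expr[ctrl, , drop = FALSE])
      } else {
        numeric(ncol(expr))
      }
      scores[, mi] <- mod_mean - ctrl_mean
    }
  })
  scores
}

#' Label each cell by its highest-scoring module
#'
#' Ties resolve to the lexicographically first module name.  Per-group sizes
#' are reported.
#'
#' @param scores Cells x modules score matrix.
#' @return Named character vector: cell id -> module name.
#' @export
assign_by_max_score <- function(scores) {
  if (is.null(dim(scores)) || ncol(scores) < 2) {
    stop_nc("at least 2 modules required")
  }
  if (nrow(scores) == 0) stop_nc("empty score matrix")
  ord <- order(colnames(scores))
  s <- scores[, ord, drop = FALSE]
  pick <- apply(s, 1, which.max)
  labels <- setNames(colnames(s)[pick], rownames(scores))
  tab <- table(labels)
  nc_msg(sprintf(
    "assign_by_max_score: %s",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")
  ))
  labels
}
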