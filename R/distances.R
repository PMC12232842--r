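#' Pairwise cosine distances within and between labeled groups
#'
#' Computes `1 - cosine similarity` between normalized expression profiles.
#' A comparison specified by a single label yields all unordered same-label
#' pairs ("within"); a pair of labels yields all cross-label pairs
#' ("between").  Zero vectors are excluded with a warning.
#'
#' @param expr Genes x cells matrix of normalized expression (or a [gem]
#'   with a `norm` layer).
#' @param labels Named character vector (cell id -> label) or a vector
#'   aligned with the matrix columns.
#' @param comparisons Named list; each element is one label (within) or two
#'   labels (between).
#' @return A list of class `distance_comparison` with elements `samples`
#'   (named list of distance vectors) and `medians`.
#' @export
pairwise_cosine_distances <- function(expr, labels, comparisons) {
  if (inherits(expr, "gem")) {
    if (is.null(expr$norm)) stop_nc("gem input needs a norm layer")
    expr <- expr$norm
  }
  if (!is.null(names(labels))) {
    common <- intersect(colnames(expr), names(labels))
    expr <- expr[, common, drop = FALSE]
    labels <- labels[common]
  } else {
    stopifnot(length(labels) == ncol(expr))
    names(labels) <- colnames(expr)
  }
  nrm <- sqrt(colSums(expr^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("%d zero vectors excluded", sum(zero)), call. = FALSE)
    expr <- expr[, !zero, drop = FALSE]
    labels <- labels[!zero]
    nrm <- nrm[!zero]
  }
  unit <- sweep(expr, 2, nrm, `/`)
  samples <- lapply(comparisons, function(cmp) {
    if (length(cmp) == 1) {
      idx <- which(labels == cmp)
      if (length(idx) < 2) {
        stop_nc(sprintf("label %s has fewer than 2 cells", cmp))
      }
      sim <- crossprod(unit[, idx, drop = FALSE])
      d <- 1 - sim[upper.tri(sim)]
    } else {
      ia <- which(labels == cmp[1])
      ib <- which(labels == cmp[2])
      if (length(ia) == 0 || length(ib) == 0) {
        stop_nc("a referenced label is empty")
      }
      sim <- crossprod(unit[, ia, drop = FALSE], unit[, ib, drop = FALSE])
      d <- 1 - as.vector(sim)
    }
    pmin(pmax(d, 0), 2)
  })
  structure(
    list(
      samples = samples,
      medians = vapply(samples, median, numeric(1))
    ),
    class = "distance_comparison"
  )
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat("<distance_comparison>\n")
  for (nm in names(x$samples)) {
    cat(sprintf(
      "  %s: n=%d, median=%.4f\n", nm, length(x$samples[[nm]]),
      x$medians[[nm]]
    ))
  }
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum of the absolute difference of the two empirical
#' distribution functions; the p-value uses the asymptotic two-sided
#' approximation.  With either sample below 2 observations a warning is
#' emitted and the result is flagged unreliable.
#'
#' @param sample_a,sample_b Numeric vectors (non-empty).
#' @return List with `D`, `p` and `reliable`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop_nc("both samples must be non-empty")
  }
  reliable <- TRUE
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    warning("sample size below 2; p-value unreliable", call. = FALSE)
    reliable <- FALSE
  }
  kt <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value), reliable = reliable)
}
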