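#' Gene expression matrix container
#'
#' A light container for a gene x cell (or gene x spot) count matrix with an
#' optional log-scale normalized layer.  Rows are genes, columns are cells;
#' both carry unique character ids as dimnames.
#'
#' @param counts Numeric matrix of non-negative integer counts
#'   (genes x cells) with unique rownames (gene ids) and colnames (cell or
#'   spot ids).  Sparse `Matrix` input is densified.
#' @param norm Optional numeric matrix of the same dimensions holding
#'   log-scale normalized values.
#' @return An object of class `gem`: a list with elements `counts` and
#'   (possibly `NULL`) `norm`.
#' @examples
#' m <- gem(matrix(c(5, 0, 0, 3), 2, 2,
#'                 dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' dim(m)
#' @export
gem <- function(counts, norm = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop_nc("`counts` must be a matrix")
  storage.mode(counts) <- "double"
  obj <- structure(list(counts = counts, norm = norm), class = "gem")
  validate_gem(obj)
  obj
}

validate_gem <- function(m) {
  counts <- m$counts
  gid <- rownames(counts)
  cid <- colnames(counts)
  if (is.null(gid) || is.null(cid)) {
    stop_nc("counts must carry gene ids (rownames) and cell ids (colnames)")
  }
  if (anyDuplicated(gid)) stop_nc("duplicate gene ids")
  if (anyDuplicated(cid)) stop_nc("duplicate cell ids")
  if (any(counts < 0)) stop_nc("counts contain negative entries")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop_nc("counts contain non-integral entries")
  }
  if (!is.null(m$norm)) {
    if (!identical(dim(m$norm), dim(counts))) {
      stop_nc("norm layer dimensions differ from counts")
    }
    if (any(!is.finite(m$norm))) stop_nc("norm layer contains non-finite values")
  }
  invisible(m)
}

#' @export
dim.gem <- function(x) dim(x$counts)

#' @export
dimnames.gem <- function(x) dimnames(x$counts)

#' Gene and cell ids of a gem
#' @param m A [gem] object.
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$counts)

#' Subset a gem by gene and/or cell ids (or indices)
#' @param m A [gem] object.
#' @param genes,cells Ids or indices to keep; `NULL` keeps all.
#' @return A [gem] with the same layers subset.
#' @export
gem_subset <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% rownames(m$counts)
  cells <- cells %||% colnames(m$counts)
  out <- structure(
    list(
      counts = m$counts[genes, cells, drop = FALSE],
      norm = if (!is.null(m$norm)) m$norm[genes, cells, drop = FALSE]
    ),
    class = "gem"
  )
  out
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf(
    "<gem> %d genes x %d cells%s\n",
    nrow(x$counts), ncol(x$counts),
    if (is.null(x$norm)) "" else " (+ norm layer)"
  ))
  invisible(x)
}

#' Spatial slide container
#'
#' Holds spot ids, spot coordinates, an optional spot-level expression
#' matrix and optional region labels.
#'
#' @param coords Data frame with columns `spot_id`, `x`, `y` and optionally
#'   `region`.
#' @param spot_expr Optional [gem] over the same spots.
#' @return An object of class `slide`.
#' @export
slide <- function(coords, spot_expr = NULL) {
  stopifnot(is.data.frame(coords))
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(coords))) {
    stop_nc("coords must have columns spot_id, x, y")
  }
  coords$spot_id <- as.character(coords$spot_id)
  if (anyDuplicated(coords$spot_id)) stop_nc("duplicate spot ids")
  if (any(!is.finite(coords$x)) || any(!is.finite(coords$y))) {
    stop_nc("spot coordinates must be finite")
  }
  if (!is.null(spot_expr)) {
    if (!all(cell_ids(spot_expr) %in% coords$spot_id)) {
      stop_nc("spot_expr columns must be a subset of slide spot ids")
    }
  }
  structure(list(coords = coords, spot_expr = spot_expr), class = "slide")
}

#' @export
print.slide <- function(x, ...) {
  nreg <- if ("region" %in% names(x$coords)) {
    length(unique(stats::na.omit(x$coords$region)))
  } else 0L
  cat(sprintf(
    "<slide> %d spots%s%s\n", nrow(x$coords),
    if (nreg > 0) sprintf(", %d regions", nreg) else "",
    if (is.null(x$spot_expr)) "" else " (+ expression)"
  ))
  invisible(x)
}

spot_regions <- function(sl) {
  if (!"region" %in% names(sl$coords)) {
    return(setNames(rep(NA_character_, nrow(sl$coords)), sl$coords$spot_id))
  }
  setNames(as.character(sl$coords$region), sl$coords$spot_id)
}
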