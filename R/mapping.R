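#' Estimate per-spot cell capacities from spot totals
#'
#' Allocates `n_cells_total` proportionally to spot total counts:
#' `capacity_i = max(1, round(n * total_i / sum(totals)))`; any deficit
#' after rounding is distributed one by one to the largest-total spots so
#' that the capacities always sum to at least `n_cells_total`.
#'
#' @param sl A [slide] with `spot_expr`, or a [gem] over spots.
#' @param n_cells_total Number of cells that must fit (positive integer).
#' @return Named integer vector of capacities per spot.
#' @export
estimate_spot_capacities <- function(sl, n_cells_total) {
  if (n_cells_total < 1) stop_nc("n_cells_total must be at least 1")
  m <- if (inherits(sl, "slide")) sl$spot_expr else sl
  if (is.null(m)) stop_nc("slide has no spot expression")
  totals <- colSums(m$counts)
  cap <- pmax(1L, as.integer(round(n_cells_total * totals / sum(totals))))
  deficit <- n_cells_total - sum(cap)
  if (deficit > 0) {
    ord <- order(-totals, names(totals))
    bump <- ord[((seq_len(deficit) - 1) %% length(cap)) + 1]
    tb <- table(bump)
    cap[as.integer(names(tb))] <- cap[as.integer(names(tb))] + as.integer(tb)
  }
  setNames(cap, colnames(m$counts))
}

# Exact rectangular linear assignment (rows <= columns) by shortest
# augmenting paths with dual potentials.  Returns, for each row, the
# assigned column index.  Deterministic: ties resolved toward the smallest
# column index.
solve_lap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop_nc("assignment infeasible: more rows than columns")
  u <- numeric(n); v <- numeric(m)
  col4row <- rep(NA_integer_, n)
  row4col <- rep(NA_integer_, m)
  for (cur in seq_len(n)) {
    spc <- rep(Inf, m)      # shortest path cost to each column
    path <- rep(NA_integer_, m)
    SR <- logical(n); SC <- logical(m)
    minVal <- 0
    i <- cur
    sink <- NA_integer_
    while (is.na(sink)) {
      SR[i] <- TRUE
      idx <- which(!SC)
      r <- minVal + cost[i, idx] - u[i] - v[idx]
      upd <- r < spc[idx]
      if (any(upd)) {
        path[idx[upd]] <- i
        spc[idx[upd]] <- r[upd]
      }
      jrel <- which.min(spc[idx])
      j <- idx[jrel]
      minVal <- spc[j]
      if (!is.finite(minVal)) stop_nc("assignment infeasible")
      SC[j] <- TRUE
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
    }
    # dual updates
    u[cur] <- u[cur] + minVal
    sr <- which(SR); sr <- sr[sr != cur]
    if (length(sr)) u[sr] <- u[sr] + minVal - spc[col4row[sr]]
    sc <- which(SC)
    v[sc] <- v[sc] - (minVal - spc[sc])
    # augment along the alternating path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- tmp
    }
  }
  col4row
}

#' Assign single cells to spots by capacity-constrained optimal matching
#'
#' Builds the cost matrix `1 - Pearson correlation` between cell and spot
#' normalized profiles over `gene_subset`, duplicates each spot according to
#' its capacity, and solves the resulting rectangular assignment problem
#' exactly (minimum total cost).  This is a deliberately simple, fully
#' specified stand-in for external expression-based mapping tools; their
#' assignment tables can be ingested with [read_assignment()] instead.
#'
#' @param cells_norm A [gem] with a `norm` layer (single cells).
#' @param spots_norm A [gem] with a `norm` layer (spots).
#' @param capacities Named integer vector (spot id -> max cells), e.g. from
#'   [estimate_spot_capacities()]; their sum must be at least the number of
#'   cells.
#' @param gene_subset Gene ids used for matching (at least 3 shared genes).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @param greedy Use a fast greedy fallback (each cell takes its cheapest
#'   remaining spot in cell order) instead of the exact solver; the result
#'   is then not guaranteed optimal (a note is emitted).
#' @return Data frame with columns `cell_id`, `spot_id`.
#' @export
map_cells_to_spots <- function(cells_norm, spots_norm, capacities,
                               gene_subset, method = c("pearson", "spearman"),
                               greedy = FALSE) {
  method <- match.arg(method)
  if (is.null(cells_norm$norm) || is.null(spots_norm$norm)) {
    stop_nc("both matrices need a norm layer")
  }
  genes <- intersect(
    intersect(gene_subset, gene_ids(cells_norm)),
    gene_ids(spots_norm)
  )
  if (length(genes) < 3) stop_nc("fewer than 3 shared genes in gene_subset")
  n_cells <- ncol(cells_norm$norm)
  if (sum(capacities) < n_cells) {
    stop_nc(sprintf(
      "total capacity %d is below the %d cells to assign",
      sum(capacities), n_cells
    ))
  }
  X <- cells_norm$norm[genes, , drop = FALSE]
  Y <- spots_norm$norm[genes, names(capacities), drop = FALSE]
  if (method == "spearman") {
    X <- apply(X, 2, rank)
    Y <- apply(Y, 2, rank)
  }
  cc <- suppressWarnings(cor(X, Y))
  cc[!is.finite(cc)] <- 0
  cost <- 1 - cc
  # capacity expansion: duplicate each spot column capacity times, keeping
  # spot-id order so ties resolve by (cell, spot) order
  expand <- rep(seq_along(capacities), times = capacities)
  if (greedy) {
    nc_msg("map_cells_to_spots: greedy mode, total cost not guaranteed optimal")
    remaining <- capacities
    pick <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      open <- which(remaining > 0)
      j <- open[which.min(cost[i, open])]
      pick[i] <- j
      remaining[j] <- remaining[j] - 1L
    }
    assigned_spot <- names(capacities)[pick]
  } else {
    big <- cost[, expand, drop = FALSE]
    sol <- solve_lap(big)
    assigned_spot <- names(capacities)[expand[sol]]
  }
  data.frame(
    cell_id = cell_ids(cells_norm), spot_id = assigned_spot,
    stringsAsFactors = FALSE
  )
}

#' Snap coordinate-valued cell positions to their nearest spots
#'
#' Assigns each cell to the spot minimizing Euclidean distance; exact ties
#' resolve to the lexicographically smallest spot id.  No capacity
#' constraint is applied.
#'
#' @param cell_coords Matrix or data frame with rownames (cell ids) and two
#'   columns (x, y) in the same units as the slide coordinates, or a data
#'   frame with columns `cell_id`, `x`, `y`.
#' @param sl A [slide].
#' @return Data frame with columns `cell_id`, `spot_id`.
#' @export
snap_to_nearest_spot <- function(cell_coords, sl) {
  if (nrow(sl$coords) == 0) stop_nc("empty slide")
  if (is.data.frame(cell_coords) && "cell_id" %in% names(cell_coords)) {
    ids <- as.character(cell_coords$cell_id)
    xy <- as.matrix(cell_coords[, c("x", "y")])
  } else {
    xy <- as.matrix(cell_coords)[, 1:2, drop = FALSE]
    ids <- rownames(xy)
  }
  if (is.null(ids)) stop_nc("cell coordinates must carry cell ids")
  ord <- order(sl$coords$spot_id)
  sx <- sl$coords$x[ord]; sy <- sl$coords$y[ord]
  sid <- sl$coords$spot_id[ord]
  pick <- vapply(seq_len(nrow(xy)), function(i) {
    d2 <- (sx - xy[i, 1])^2 + (sy - xy[i, 2])^2
    which.min(d2) # first = lexicographically smallest spot id on ties
  }, integer(1))
  data.frame(cell_id = ids, spot_id = sid[pick], stringsAsFactors = FALSE)
}
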