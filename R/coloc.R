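#' Binary spot-presence matrix of cell types / spatial groups
#'
#' A spot scores 1 for a label if at least one cell carrying that label is
#' assigned to it.  Focal spatial groups (the annotation's `group` column,
#' where non-missing) replace their parent cell type as distinct columns.
#' All spots of the universe appear as rows, empty spots included.
#'
#' @param a Assignment data frame (`cell_id`, `spot_id`).
#' @param annotation Annotation data frame (`cell_id`, `cell_type`,
#'   optional `group`); must cover the assigned cells.
#' @param spot_ids Spot universe (row order of the result).
#' @return Binary spots x labels matrix.
#' @export
build_presence_matrix <- function(a, annotation, spot_ids) {
  missing <- setdiff(a$cell_id, annotation$cell_id)
  if (length(missing)) {
    stop_nc(sprintf(
      "%d assigned cells missing from annotation", length(missing)
    ))
  }
  lab <- setNames(annotation$cell_type, annotation$cell_id)
  if ("group" %in% names(annotation)) {
    has_grp <- !is.na(annotation$group)
    lab[annotation$cell_id[has_grp]] <- annotation$group[has_grp]
  }
  labels <- sort(unique(unname(lab)))
  P <- matrix(0L, length(spot_ids), length(labels),
    dimnames = list(spot_ids, labels)
  )
  cell_lab <- lab[a$cell_id]
  keep <- a$spot_id %in% spot_ids
  P[cbind(a$spot_id[keep], cell_lab[keep])] <- 1L
  P
}

#' Jaccard colocalization matrix from a presence matrix
#'
#' `J(A, B) = |spots(A) and spots(B)| / |spots(A) or spots(B)|`.  When both
#' presence sets are empty the value is defined as 0 and the pair is listed
#' in the `"empty_pairs"` attribute.
#'
#' @param p Binary spots x labels matrix.
#' @return Symmetric labels x labels matrix of Jaccard values in `[0, 1]`.
#' @export
jaccard_matrix <- function(p) {
  if (ncol(p) < 2) stop_nc("at least 2 type columns required")
  p <- (p > 0) + 0
  inter <- crossprod(p)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  empty <- which(uni == 0 & upper.tri(uni, diag = TRUE), arr.ind = TRUE)
  if (nrow(empty)) {
    attr(J, "empty_pairs") <- cbind(
      colnames(p)[empty[, 1]], colnames(p)[empty[, 2]]
    )
  }
  J
}

#' Fraction of focal spots shared with any other cell type
#'
#' @param p Binary spots x labels presence matrix.
#' @param focal Focal column name.
#' @return Fraction in `[0, 1]` of focal-occupied spots that also host at
#'   least one cell of another label.
#' @export
spot_sharing_fraction <- function(p, focal) {
  if (!focal %in% colnames(p)) stop_nc("focal column not present")
  occ <- p[, focal] > 0
  if (!any(occ)) stop_nc("focal column is all-zero")
  others <- p[, colnames(p) != focal, drop = FALSE]
  mean(rowSums(others[occ, , drop = FALSE]) > 0)
}

#' Spearman rank correlation with average-rank ties
#'
#' `rho` is the Pearson correlation of the average-rank vectors; the
#' p-value uses the t approximation with `n - 2` degrees of freedom.  A
#' constant vector yields `rho = NA` with `defined = FALSE`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return List with `rho`, `p`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_nc("length mismatch")
  n <- length(x)
  if (n < 3) stop_nc("at least 3 observations required")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' Concordance between communication counts and colocalization
#'
#' For each focal group, the Spearman correlation between its per-partner
#' significant-interaction counts and its per-partner Jaccard
#' colocalization.  The focal group itself is excluded from the partner
#' list; sibling focal groups are included by default.
#'
#' @param counts Output of [count_significant()].
#' @param coloc Jaccard matrix from [jaccard_matrix()].
#' @param focal_groups Focal group labels.
#' @param include_siblings Keep the other focal groups as partners
#'   (default TRUE).
#' @return A list of class `concordance_report`: per focal group a list with
#'   `partners`, `counts`, `jaccard`, `rho`, `p`, `n`.
#' @export
concordance <- function(counts, coloc, focal_groups,
                        include_siblings = TRUE) {
  out <- list()
  for (f in focal_groups) {
    partners <- setdiff(colnames(coloc), f)
    if (!include_siblings) partners <- setdiff(partners, focal_groups)
    partners <- intersect(partners, unique(counts$partner[counts$focal == f]))
    if (length(partners) < 3) stop_nc("fewer than 3 shared partners")
    cnt <- setNames(
      counts$count[counts$focal == f][match(
        partners, counts$partner[counts$focal == f]
      )],
      partners
    )
    jac <- coloc[f, partners]
    sp <- spearman_cor(cnt, jac)
    out[[f]] <- list(
      partners = partners, counts = cnt, jaccard = jac,
      rho = sp$rho, p = sp$p, n = sp$n
    )
  }
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  for (f in names(x)) {
    cat(sprintf(
      "  %s: rho=%.3f (p=%.3g, n=%d partners)\n", f, x[[f]]$rho, x[[f]]$p,
      x[[f]]$n
    ))
  }
  invisible(x)
}

#' Subsample groups to the minimum group size
#'
#' Builds `n_datasets` label subsets in which every group is downsampled
#' without replacement to the size of the smallest group.  Datasets are
#' pairwise distinct when combinatorially possible (rejection sampling with
#' a capped number of attempts, then duplicates are accepted with a
#' warning).
#'
#' @param groups Named vector (cell id -> group label) with at least 2
#'   groups, none empty.
#' @param n_datasets Number of subsampled datasets (default 10).
#' @param seed Integer seed.
#' @return List of named group vectors (subsets of `groups`).
#' @export
subsample_equalize <- function(groups, n_datasets = 10, seed = 1) {
  groups <- groups[!is.na(groups)]
  tab <- table(groups)
  if (length(tab) < 2) stop_nc("at least 2 groups required")
  if (any(tab == 0)) stop_nc("a group has size 0")
  m <- min(tab)
  by_group <- split(names(groups), as.character(groups))
  if (all(tab == m)) {
    # no subsampling possible: every dataset is the full labeling
    return(replicate(n_datasets, groups[sort(names(groups))],
      simplify = FALSE
    ))
  }
  with_seed_(seed, {
    seen <- character(0)
    out <- vector("list", n_datasets)
    for (d in seq_len(n_datasets)) {
      attempt <- 0
      repeat {
        attempt <- attempt + 1
        cells <- sort(unlist(lapply(by_group, function(cc) {
          if (length(cc) == m) cc else sample(cc, m)
        })))
        sig <- paste(cells, collapse = "\r")
        if (!(sig %in% seen) || attempt >= 1000) {
          if (sig %in% seen) {
            warning("duplicate subsampled dataset accepted", call. = FALSE)
          }
          seen <- c(seen, sig)
          out[[d]] <- groups[cells]
          break
        }
      }
    }
    out
  })
}
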