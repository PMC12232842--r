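# internal: per-group mean normalized expression (and optionally expressed
# fractions) for a gene subset.  groups: factor aligned with columns.
group_stats <- function(expr, groups, with_fracs = FALSE) {
  G <- levels(groups)
  ind <- vapply(G, function(g) as.numeric(groups == g), numeric(length(groups)))
  sizes <- colSums(ind)
  means <- (expr %*% ind) / rep(sizes, each = nrow(expr))
  fracs <- if (with_fracs) {
    ((expr > 0) %*% ind) / rep(sizes, each = nrow(expr))
  }
  list(means = means, fracs = fracs, sizes = sizes)
}

# internal: min-over-components value per interaction x group given per-gene
# group means; interactions with any absent component yield 0.  `side` is the
# precomputed component index structure from prep_ccc.
complex_values <- function(means, side) {
  n_int <- length(side$present)
  val <- matrix(0, n_int, ncol(means))
  ok <- side$present & side$single
  if (any(ok)) val[ok, ] <- means[side$first_idx[ok], , drop = FALSE]
  for (i in which(side$present & !side$single)) {
    mm <- means[side$idx[[i]], , drop = FALSE]
    val[i, ] <- do.call(pmin, lapply(seq_len(nrow(mm)), function(r) mm[r, ]))
  }
  val
}

# same structure for the expressed-fraction gate (all components > expr_prop)
complex_gate <- function(fracs, side, expr_prop) {
  n_int <- length(side$present)
  gate <- matrix(FALSE, n_int, ncol(fracs))
  ok <- side$present & side$single
  if (any(ok)) gate[ok, ] <- fracs[side$first_idx[ok], , drop = FALSE] > expr_prop
  for (i in which(side$present & !side$single)) {
    ff <- fracs[side$idx[[i]], , drop = FALSE]
    gate[i, ] <- colSums(ff > expr_prop) == nrow(ff)
  }
  gate
}

# index one side (ligand or receptor) of an LR database against gene rownames
index_side <- function(components, genes) {
  idx <- lapply(components, function(comp) match(comp, genes))
  present <- !vapply(idx, anyNA, logical(1))
  single <- lengths(components) == 1
  first_idx <- vapply(idx, `[`, numeric(1), 1)
  list(idx = idx, present = present, single = single, first_idx = first_idx)
}

#' Group mean expression and expressed-fraction gate for a gene complex
#'
#' Per component gene: mean normalized expression over the group's cells
#' and the fraction of cells expressing it (> 0).  The complex value is the
#' minimum of the component means; the gate is true iff every component is
#' expressed in more than `expr_prop` of the group's cells.  Component genes
#' absent from the matrix give value 0, gate false, with a warning.
#'
#' @param expr Genes x cells matrix of normalized expression (or a [gem]
#'   with a `norm` layer).
#' @param cells Cell ids of the group.
#' @param components Character vector of component gene ids (non-empty).
#' @param expr_prop Expressed-fraction threshold (default 0.1).
#' @return List with `value` and `gate`.
#' @export
group_mean_expression <- function(expr, cells, components, expr_prop = 0.1) {
  if (inherits(expr, "gem")) {
    if (is.null(expr$norm)) stop_nc("gem input needs a norm layer")
    expr <- expr$norm
  }
  if (length(components) == 0) stop_nc("components must be non-empty")
  present <- components %in% rownames(expr)
  if (!all(present)) {
    warning(sprintf(
      "component genes absent from matrix: %s",
      paste(components[!present], collapse = ", ")
    ), call. = FALSE)
    return(list(value = 0, gate = FALSE))
  }
  sub <- expr[components, cells, drop = FALSE]
  means <- rowMeans(sub)
  fracs <- rowMeans(sub > 0)
  list(value = min(means), gate = all(fracs > expr_prop))
}

#' Observed ligand-receptor interaction scores across group pairs
#'
#' For every ordered (sender, receiver) pair of eligible groups and every
#' interaction: `score = (ligand complex value in sender + receptor complex
#' value in receiver) / 2`, with the expressed-fraction gate required on
#' both sides.  Groups with fewer than `min_cells` cells are excluded with a
#' warning.  Autocrine pairs (sender == receiver) are included.
#'
#' @param expr Genes x cells normalized matrix or [gem] with `norm`.
#' @param groups Named vector (cell id -> group label).
#' @param lrdb An [lr_database()].
#' @param expr_prop Expressed-fraction gate threshold (default 0.1).
#' @param min_cells Minimum group size (default 10).
#' @return Data frame with columns `sender`, `receiver`, `interaction_id`,
#'   `score`, `gate`.
#' @export
score_interactions <- function(expr, groups, lrdb, expr_prop = 0.1,
                               min_cells = 10) {
  prep <- prep_ccc(expr, groups, lrdb, min_cells)
  data.frame(
    sender = prep$pairs$sender, receiver = prep$pairs$receiver,
    interaction_id = prep$pairs$interaction_id,
    score = ccc_scores(prep, prep$groups),
    gate = gate_pairs(prep, expr_prop),
    stringsAsFactors = FALSE
  )
}

# internal shared preparation for observed scoring and permutations
prep_ccc <- function(expr, groups, lrdb, min_cells) {
  if (inherits(expr, "gem")) {
    if (is.null(expr$norm)) stop_nc("gem input needs a norm layer")
    expr <- expr$norm
  }
  groups <- groups[!is.na(groups)]
  # canonical cell order so permutation draws, hence p-values, do not
  # depend on the input column order
  common <- sort(intersect(colnames(expr), names(groups)))
  expr <- expr[, common, drop = FALSE]
  groups <- factor(as.character(groups[common]))
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning(sprintf(
      "groups below min_cells excluded: %s", paste(small, collapse = ", ")
    ), call. = FALSE)
    keep <- !(groups %in% small)
    expr <- expr[, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) == 0) stop_nc("no eligible groups")
  genes <- unique(unlist(c(lrdb$ligand_components, lrdb$receptor_components)))
  genes <- intersect(genes, rownames(expr))
  G <- levels(groups)
  nG <- length(G)
  n_int <- nrow(lrdb)
  pairs <- expand.grid(
    sender = G, receiver = G,
    interaction_id = lrdb$interaction_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # flat (interaction, sender, receiver) index vectors in pairs order:
  # sender varies fastest, then receiver, then interaction
  i_snd <- rep(rep(seq_len(nG), times = nG), times = n_int)
  i_rcv <- rep(rep(seq_len(nG), each = nG), times = n_int)
  i_int <- rep(seq_len(n_int), each = nG * nG)
  list(
    expr = expr[genes, , drop = FALSE], groups = groups, lrdb = lrdb,
    genes = genes, G = G, pairs = pairs,
    lig_side = index_side(lrdb$ligand_components, genes),
    rec_side = index_side(lrdb$receptor_components, genes),
    i_snd = i_snd, i_rcv = i_rcv, i_int = i_int
  )
}

# internal: flat score vector in prep$pairs order for an arbitrary labeling
ccc_scores <- function(prep, labels) {
  means <- group_stats(prep$expr, labels)$means
  ligV <- complex_values(means, prep$lig_side)
  recV <- complex_values(means, prep$rec_side)
  (ligV[cbind(prep$i_int, prep$i_snd)] +
    recV[cbind(prep$i_int, prep$i_rcv)]) / 2
}

# expressed-fraction gate, flat in prep$pairs order, on the observed labels
gate_pairs <- function(prep, expr_prop) {
  fracs <- group_stats(prep$expr, prep$groups, with_fracs = TRUE)$fracs
  ligG <- complex_gate(fracs, prep$lig_side, expr_prop)
  recG <- complex_gate(fracs, prep$rec_side, expr_prop)
  ligG[cbind(prep$i_int, prep$i_snd)] & recG[cbind(prep$i_int, prep$i_rcv)]
}

#' Permutation significance of ligand-receptor interactions
#'
#' Group labels are permuted over all cells `n_perm` times (seeded); for
#' every (sender, receiver, interaction) triple the p-value is
#' `(1 + #\{permuted score >= observed\}) / (n_perm + 1)`.  Gated-out
#' triples carry p = 1.  With `mode = "exhaustive"` (two groups only) all
#' distinct label arrangements are enumerated and
#' `p = #\{arrangements with score >= observed\} / n_arrangements`.
#'
#' @inheritParams score_interactions
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance threshold on p (default 0.05).
#' @param seed Integer seed.
#' @param mode `"sampled"` (default) or `"exhaustive"`.
#' @return Data frame of class `ccc_result` with columns `sender`,
#'   `receiver`, `interaction_id`, `score`, `gate`, `pval`, `significant`;
#'   metadata in attributes (`n_perm`, `expr_prop`, `alpha`, `seed`).
#' @export
permutation_pvalues <- function(expr, groups, lrdb, n_perm = 1000,
                                expr_prop = 0.1, min_cells = 10,
                                alpha = 0.05, seed = 1,
                                mode = c("sampled", "exhaustive")) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop_nc("n_perm must be at least 1")
  prep <- prep_ccc(expr, groups, lrdb, min_cells)
  obs <- ccc_scores(prep, prep$groups)
  gate <- gate_pairs(prep, expr_prop)
  n_cells <- ncol(prep$expr)

  if (mode == "exhaustive") {
    if (length(prep$G) != 2) {
      stop_nc("exhaustive mode supports exactly 2 groups")
    }
    n1 <- sum(prep$groups == prep$G[1])
    sets <- combn(n_cells, n1)
    ge <- numeric(length(obs))
    for (k in seq_len(ncol(sets))) {
      lab <- factor(rep(prep$G[2], n_cells), levels = prep$G)
      lab[sets[, k]] <- prep$G[1]
      ge <- ge + (ccc_scores(prep, lab) >= obs)
    }
    pval <- ge / ncol(sets)
    n_used <- ncol(sets)
  } else {
    ge <- numeric(length(obs))
    with_seed_(seed, {
      for (k in seq_len(n_perm)) {
        lab <- prep$groups[sample.int(n_cells)]
        ge <- ge + (ccc_scores(prep, lab) >= obs)
      }
    })
    pval <- (1 + ge) / (n_perm + 1)
    n_used <- n_perm
  }
  pval[!gate] <- 1
  out <- data.frame(
    sender = prep$pairs$sender, receiver = prep$pairs$receiver,
    interaction_id = prep$pairs$interaction_id,
    score = obs, gate = gate, pval = pval,
    stringsAsFactors = FALSE
  )
  out$significant <- out$gate & out$pval < alpha
  attr(out, "n_perm") <- n_used
  attr(out, "expr_prop") <- expr_prop
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  class(out) <- c("ccc_result", "data.frame")
  out
}

#' Count significant interactions per focal group and partner
#'
#' @param ccc A `ccc_result` (from [permutation_pvalues()] or
#'   [ingest_external_ccc()]).
#' @param focal_groups Character vector of focal group labels present in the
#'   result.
#' @param direction_mode `"both_summed"` (default: focal as sender plus
#'   focal as receiver), `"sender_only"` or `"receiver_only"`.
#' @return Data frame `focal`, `partner`, `count` covering every partner
#'   label in the result (zero counts included).
#' @export
count_significant <- function(ccc, focal_groups,
                              direction_mode = c(
                                "both_summed", "sender_only", "receiver_only"
                              )) {
  direction_mode <- match.arg(direction_mode)
  labels <- sort(unique(c(ccc$sender, ccc$receiver)))
  missing <- setdiff(focal_groups, labels)
  if (length(missing)) {
    stop_nc(sprintf(
      "unknown focal groups: %s", paste(missing, collapse = ", ")
    ))
  }
  sig <- ccc[ccc$significant, , drop = FALSE]
  out <- expand.grid(
    focal = focal_groups, partner = labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out$count <- mapply(function(f, p) {
    as_sender <- sum(sig$sender == f & sig$receiver == p)
    as_receiver <- sum(sig$receiver == f & sig$sender == p)
    switch(direction_mode,
      both_summed = as_sender + as_receiver,
      sender_only = as_sender,
      receiver_only = as_receiver
    )
  }, out$focal, out$partner)
  out
}

#' Ingest an externally computed cell-cell communication table
#'
#' Reads a long-format TSV with source/target/interaction/p columns (names
#' remappable through `dialect`), normalizes it into a `ccc_result` with
#' gate true and no scores, and recomputes significance at `alpha`.
#'
#' @param path Path to the TSV file.
#' @param dialect Named character vector mapping the required names
#'   (`source`, `target`, `interaction`, `p`) to the file's column names.
#' @param alpha Significance threshold (default 0.05).
#' @return A `ccc_result` data frame.
#' @export
ingest_external_ccc <- function(path,
                                dialect = c(
                                  source = "source", target = "target",
                                  interaction = "interaction", p = "p"
                                ),
                                alpha = 0.05) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "interaction", "p")
  cols <- dialect[need]
  if (any(is.na(cols)) || !all(cols %in% names(df))) {
    stop_nc("missing mapped columns in external CCC table")
  }
  key <- paste(df[[cols["source"]]], df[[cols["target"]]],
    df[[cols["interaction"]]],
    sep = "\r"
  )
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop_nc(sprintf(
      "duplicate (source, target, interaction) rows: %s",
      paste(gsub("\r", "/", head(dups, 5)), collapse = "; ")
    ))
  }
  out <- data.frame(
    sender = as.character(df[[cols["source"]]]),
    target = as.character(df[[cols["target"]]]),
    interaction_id = as.character(df[[cols["interaction"]]]),
    score = NA_real_, gate = TRUE,
    pval = as.numeric(df[[cols["p"]]]),
    stringsAsFactors = FALSE
  )
  names(out)[2] <- "receiver"
  out$significant <- out$pval < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("ccc_result", "data.frame")
  out
}

#' @rdname permutation_pvalues
#' @param ccc A `ccc_result`.
#' @param path Output TSV path.
#' @export
write_ccc <- function(ccc, path) {
  write.table(as.data.frame(ccc), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
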