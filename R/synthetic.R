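#' Configuration for the synthetic paired dataset generator
#'
#' Describes a spot grid with named rectangular regions, cell types with
#' per-region abundance weights, negative-binomial expression with per-type
#' marker signatures, optional niche-dependent expression shifts of stated
#' log2 fold change, and planted ligand-receptor activity that is either
#' restricted to spatially colocalized type pairs (`"coupled"`) or applied
#' independently of space (`"decoupled"`).
#'
#' @param type_names Character vector of cell type names.
#' @param cells_per_type Integer scalar (recycled) or vector of cell counts
#'   per type.
#' @param focal_type The type stratified into spatial groups downstream.
#' @param grid `c(n_rows, n_cols)` spot lattice.
#' @param spacing Lattice spacing in slide units.
#' @param regions Named list; each element
#'   `list(rows = c(r1, r2), cols = c(c1, c2), weights = c(type = w, ...))`.
#'   Types absent from `weights` get weight 0 in that region.
#' @param cells_per_spot_range `c(min, max)` cells a spot can host
#'   (default `c(1, 9)`, the Visium-scale span).
#' @param n_base_genes Number of background genes.
#' @param n_markers_per_type Exclusive marker genes per type.
#' @param signature_strength Log-mean offset of marker genes over baseline.
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline
#'   negative-binomial means.
#' @param nb_dispersion NB size parameter theta (variance `mu + mu^2/theta`).
#' @param niche_effect List of plantings, each
#'   `list(cell_type =, region =, n_genes =, log2fc =)`; planted genes get
#'   their NB mean multiplied by `2^log2fc` for cells of `cell_type` whose
#'   true spot lies in `region`.
#' @param lr_edges Data frame with columns `sender`, `receiver`, `n_interactions`:
#'   planted communication edges (one ligand/receptor gene pair is created
#'   per interaction).
#' @param n_lr_decoys Additional inactive interactions in the LR database.
#' @param lr_base_mean,lr_active_mean NB mean of ligand/receptor genes at
#'   baseline and in the active sender/receiver type.
#' @param coupling_mode `"coupled"` or `"decoupled"` (see above).
#' @param noise_rate Poisson rate of extra counts per spot-matrix entry.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(type_names, cells_per_type, focal_type,
                             grid, regions, spacing = 1,
                             cells_per_spot_range = c(1, 9),
                             n_base_genes = 100, n_markers_per_type = 10,
                             signature_strength = 1.6,
                             base_meanlog = log(1.5), base_sdlog = 0.6,
                             nb_dispersion = 8,
                             niche_effect = list(),
                             lr_edges = NULL, n_lr_decoys = 10,
                             lr_base_mean = 0.01, lr_active_mean = 3,
                             coupling_mode = c("coupled", "decoupled"),
                             noise_rate = 0.1, seed = 1) {
  coupling_mode <- match.arg(coupling_mode)
  if (length(cells_per_type) == 1) {
    cells_per_type <- rep(cells_per_type, length(type_names))
  }
  stopifnot(
    length(cells_per_type) == length(type_names),
    all(cells_per_type >= 1),
    focal_type %in% type_names,
    length(grid) == 2, all(grid >= 1),
    length(cells_per_spot_range) == 2,
    cells_per_spot_range[1] >= 1,
    cells_per_spot_range[2] >= cells_per_spot_range[1],
    nb_dispersion > 0, noise_rate >= 0
  )
  for (rg in regions) {
    w <- rg$weights
    if (any(w < 0) || sum(w) == 0) {
      stop_nc("region abundance weights must be >= 0 and not all zero")
    }
  }
  for (ne in niche_effect) {
    if (!is.finite(ne$log2fc)) stop_nc("niche log2fc must be finite")
  }
  structure(
    list(
      type_names = type_names,
      cells_per_type = setNames(as.integer(cells_per_type), type_names),
      focal_type = focal_type, grid = as.integer(grid), spacing = spacing,
      regions = regions, cells_per_spot_range = as.integer(cells_per_spot_range),
      n_base_genes = n_base_genes, n_markers_per_type = n_markers_per_type,
      signature_strength = signature_strength,
      base_meanlog = base_meanlog, base_sdlog = base_sdlog,
      nb_dispersion = nb_dispersion, niche_effect = niche_effect,
      lr_edges = lr_edges, n_lr_decoys = n_lr_decoys,
      lr_base_mean = lr_base_mean, lr_active_mean = lr_active_mean,
      coupling_mode = coupling_mode, noise_rate = noise_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

region_of_spots <- function(cfg) {
  nr <- cfg$grid[1]; nc_ <- cfg$grid[2]
  row_idx <- rep(seq_len(nr), each = nc_)
  col_idx <- rep(seq_len(nc_), times = nr)
  region <- rep(NA_character_, nr * nc_)
  for (nm in names(cfg$regions)) {
    rg <- cfg$regions[[nm]]
    inside <- row_idx >= rg$rows[1] & row_idx <= rg$rows[2] &
      col_idx >= rg$cols[1] & col_idx <= rg$cols[2]
    region[inside & is.na(region)] <- nm
  }
  list(row = row_idx, col = col_idx, region = region)
}

#' Generate a paired single-cell + spot-level dataset with planted truth
#'
#' Draws spot capacities, places cells into spots region by region according
#' to the configured abundance weights, simulates negative-binomial counts
#' from per-type gene signatures with the configured niche-dependent shifts
#' and ligand-receptor activity, and aggregates spot expression.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `cells` ([gem]), `slide` ([slide] whose
#'   `spot_expr` is the aggregated spot matrix and whose coordinate table
#'   carries region labels), `annotation` (cell_id/cell_type/group data
#'   frame), `lrdb` ([lr_database()]) and `truth` (list: `assignment`,
#'   `group` per focal cell, `deg` planted-DEG table, `active_edges`,
#'   `capacities`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  geo <- region_of_spots(cfg)
  n_spots <- length(geo$region)
  spot_ids <- sprintf("s%04d", seq_len(n_spots))
  coords <- data.frame(
    spot_id = spot_ids,
    x = (geo$col - 1) * cfg$spacing,
    y = (geo$row - 1) * cfg$spacing,
    region = geo$region,
    stringsAsFactors = FALSE
  )

  # per-spot capacity draws within the configured cells-per-spot span
  rng <- cfg$cells_per_spot_range
  capacity <- sample(seq(rng[1], rng[2]), n_spots, replace = TRUE)

  # region x type weight matrix
  types <- cfg$type_names
  W <- matrix(0, length(cfg$regions), length(types),
    dimnames = list(names(cfg$regions), types)
  )
  for (nm in names(cfg$regions)) {
    w <- cfg$regions[[nm]]$weights
    W[nm, names(w)] <- w
  }

  # place cells one by one (shuffled order) with prob ~ remaining capacity
  # times the type's weight in the spot's region
  cell_type <- rep(types, times = cfg$cells_per_type)
  n_cells <- length(cell_type)
  if (sum(capacity) < n_cells) {
    stop_nc("grid too small to host requested cells at drawn capacities")
  }
  cell_type <- sample(cell_type)
  cell_ids <- sprintf("c%05d", seq_len(n_cells))
  remaining <- capacity
  spot_region <- geo$region
  wt_by_spot <- function(ty) {
    w <- rep(0, n_spots)
    lab <- !is.na(spot_region)
    w[lab] <- W[spot_region[lab], ty]
    w
  }
  type_spot_w <- vapply(types, wt_by_spot, numeric(n_spots))
  assigned <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    p <- remaining * type_spot_w[, cell_type[i]]
    tot <- sum(p)
    if (tot <= 0) {
      stop_nc(sprintf(
        "grid too small: no remaining capacity for cells of type %s",
        cell_type[i]
      ))
    }
    s <- sample.int(n_spots, 1, prob = p)
    assigned[i] <- s
    remaining[s] <- remaining[s] - 1L
  }
  assignment <- data.frame(
    cell_id = cell_ids, spot_id = spot_ids[assigned],
    stringsAsFactors = FALSE
  )

  # focal spatial groups from the true spot's region
  focal <- cell_type == cfg$focal_type
  group <- rep(NA_character_, n_cells)
  group[focal] <- paste0(cfg$focal_type, "@", spot_region[assigned[focal]])
  annotation <- data.frame(
    cell_id = cell_ids, cell_type = cell_type, group = group,
    stringsAsFactors = FALSE
  )

  # gene panel: baseline + exclusive markers + niche plantings + LR genes
  base_ids <- sprintf("B%03d", seq_len(cfg$n_base_genes))
  marker_ids <- unlist(lapply(types, function(ty) {
    sprintf("MK.%s.%02d", ty, seq_len(cfg$n_markers_per_type))
  }))
  niche_gene_sets <- list()
  k <- 0
  for (j in seq_along(cfg$niche_effect)) {
    ne <- cfg$niche_effect[[j]]
    ids <- sprintf("NG%03d", k + seq_len(ne$n_genes))
    k <- k + ne$n_genes
    niche_gene_sets[[j]] <- ids
  }
  niche_ids <- unlist(niche_gene_sets)

  # LR interactions: one ligand/receptor gene pair per planted interaction,
  # plus inactive decoys
  edges <- cfg$lr_edges
  lr_tab <- NULL
  if (!is.null(edges) && nrow(edges) > 0) {
    lr_tab <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
      data.frame(
        sender = edges$sender[i], receiver = edges$receiver[i],
        idx = seq_len(edges$n_interactions[i]), stringsAsFactors = FALSE
      )
    }))
    lr_tab$interaction_id <- sprintf("I%03d", seq_len(nrow(lr_tab)))
  }
  n_active <- if (is.null(lr_tab)) 0L else nrow(lr_tab)
  n_int <- n_active + cfg$n_lr_decoys
  int_ids <- c(
    if (n_active) lr_tab$interaction_id,
    if (cfg$n_lr_decoys) sprintf("D%03d", seq_len(cfg$n_lr_decoys))
  )
  lig_ids <- sprintf("LG%03d", seq_len(n_int))
  rec_ids <- sprintf("RC%03d", seq_len(n_int))
  lrdb <- if (n_int > 0) lr_database(int_ids, lig_ids, rec_ids) else NULL

  all_genes <- c(base_ids, marker_ids, niche_ids, lig_ids, rec_ids)

  # per-type NB mean matrix
  base_mean <- rlnorm(length(c(base_ids, marker_ids, niche_ids)),
    meanlog = cfg$base_meanlog, sdlog = cfg$base_sdlog
  )
  mu_type <- matrix(c(base_mean, rep(cfg$lr_base_mean, 2 * n_int)),
    nrow = length(all_genes), ncol = length(types),
    dimnames = list(all_genes, types)
  )
  for (ty in types) {
    mk <- sprintf("MK.%s.%02d", ty, seq_len(cfg$n_markers_per_type))
    mu_type[mk, ty] <- mu_type[mk, ty] * exp(cfg$signature_strength)
  }

  # planted LR activity: in coupled mode only for type pairs sharing >= 1
  # true spot; in decoupled mode for every planted edge
  active_edges <- NULL
  if (n_active > 0) {
    share_spot <- function(t1, t2) {
      length(intersect(
        assignment$spot_id[cell_type == t1],
        assignment$spot_id[cell_type == t2]
      )) >= 1
    }
    act <- if (cfg$coupling_mode == "decoupled") {
      rep(TRUE, n_active)
    } else {
      mapply(share_spot, lr_tab$sender, lr_tab$receiver)
    }
    for (i in which(act)) {
      mu_type[lig_ids[i], lr_tab$sender[i]] <- cfg$lr_active_mean
      mu_type[rec_ids[i], lr_tab$receiver[i]] <- cfg$lr_active_mean
    }
    active_edges <- lr_tab[act, c("sender", "receiver", "interaction_id")]
    rownames(active_edges) <- NULL
  }

  # per-cell means, then niche multipliers for focal cells in named regions
  mu <- mu_type[, cell_type, drop = FALSE]
  colnames(mu) <- cell_ids
  deg_tab <- NULL
  for (j in seq_along(cfg$niche_effect)) {
    ne <- cfg$niche_effect[[j]]
    gset <- niche_gene_sets[[j]]
    in_cells <- cell_type == ne$cell_type &
      !is.na(spot_region[assigned]) & spot_region[assigned] == ne$region
    mu[gset, in_cells] <- mu[gset, in_cells] * 2^ne$log2fc
    deg_tab <- rbind(deg_tab, data.frame(
      gene = gset, log2fc = ne$log2fc, cell_type = ne$cell_type,
      region = ne$region, stringsAsFactors = FALSE
    ))
  }

  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  cells <- gem(counts)

  spot_expr <- aggregate_spot_expression(cells, assignment, spot_ids,
    noise_rate = cfg$noise_rate
  )
  sl <- slide(coords, spot_expr = spot_expr)

  truth <- list(
    assignment = assignment,
    group = setNames(group[focal], cell_ids[focal]),
    deg = deg_tab,
    active_edges = active_edges,
    capacities = setNames(capacity, spot_ids)
  )
  list(
    cells = cells, slide = sl, annotation = annotation, lrdb = lrdb,
    truth = truth, config = cfg
  )
}

#' Aggregate single-cell counts into spot-level expression
#'
#' Each spot column is the per-gene sum of its constituent cells' counts,
#' plus independent Poisson(`noise_rate`) extra counts per entry.  Spots
#' hosting no cells yield all-zero columns.  With `noise_rate = 0` the grand
#' total of the spot matrix equals the grand total of the assigned cells.
#'
#' @param cells A [gem] of single-cell counts.
#' @param assignment Data frame with columns `cell_id`, `spot_id`; every
#'   assigned cell must exist in `cells`.
#' @param spot_ids Character vector defining the spot universe (column
#'   order of the result).
#' @param noise_rate Poisson rate of extra counts per entry (default 0).
#' @return A [gem] over spots.
#' @export
aggregate_spot_expression <- function(cells, assignment, spot_ids,
                                      noise_rate = 0) {
  if (!all(assignment$cell_id %in% cell_ids(cells))) {
    stop_nc("assignment references cells absent from the matrix")
  }
  out <- matrix(0,
    nrow = nrow(cells$counts), ncol = length(spot_ids),
    dimnames = list(gene_ids(cells), spot_ids)
  )
  if (nrow(assignment) > 0) {
    sub <- cells$counts[, assignment$cell_id, drop = FALSE]
    agg <- t(rowsum(t(sub), group = assignment$spot_id))
    out[, colnames(agg)] <- agg
  }
  if (noise_rate > 0) {
    out <- out + matrix(rpois(length(out), noise_rate), nrow = nrow(out))
  }
  gem(out)
}

#' Scenario presets for the three tissue archetypes
#'
#' `breast_like`: disjoint region blocks, a focal tumor-like type present in
#' two regions with four colocalized partner types of graded abundance and
#' four spatially disjoint types, plus planted ligand-receptor edges whose
#' per-partner counts are rank-orthogonal to the colocalization gradient
#' (so the decoupled variant is a stable negative control).
#' `layered_like`: a focal neuron-like type spanning three contiguous bands
#' with band-specific neighbors and band-specific planted gene programs
#' (the substrate for spatially weighted co-expression grouping).
#' `node_like`: one region dominated (>50 percent of its cells) by a single
#' fibroblast-like type.
#'
#' @param name One of `"breast_like"`, `"layered_like"`, `"node_like"`.
#' @param seed Integer seed stored in the config.
#' @param coupling_mode `"coupled"` (default) or `"decoupled"`.
#' @return A [synthetic_config()].
#' @export
scenario_preset <- function(name = c("breast_like", "layered_like", "node_like"),
                            seed = 1,
                            coupling_mode = c("coupled", "decoupled")) {
  name <- match.arg(name)
  coupling_mode <- match.arg(coupling_mode)
  if (name == "breast_like") {
    types <- c(
      "Cancer", "Tcell", "Myeloid", "Endothelial", "CAF",
      "Bcell", "Plasma", "Epithelial", "PVL"
    )
    ncells <- c(120, 100, 70, 45, 30, 45, 45, 45, 45)
    shared <- c(Cancer = 1, Tcell = 1, Myeloid = 1, Endothelial = 1, CAF = 1)
    distal <- c(Bcell = 1, Plasma = 1, Epithelial = 1, PVL = 1)
    regions <- list(
      R1 = list(rows = c(1, 12), cols = c(1, 4), weights = shared),
      R2 = list(rows = c(1, 12), cols = c(5, 8), weights = shared),
      R3 = list(rows = c(1, 12), cols = c(9, 12), weights = distal)
    )
    # planted significant-interaction counts per partner, chosen so their
    # ranks are orthogonal to the expected colocalization ranking
    # (Tcell > Myeloid > Endothelial > CAF > disjoint types = sibling group)
    # when all partners, including the sibling focal group, are in the list
    lr_edges <- data.frame(
      sender = "Cancer",
      receiver = c(
        "Tcell", "Myeloid", "Endothelial", "CAF",
        "Bcell", "Plasma", "Epithelial", "PVL"
      ),
      n_interactions = c(3, 4, 8, 7, 2, 5, 6, 9),
      stringsAsFactors = FALSE
    )
    synthetic_config(
      type_names = types, cells_per_type = ncells, focal_type = "Cancer",
      grid = c(12, 12), regions = regions,
      niche_effect = list(
        list(cell_type = "Cancer", region = "R1", n_genes = 25, log2fc = 1.5)
      ),
      lr_edges = lr_edges, n_lr_decoys = 16,
      coupling_mode = coupling_mode, seed = seed
    )
  } else if (name == "layered_like") {
    types <- c("L5", "L4", "Astro", "L6", "Endo")
    ncells <- c(180, 70, 70, 70, 50)
    everywhere <- c(L5 = 1, Endo = 0.4)
    regions <- list(
      outer = list(rows = c(1, 3), cols = c(1, 10),
                   weights = c(everywhere, L4 = 2)),
      middle = list(rows = c(4, 6), cols = c(1, 10),
                    weights = c(everywhere, Astro = 2)),
      inner = list(rows = c(7, 9), cols = c(1, 10),
                   weights = c(everywhere, L6 = 2))
    )
    lr_edges <- data.frame(
      sender = "L5", receiver = c("L4", "Astro", "L6", "Endo"),
      n_interactions = c(6, 4, 6, 3), stringsAsFactors = FALSE
    )
    synthetic_config(
      type_names = types, cells_per_type = ncells, focal_type = "L5",
      grid = c(9, 10), regions = regions,
      niche_effect = list(
        list(cell_type = "L5", region = "outer", n_genes = 15, log2fc = 2),
        list(cell_type = "L5", region = "middle", n_genes = 15, log2fc = 2),
        list(cell_type = "L5", region = "inner", n_genes = 15, log2fc = 2)
      ),
      lr_edges = lr_edges, n_lr_decoys = 10,
      coupling_mode = coupling_mode, seed = seed
    )
  } else {
    types <- c("Fibro", "aCM", "Endo", "Myeloid", "Neural")
    ncells <- c(160, 80, 60, 50, 30)
    regions <- list(
      node = list(rows = c(4, 8), cols = c(4, 8),
                  weights = c(Fibro = 8, Endo = 0.5, Myeloid = 0.5,
                              Neural = 0.5)),
      myocardium = list(rows = c(1, 11), cols = c(1, 11),
                        weights = c(Fibro = 1, aCM = 3, Endo = 1,
                                    Myeloid = 1, Neural = 0.3))
    )
    lr_edges <- data.frame(
      sender = "Fibro", receiver = c("aCM", "Endo", "Myeloid"),
      n_interactions = c(5, 4, 3), stringsAsFactors = FALSE
    )
    synthetic_config(
      type_names = types, cells_per_type = ncells, focal_type = "Fibro",
      grid = c(11, 11), regions = regions,
      niche_effect = list(
        list(cell_type = "Fibro", region = "node", n_genes = 20, log2fc = 1.5)
      ),
      lr_edges = lr_edges, n_lr_decoys = 10,
      coupling_mode = coupling_mode, seed = seed
    )
  }
}

#' Simulate a two-group negative-binomial count matrix with planted DEGs
#'
#' A direct two-group simulator (no spatial structure) used to calibrate and
#' validate the differential-expression stages: baseline gene means are
#' log-normal, both groups share them except for `n_planted` genes whose
#' group-1 mean is multiplied by `2^log2fc`.
#'
#' @param n_genes Total genes.
#' @param n_per_group Cells per group.
#' @param n_planted Number of planted DEGs (first `n_planted` genes).
#' @param log2fc Planted log2 fold change (group 1 over group 2).
#' @param nb_dispersion NB size theta.
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline means.
#' @param seed Integer seed.
#' @return List with `m` ([gem]), `groups` (factor of length `2*n_per_group`)
#'   and `planted` (gene ids).
#' @export
simulate_two_group_counts <- function(n_genes, n_per_group, n_planted = 0,
                                      log2fc = 0, nb_dispersion = 8,
                                      base_meanlog = log(2), base_sdlog = 0.5,
                                      seed = 1) {
  with_seed_(seed, {
    gids <- sprintf("g%04d", seq_len(n_genes))
    cids <- sprintf("c%04d", seq_len(2 * n_per_group))
    groups <- factor(rep(c("g1", "g2"), each = n_per_group))
    mu <- rlnorm(n_genes, base_meanlog, base_sdlog)
    mu1 <- mu
    planted <- character(0)
    if (n_planted > 0) {
      planted <- gids[seq_len(n_planted)]
      mu1[seq_len(n_planted)] <- mu1[seq_len(n_planted)] * 2^log2fc
    }
    mumat <- cbind(
      matrix(mu1, n_genes, n_per_group),
      matrix(mu, n_genes, n_per_group)
    )
    dimnames(mumat) <- list(gids, cids)
    counts <- matrix(rnbinom(length(mumat), mu = mumat, size = nb_dispersion),
      nrow = n_genes, dimnames = dimnames(mumat)
    )
    list(m = gem(counts), groups = setNames(groups, cids), planted = planted)
  })
}

#' Simulate two spatially segregated co-expression gene blocks
#'
#' Cells sit in two spatial clusters; block-A genes are elevated in cluster
#' 1, block-B genes in cluster 2, on top of independent noise.  Used to
#' validate spatially weighted correlation, module detection and module
#' scoring against planted membership.
#'
#' @param n_per_cluster Cells per spatial cluster.
#' @param n_per_block Genes per block.
#' @param shift Elevation (log-scale units) of a block in its home cluster.
#' @param noise_sd Standard deviation of the per-cell noise.
#' @param cluster_sep Distance between the cluster centers.
#' @param seed Integer seed.
#' @return List with `expr` (genes x cells matrix of log-scale values),
#'   `coords` (cells x 2), `blocks` (named list of gene ids) and `cluster`
#'   (integer vector per cell).
#' @export
simulate_module_blocks <- function(n_per_cluster = 40, n_per_block = 15,
                                   shift = 1, noise_sd = 0.5,
                                   cluster_sep = 10, seed = 1) {
  with_seed_(seed, {
    n_cells <- 2 * n_per_cluster
    cluster <- rep(1:2, each = n_per_cluster)
    coords <- cbind(
      x = rnorm(n_cells, mean = c(0, cluster_sep)[cluster], sd = 1),
      y = rnorm(n_cells, sd = 1)
    )
    rownames(coords) <- sprintf("c%03d", seq_len(n_cells))
    blockA <- sprintf("A%02d", seq_len(n_per_block))
    blockB <- sprintf("B%02d", seq_len(n_per_block))
    gids <- c(blockA, blockB)
    expr <- matrix(rnorm(length(gids) * n_cells, sd = noise_sd),
      nrow = length(gids), dimnames = list(gids, rownames(coords))
    )
    expr[blockA, cluster == 1] <- expr[blockA, cluster == 1] + shift
    expr[blockB, cluster == 2] <- expr[blockB, cluster == 2] + shift
    list(
      expr = expr, coords = coords,
      blocks = list(A = blockA, B = blockB), cluster = cluster
    )
  })
}

#' Write a generated dataset to a directory in the package's file formats
#'
#' Emits the sparse count matrix with label files, spot coordinates with
#' region labels, the annotation and true assignment tables, the LR database
#' and the truth tables, plus the configuration as YAML.
#'
#' @param ds Result of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_counts(ds$cells, p("matrix.mtx"), p("genes.tsv"), p("barcodes.tsv"))
  write_counts(
    ds$slide$spot_expr, p("spot_matrix.mtx"), p("spot_genes.tsv"),
    p("spot_barcodes.tsv")
  )
  write_spot_coords(ds$slide, p("spots.tsv"))
  write_annotation(ds$annotation, p("annotation.tsv"))
  write_assignment(ds$truth$assignment, p("true_assignment.tsv"))
  if (!is.null(ds$lrdb)) write_lr_database(ds$lrdb, p("lr_database.csv"))
  if (!is.null(ds$truth$deg)) {
    write.table(ds$truth$deg, p("truth_deg.tsv"),
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  if (!is.null(ds$truth$active_edges)) {
    write.table(ds$truth$active_edges, p("truth_lr_edges.tsv"),
      sep = "\t",
      quote = FALSE, row.names = FALSE
    )
  }
  cfg <- ds$config
  cfg$niche_effect <- lapply(cfg$niche_effect, function(x) x)
  write_config(unclass(cfg)[!vapply(unclass(cfg), is.data.frame, TRUE)],
    p("config.yaml"))
  invisible(dir)
}
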