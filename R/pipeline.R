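#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()] with its default.
#' Defaults follow the package-wide conventions: counts-per-10,000
#' natural-log normalization, expressed-fraction gate 0.1, permutation count
#' 1000, significance threshold 0.05, linear fold-change gate 1.5 for the
#' Wilcoxon branch and log2 gate 1.5 for the pseudobulk branch, 3
#' pseudoreplicates, 10 subsampled datasets.  QC thresholds here are scaled
#' to the synthetic presets; for real Visium-scale slides use
#' [qc_filter_spots()] defaults.
#'
#' @param preset Scenario preset name (see [scenario_preset()]).
#' @param seed Integer master seed (generator and all stage seeds derive
#'   from it).
#' @param coupling_mode `"coupled"` or `"decoupled"` planted communication.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param assignment `"map"` (capacity-constrained expression mapping) or
#'   `"truth"` (use the generator's true assignment).
#' @param grouping `"region"` or `"scoexp"`; `NULL` picks `"scoexp"` for
#'   the layered preset and `"region"` otherwise.
#' @param target_sum,log_base Normalization parameters.
#' @param qc Named list: `min_counts`, `max_counts`, `max_mito_pct`,
#'   `min_spots_per_gene`, `mito_prefix`.
#' @param hvg_n_map Number of spot-matrix HVGs used for mapping.
#' @param scoexp Named list: `k`, `min_size`, `sigma` (`NULL` = median
#'   distance), `n_genes` (focal HVGs fed to the weighted correlation),
#'   `n_bins`, `n_controls`.
#' @param deg Named list: `fc_threshold` (linear, Wilcoxon),
#'   `lfc_threshold` (log2, pseudobulk), `alpha`, `n_reps`.
#' @param ccc Named list: `n_perm`, `alpha`, `expr_prop`, `min_cells`.
#' @param subsample_n Number of equal-size subsampled datasets for the CCC
#'   robustness control (0 disables it).
#' @param do_distances,do_deg,do_subsample Stage switches.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "breast_like", seed = 1,
                            coupling_mode = "coupled", out_dir = NULL,
                            assignment = c("map", "truth"),
                            grouping = NULL,
                            target_sum = 1e4, log_base = "e",
                            qc = list(
                              min_counts = 200, max_counts = 1e6,
                              max_mito_pct = 20, min_spots_per_gene = 3,
                              mito_prefix = "MT-"
                            ),
                            hvg_n_map = 150,
                            scoexp = list(
                              k = 3, min_size = 10, sigma = NULL,
                              n_genes = 80, n_bins = 24, n_controls = 100
                            ),
                            deg = list(
                              fc_threshold = 1.5, lfc_threshold = 1.5,
                              alpha = 0.05, n_reps = 3
                            ),
                            ccc = list(
                              n_perm = 1000, alpha = 0.05, expr_prop = 0.1,
                              min_cells = 10
                            ),
                            subsample_n = 10,
                            do_distances = TRUE, do_deg = TRUE,
                            do_subsample = TRUE) {
  assignment <- match.arg(assignment)
  if (is.null(grouping)) {
    grouping <- if (preset == "layered_like") "scoexp" else "region"
  }
  structure(
    list(
      preset = preset, seed = as.integer(seed),
      coupling_mode = coupling_mode,
      out_dir = out_dir, assignment = assignment, grouping = grouping,
      target_sum = target_sum, log_base = log_base, qc = qc,
      hvg_n_map = hvg_n_map, scoexp = scoexp, deg = deg, ccc = ccc,
      subsample_n = subsample_n, do_distances = do_distances,
      do_deg = do_deg, do_subsample = do_subsample
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes simulate -> assign -> group -> distances/DEG -> permutation CCC
#' (with optional equal-size subsampling reruns) -> colocalization ->
#' concordance, optionally writing every table plus a JSON summary and a
#' run log (no timestamps, so fixed-seed reruns are byte-identical).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage outputs (`dataset`,
#'   `assignment`, `groups`, `distances`, `deg`, `ccc`, `counts`,
#'   `presence`, `jaccard`, `concordance`, `subsample`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  res <- tryCatch(
    run_pipeline_impl(config, function(s) stage <<- s),
    error = function(e) {
      stop_nc(sprintf("pipeline failed at stage %s: %s", stage,
                      conditionMessage(e)))
    }
  )
  invisible(res)
}

run_pipeline_impl <- function(config, set_stage) {
  scfg <- scenario_preset(config$preset,
    seed = config$seed,
    coupling_mode = config$coupling_mode
  )
  ds <- generate_dataset(scfg)
  focal_type <- scfg$focal_type
  ann <- ds$annotation

  set_stage("normalize")
  cells <- normalize_log(ds$cells,
    target_sum = config$target_sum,
    base = config$log_base
  )
  spots_qc <- do.call(qc_filter_spots, c(list(ds$slide$spot_expr), config$qc))
  spots_qc <- normalize_log(spots_qc,
    target_sum = config$target_sum,
    base = config$log_base
  )
  spot_universe <- cell_ids(spots_qc)

  set_stage("map")
  if (config$assignment == "truth") {
    a <- ds$truth$assignment
    a <- a[a$spot_id %in% spot_universe, , drop = FALSE]
  } else {
    caps <- estimate_spot_capacities(spots_qc, ncol(cells$counts))
    hvg <- select_hvg(spots_qc, config$hvg_n_map)
    a <- map_cells_to_spots(cells, spots_qc, caps, hvg)
  }

  set_stage("group")
  if (config$grouping == "region") {
    grp <- split_by_region(a, ds$slide, ann, focal_type)
    grp[] <- paste0(focal_type, "@", grp)
  } else {
    focal_cells <- intersect(
      ann$cell_id[ann$cell_type == focal_type], a$cell_id
    )
    fmat <- gem_subset(cells, cells = focal_cells)
    cand <- select_hvg(fmat, config$scoexp$n_genes)
    coord_map <- ds$slide$coords
    rownames(coord_map) <- coord_map$spot_id
    spot_of <- setNames(a$spot_id, a$cell_id)[focal_cells]
    coords <- as.matrix(coord_map[spot_of, c("x", "y")])
    cc <- spatially_weighted_correlation(
      fmat$norm[cand, , drop = FALSE], coords,
      sigma = config$scoexp$sigma
    )
    mods <- detect_modules(cc,
      k = config$scoexp$k,
      min_size = config$scoexp$min_size
    )
    sc <- score_modules(fmat, mods,
      n_bins = config$scoexp$n_bins,
      n_controls = config$scoexp$n_controls,
      seed = config$seed + 101L
    )
    grp <- assign_by_max_score(sc)
    grp[] <- paste0(focal_type, "@", grp)
  }
  sizes <- sort(table(grp), decreasing = TRUE)
  if (length(sizes) < 2) stop_nc("fewer than 2 spatial groups for the focal type")
  g_top <- names(sizes)[order(-sizes, names(sizes))][1:2]
  focal_groups <- sort(g_top)

  # labels for CCC / presence: focal cells carry their spatial group, other
  # cells their type; ungrouped focal cells are excluded
  labels <- setNames(ann$cell_type, ann$cell_id)
  labels[ann$cell_id[ann$cell_type == focal_type]] <- NA
  labels[names(grp)] <- grp
  ann_grp <- ann
  ann_grp$group <- unname(grp[ann$cell_id])

  dist_res <- NULL
  if (isTRUE(config$do_distances)) {
    set_stage("distances")
    bg <- labels
    bg[!is.na(bg) & !(bg %in% focal_groups)] <- "background"
    dist_res <- pairwise_cosine_distances(
      cells, bg,
      comparisons = list(
        within_1 = focal_groups[1],
        within_2 = focal_groups[2],
        between = focal_groups,
        background = c(focal_groups[1], "background")
      )
    )
    dist_res$ks <- list(
      within1_vs_between = ks_compare(
        dist_res$samples$within_1, dist_res$samples$between
      ),
      within2_vs_between = ks_compare(
        dist_res$samples$within_2, dist_res$samples$between
      )
    )
  }

  deg_res <- NULL
  if (isTRUE(config$do_deg)) {
    set_stage("deg")
    two <- grp[grp %in% focal_groups]
    deg_res <- list(
      wilcoxon = deg_wilcoxon(cells, two,
        fc_threshold = config$deg$fc_threshold,
        alpha = config$deg$alpha
      ),
      pseudobulk = pseudobulk_deg(
        make_pseudobulk(cells, two,
          n_reps = config$deg$n_reps,
          seed = config$seed + 202L
        ),
        lfc_threshold = config$deg$lfc_threshold,
        alpha = config$deg$alpha
      )
    )
  }

  set_stage("ccc")
  ccc <- permutation_pvalues(cells, labels, ds$lrdb,
    n_perm = config$ccc$n_perm, expr_prop = config$ccc$expr_prop,
    min_cells = config$ccc$min_cells, alpha = config$ccc$alpha,
    seed = config$seed + 303L
  )
  counts <- count_significant(ccc, focal_groups)

  subs <- NULL
  if (isTRUE(config$do_subsample) && config$subsample_n > 0) {
    set_stage("subsample")
    two <- grp[grp %in% focal_groups]
    datasets <- subsample_equalize(two,
      n_datasets = config$subsample_n,
      seed = config$seed + 404L
    )
    sub_counts <- lapply(seq_along(datasets), function(d) {
      lab_d <- labels
      drop_focal <- setdiff(names(grp), names(datasets[[d]]))
      lab_d[drop_focal] <- NA
      ccc_d <- suppressWarnings(permutation_pvalues(
        cells, lab_d, ds$lrdb,
        n_perm = config$ccc$n_perm, expr_prop = config$ccc$expr_prop,
        min_cells = config$ccc$min_cells, alpha = config$ccc$alpha,
        seed = config$seed + 404L + d
      ))
      count_significant(ccc_d, intersect(
        focal_groups, unique(c(ccc_d$sender, ccc_d$receiver))
      ))
    })
    # per focal group and partner: dispersion across the subsampled datasets
    all_sub <- do.call(rbind, sub_counts)
    subs <- aggregate(count ~ focal + partner, all_sub, function(v) {
      c(min = min(v), median = median(v), max = max(v))
    })
    subs <- cbind(subs[1:2], as.data.frame(subs$count))
  }

  set_stage("coloc")
  presence <- build_presence_matrix(a, ann_grp, spot_universe)
  jac <- jaccard_matrix(presence)
  sharing <- vapply(
    focal_groups,
    function(f) spot_sharing_fraction(presence, f), numeric(1)
  )

  set_stage("concordance")
  conc <- concordance(counts, jac, focal_groups)

  summary <- list(
    preset = config$preset, seed = config$seed,
    coupling_mode = config$coupling_mode,
    n_cells = ncol(ds$cells$counts), n_spots_qc = length(spot_universe),
    focal_groups = focal_groups,
    group_sizes = as.list(sizes[focal_groups]),
    spearman = lapply(conc, function(x) list(rho = x$rho, p = x$p, n = x$n)),
    n_significant_interactions = sum(ccc$significant),
    sharing_fraction = as.list(sharing)
  )
  if (!is.null(dist_res)) {
    summary$median_cosine <- as.list(dist_res$medians)
  }
  if (!is.null(deg_res)) {
    summary$n_deg_wilcoxon <- sum(deg_res$wilcoxon$significant)
    summary$n_deg_pseudobulk <- sum(deg_res$pseudobulk$significant,
      na.rm = TRUE
    )
  }

  res <- list(
    dataset = ds, assignment = a, groups = grp, distances = dist_res,
    deg = deg_res, ccc = ccc, counts = counts, presence = presence,
    jaccard = jac, concordance = conc, subsample = subs, summary = summary
  )

  if (!is.null(config$out_dir)) {
    set_stage("write")
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_assignment(a, p("assignment.tsv"))
    write.table(
      data.frame(cell_id = names(grp), group = unname(grp)),
      p("groups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_ccc(ccc, p("ccc.tsv"))
    write.table(counts, p("ccc_counts.tsv"),
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    write.table(cbind(spot_id = rownames(presence), as.data.frame(presence)),
      p("presence.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(cbind(type = rownames(jac), as.data.frame(jac)),
      p("jaccard.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (!is.null(deg_res)) {
      write_deg_table(deg_res$wilcoxon, p("deg_wilcoxon.tsv"))
      write_deg_table(deg_res$pseudobulk, p("deg_pseudobulk.tsv"))
    }
    if (!is.null(subs)) {
      write.table(subs, p("subsample_counts.tsv"),
        sep = "\t", quote = FALSE,
        row.names = FALSE
      )
    }
    jsonlite::write_json(summary, p("summary.json"),
      auto_unbox = TRUE,
      digits = NA, pretty = TRUE
    )
    writeLines(
      c(
        sprintf("nichecomm %s", as.character(utils::packageVersion("nichecomm"))),
        sprintf("preset: %s", config$preset),
        sprintf("coupling_mode: %s", config$coupling_mode),
        sprintf("seed: %d", config$seed),
        sprintf("stage seeds: scoexp=%d deg=%d ccc=%d subsample=%d",
                config$seed + 101L, config$seed + 202L,
                config$seed + 303L, config$seed + 404L)
      ),
      p("run_log.txt")
    )
  }
  res
}
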