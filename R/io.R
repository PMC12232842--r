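#' Read a gene x cell count matrix
#'
#' Reads either a Matrix Market coordinate file accompanied by one-id-per-line
#' gene and cell label files, or a dense TSV (gene rows, cell columns, first
#' column gene id, header row of cell ids).
#'
#' @param matrix_path Path to the `.mtx` file or dense TSV.
#' @param gene_label_path,cell_label_path Paths to label files (one id per
#'   line); required for Matrix Market input, ignored for dense TSV.
#' @return A [gem] with counts attached in file order and no normalization.
#' @export
read_counts <- function(matrix_path, gene_label_path = NULL,
                        cell_label_path = NULL) {
  first <- readLines(matrix_path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    if (is.null(gene_label_path) || is.null(cell_label_path)) {
      stop_nc("Matrix Market input requires gene and cell label files")
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    genes <- readLines(gene_label_path)
    cells <- readLines(cell_label_path)
    if (length(genes) != nrow(m)) {
      stop_nc(sprintf(
        "gene label file has %d ids but matrix declares %d rows",
        length(genes), nrow(m)
      ))
    }
    if (length(cells) != ncol(m)) {
      stop_nc(sprintf(
        "cell label file has %d ids but matrix declares %d columns",
        length(cells), ncol(m)
      ))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    df <- read.delim(matrix_path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
  }
  gem(m)
}

#' Write a count matrix as Matrix Market plus label files
#'
#' @param m A [gem].
#' @param matrix_path,gene_label_path,cell_label_path Output paths.
#' @return Invisibly, the matrix path.
#' @export
write_counts <- function(m, matrix_path, gene_label_path, cell_label_path) {
  sm <- Matrix::Matrix(m$counts, sparse = TRUE)
  Matrix::writeMM(sm, matrix_path)
  writeLines(gene_ids(m), gene_label_path)
  writeLines(cell_ids(m), cell_label_path)
  invisible(matrix_path)
}

#' Read spot coordinates (and optional region labels)
#'
#' Expects a TSV with header `spot_id`, `x`, `y` and optionally `region`.
#'
#' @param path Path to the TSV file.
#' @return A [slide] without expression.
#' @export
read_spot_coords <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(df))) {
    stop_nc("coordinate table must have columns spot_id, x, y")
  }
  slide(df)
}

#' @rdname read_spot_coords
#' @param sl A [slide].
#' @export
write_spot_coords <- function(sl, path) {
  write.table(sl$coords, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a cell annotation table
#'
#' TSV with header `cell_id`, `cell_type` and optionally `group` (spatial
#' group labels for the focal type).
#'
#' @param path Path to the TSV file.
#' @param expr Optional [gem]; when given, every annotated cell must be a
#'   column of it.
#' @return Data frame with columns `cell_id`, `cell_type` and, when present
#'   in the file, `group`.
#' @export
read_annotation <- function(path, expr = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% names(df))) {
    stop_nc("annotation table must have columns cell_id, cell_type")
  }
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) stop_nc("duplicate cell ids in annotation")
  if (!is.null(expr) && !all(df$cell_id %in% cell_ids(expr))) {
    stop_nc("annotation references cells absent from the expression matrix")
  }
  df
}

#' @rdname read_annotation
#' @param ann Annotation data frame.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-to-spot assignment table
#'
#' TSV with header `cell_id`, `spot_id`.  Accepts the output of external
#' mapping tools as long as it is reduced to this two-column dialect.
#'
#' @param path Path to the TSV file.
#' @param sl Optional [slide]; when given, every spot id must exist on it.
#' @return Data frame with columns `cell_id`, `spot_id`.
#' @export
read_assignment <- function(path, sl = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "spot_id") %in% names(df))) {
    stop_nc("assignment table must have columns cell_id, spot_id")
  }
  df$cell_id <- as.character(df$cell_id)
  df$spot_id <- as.character(df$spot_id)
  if (anyDuplicated(df$cell_id)) stop_nc("a cell is assigned to several spots")
  if (!is.null(sl)) {
    unknown <- setdiff(df$spot_id, sl$coords$spot_id)
    if (length(unknown)) {
      stop_nc(sprintf(
        "assignment references unknown spot ids: %s",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
  }
  df
}

#' @rdname read_assignment
#' @param a Assignment data frame.
#' @export
write_assignment <- function(a, path) {
  write.table(a[, c("cell_id", "spot_id")], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a ligand-receptor interaction database
#'
#' CSV with header `interaction_id`, `ligand`, `receptor`.  Multi-subunit
#' complexes are encoded with `_`-joined gene ids.
#'
#' @param path Path to the CSV file.
#' @param sep Subunit separator (default `"_"`).
#' @return Data frame of class `lrdb` with columns `interaction_id`,
#'   `ligand`, `receptor` plus list columns `ligand_components`,
#'   `receptor_components`.
#' @export
read_lr_database <- function(path, sep = "_") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("interaction_id", "ligand", "receptor") %in% names(df))) {
    stop_nc("LR database must have columns interaction_id, ligand, receptor")
  }
  lr_database(df$interaction_id, df$ligand, df$receptor, sep = sep)
}

#' Construct a ligand-receptor database from vectors
#'
#' @param interaction_id Unique interaction ids.
#' @param ligand,receptor `_`-joined component gene ids.
#' @param sep Subunit separator.
#' @return An `lrdb` data frame; see [read_lr_database()].
#' @export
lr_database <- function(interaction_id, ligand, receptor, sep = "_") {
  if (anyDuplicated(interaction_id)) stop_nc("duplicate interaction ids")
  lig <- strsplit(as.character(ligand), sep, fixed = TRUE)
  rec <- strsplit(as.character(receptor), sep, fixed = TRUE)
  if (any(lengths(lig) == 0) || any(lengths(rec) == 0)) {
    stop_nc("empty component lists in LR database")
  }
  out <- data.frame(
    interaction_id = as.character(interaction_id),
    ligand = as.character(ligand),
    receptor = as.character(receptor),
    stringsAsFactors = FALSE
  )
  out$ligand_components <- lig
  out$receptor_components <- rec
  class(out) <- c("lrdb", "data.frame")
  out
}

#' @rdname read_lr_database
#' @param lrdb An `lrdb` object.
#' @export
write_lr_database <- function(lrdb, path) {
  write.table(lrdb[, c("interaction_id", "ligand", "receptor")], path,
    sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Map gene ids through an ortholog table
#'
#' Renames genes by a two-column (source_id, target_id) table.  Genes absent
#' from the table are dropped (count reported); several source genes mapping
#' to one target are collapsed by summing counts; a source gene listed with
#' several targets keeps only its first target in table order.  The
#' normalized layer, if any, is dropped (log values cannot be summed) and
#' must be recomputed.
#'
#' @param m A [gem].
#' @param table Data frame whose first two columns are source and target ids.
#' @return A [gem] with remapped gene ids.
#' @export
map_orthologs <- function(m, table) {
  if (!is.data.frame(table) || ncol(table) < 2 || nrow(table) == 0) {
    stop_nc("ortholog table must be a non-empty two-column data frame")
  }
  src <- as.character(table[[1]])
  tgt <- as.character(table[[2]])
  keep_first <- !duplicated(src)
  if (any(!keep_first)) {
    nc_msg(sprintf(
      "map_orthologs: %d one-to-many source genes reduced to their first target",
      sum(!keep_first)
    ))
  }
  map <- setNames(tgt[keep_first], src[keep_first])
  present <- gene_ids(m) %in% names(map)
  n_drop <- sum(!present)
  if (n_drop > 0) {
    nc_msg(sprintf("map_orthologs: dropped %d unmapped genes", n_drop))
  }
  if (!any(present)) stop_nc("no genes could be mapped")
  counts <- m$counts[present, , drop = FALSE]
  new_ids <- unname(map[rownames(counts)])
  collapsed <- rowsum(counts, group = new_ids, reorder = FALSE)
  gem(collapsed)
}

#' Read a nested key-value configuration file (YAML)
#'
#' @param path Path to the YAML file.
#' @return A named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param cfg A named list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
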