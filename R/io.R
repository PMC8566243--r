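# On-disk formats.
#
# Expression matrices travel either as MatrixMarket MTX (1-based on disk, per
# the format standard) with two companion newline-delimited id files, or as
# dense CSV/TSV with the first column holding row ids and the header holding
# gene ids. Integer data round-trips bit-exactly through both.

#' Read an expression matrix
#'
#' @param path For `"csv"`/`"tsv"`: the file. For `"mtx"`: the `.mtx` file;
#'   row ids are read from `row_ids` and column ids from `col_ids` (defaults:
#'   the mtx path with suffixes `.rows.txt` / `.cols.txt` replacing `.mtx`).
#' @param format `"csv"`, `"tsv"` or `"mtx"`; guessed from the extension when
#'   missing.
#' @param type `"sc"` (rows are cells) or `"spatial"` (rows are voxels).
#' @param row_ids,col_ids Optional id-file paths for MTX input.
#' @return An `sc_matrix` or `spatial_matrix`.
#' @export
read_expression <- function(path, format = NULL, type = c("sc", "spatial"),
                            row_ids = NULL, col_ids = NULL) {
  type <- match.arg(type)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", mtx = "mtx",
                     stop("cannot guess format of ", path, call. = FALSE))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]][-1L]
    if (anyDuplicated(header))
      stop("duplicate gene columns in ", path, ": ",
           paste(unique(header[duplicated(header)]), collapse = ", "),
           call. = FALSE)
    dt <- data.table::fread(path, sep = sep, header = TRUE)
    ids <- as.character(dt[[1L]])
    vals <- as.matrix(dt[, -1L, drop = FALSE])
    genes <- header
  } else {
    m <- Matrix::readMM(path)
    stem <- sub("\\.mtx$", "", path)
    row_ids <- row_ids %||% paste0(stem, ".rows.txt")
    col_ids <- col_ids %||% paste0(stem, ".cols.txt")
    ids <- readLines(row_ids)
    genes <- readLines(col_ids)
    if (length(ids) != nrow(m) || length(genes) != ncol(m))
      stop(sprintf("MTX dims %dx%d do not match id files (%d rows, %d cols)",
                   nrow(m), ncol(m), length(ids), length(genes)),
           call. = FALSE)
    vals <- as.matrix(m)
  }
  rownames(vals) <- ids
  colnames(vals) <- genes
  if (type == "sc") sc_matrix(vals) else spatial_matrix(vals)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; MTX output writes the two companion id
#' files next to the matrix.
#'
#' @param m An `sc_matrix` or `spatial_matrix` (or a plain named matrix).
#' @param path Output path; extension selects the format unless given.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = NULL) {
  vals <- if (is.list(m)) m$values else as.matrix(m)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", mtx = "mtx",
                     stop("cannot guess format of ", path, call. = FALSE))
  if (format %in% c("csv", "tsv")) {
    dt <- data.table::data.table(id = rownames(vals))
    dt <- cbind(dt, data.table::as.data.table(vals))
    data.table::fwrite(dt, path, sep = if (format == "csv") "," else "\t")
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(vals), paste0(stem, ".rows.txt"))
    writeLines(colnames(vals), paste0(stem, ".cols.txt"))
  }
  invisible(path)
}

#' Read a per-cell annotation/label table
#'
#' CSV with an id column (first column) and one or more annotation columns.
#'
#' @param path CSV path.
#' @return data.frame with column `id` first.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  df <- as.data.frame(dt)
  names(df)[1L] <- "id"
  df$id <- as.character(df$id)
  df
}

#' Run the full mapping pipeline from a configuration
#'
#' Executes marker selection, gene-panel intersection, fitting, annotation
#' projection and (optionally) evaluation from a single configuration list
#' (or YAML file), writing all artifacts to an output directory: the mapping
#' matrix (MTX + ids), the filter, the loss trace, projections, score tables
#' and the resolved configuration, so that a run is regenerable from its
#' artifact directory alone.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `sc`, `spatial` (paths or in-memory containers), `labels` (CSV path,
#'   optional when `sc` carries labels), `mode` (`"targeted"`, `"spots"`,
#'   `"deconvolve"`), `seg_counts` (CSV path or numeric vector),
#'   `density` (`"uniform"`, `"segmentation"` or a CSV path), `panel`
#'   (file with one gene per line, optional), `top_k` (markers per type,
#'   default 100), `epochs`, `lr`, `seed`, `lambda_r1`, `weights`,
#'   `evaluate` (logical: leave-one-out scores), `out` (output directory).
#' @return Invisibly, a list with the `mapping_result`, the panel, and paths
#'   of written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    mode = "spots", top_k = 100L, epochs = NULL, lr = 0.1, seed = 0L,
    lambda_r1 = 0, weights = c(1, 1, 1), evaluate = FALSE, out = NULL),
    config)

  load_side <- function(x, type) {
    if (inherits(x, c("sc_matrix", "spatial_matrix"))) return(x)
    if (!is.character(x) || !file.exists(x))
      stop("stage input: cannot read ", type, " matrix from ",
           if (is.character(x)) x else class(x)[1L], call. = FALSE)
    read_expression(x, type = type)
  }
  sc <- load_side(cfg$sc, "sc")
  sp <- load_side(cfg$spatial, "spatial")
  if (!is.null(cfg$labels) && is.character(cfg$labels)) {
    lab <- read_annotations(cfg$labels)
    sc$labels <- as.character(lab[[2L]][match(sc$cell_ids, lab$id)])
  }

  rep <- validate_inputs(sc, sp)
  if (!rep$pass)
    stop("stage validation: ", paste(rep$violations, collapse = "; "),
         call. = FALSE)

  # training panel: explicit file, or marker selection from labels
  if (!is.null(cfg$panel)) {
    panel <- if (is.character(cfg$panel) && length(cfg$panel) == 1L &&
                 file.exists(cfg$panel)) readLines(cfg$panel)
             else as.character(cfg$panel)
  } else if (!is.null(sc$labels)) {
    ranking <- rank_markers(preprocess_for_markers(sc), labels = sc$labels)
    panel <- training_panel(ranking, k = cfg$top_k, sp = sp)
  } else {
    panel <- NULL   # all shared genes
  }
  aligned <- intersect_genes(sc, sp, panel)

  seg <- NULL
  if (!is.null(cfg$seg_counts)) {
    seg <- if (is.character(cfg$seg_counts))
      read_annotations(cfg$seg_counts)[[2L]] else as.numeric(cfg$seg_counts)
  }
  setup <- switch(cfg$mode,
    targeted = mode_targeted(aligned$sc, aligned$sp),
    deconvolve = {
      if (is.null(seg)) stop("stage setup: deconvolve mode needs seg_counts",
                             call. = FALSE)
      mode_deconvolution(aligned$sc, aligned$sp, seg)
    },
    spots = list(
      mode = "plain", n_target_cells = NULL,
      d = if (!is.null(seg)) density_from_segmentation(seg)
          else uniform_density(nrow(aligned$sp$values))),
    stop("stage setup: unknown mode ", cfg$mode, call. = FALSE))
  if (!is.null(cfg$density) && is.character(cfg$density) &&
      file.exists(cfg$density))
    setup$d <- density_prior(read_annotations(cfg$density)[[2L]])

  epochs <- cfg$epochs %||% default_epochs(
    switch(cfg$mode, targeted = "targeted", spots = "spots",
           deconvolve = "deconvolution"))
  fit <- fit_mapping(aligned$sc, aligned$sp, setup$d, mode = setup$mode,
                     n_target_cells = setup$n_target_cells, epochs = epochs,
                     lr = cfg$lr, seed = cfg$seed, weights = cfg$weights,
                     lambda_r1 = cfg$lambda_r1)

  artifacts <- list()
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out, f)
    write_expression(fit$M, p("mapping.mtx"))
    data.table::fwrite(fit$loss_trace, p("loss_trace.csv"))
    if (!is.null(fit$f))
      data.table::fwrite(data.table::data.table(cell_id = sc$cell_ids,
                                                f = fit$f), p("filter.csv"))
    if (!is.null(sc$labels)) {
      proj <- project_annotations(fit, one_hot_labels(sc$labels, sc$cell_ids))
      write_expression(proj$values, p("celltype_projection.csv"))
    }
    writeLines(aligned$genes, p("panel.txt"))
    yaml::write_yaml(c(cfg[setdiff(names(cfg), c("sc", "spatial"))],
                       list(mode_resolved = setup$mode, epochs_resolved = epochs,
                            n_target_cells = setup$n_target_cells)),
                     p("config.yaml"))
    artifacts <- list(dir = cfg$out)
  }

  scores <- NULL
  if (isTRUE(cfg$evaluate)) {
    scores <- leave_one_out(aligned$sc, aligned$sp, setup$d, aligned$genes,
                            mode = setup$mode,
                            n_target_cells = setup$n_target_cells,
                            epochs = epochs, lr = cfg$lr, seed = cfg$seed)
    if (!is.null(cfg$out))
      data.table::fwrite(scores, file.path(cfg$out, "gene_scores.csv"))
  }

  invisible(list(fit = fit, panel = aligned$genes, scores = scores,
                 artifacts = artifacts))
}
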