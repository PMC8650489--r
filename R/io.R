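# Plain-text persistence: TSV for matrices/time series/partitions/hub
# tables, JSON for designs and reports.

#' Write / read ROI time series as TSV
#'
#' Rows are ROIs (first column `roi`), remaining columns are volumes named
#' `V<original index>`; TR is stored in a `# tr_s=` comment on the first
#' line.
#'
#' @param ts A [roi_timeseries()].
#' @param path Output file.
#' @return `write_roi_timeseries_tsv` returns `path` invisibly;
#'   `read_roi_timeseries_tsv` returns a [roi_timeseries()].
#' @export
write_roi_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_s=%.17g", ts$tr_s), con)
  df <- data.frame(roi = ts$roi_names, ts$values, check.names = FALSE)
  colnames(df) <- c("roi", sprintf("V%d", ts$volume_index))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_timeseries_tsv
#' @export
read_roi_timeseries_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  tr_s <- if (startsWith(first, "# tr_s=")) as.numeric(sub("# tr_s=", "", first)) else 2.5
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  roi_timeseries(vals, roi_names = df[[1L]], tr_s = tr_s,
                 volume_index = as.integer(sub("^V", "", colnames(vals))))
}

#' Write / read a square adjacency or connectivity matrix as TSV
#'
#' @param w Symmetric matrix with node dimnames (a connectivity matrix or a
#'   `brain_graph`'s adjacency).
#' @param path Output file.
#' @return `read_adjacency_tsv` returns the named matrix.
#' @export
write_adjacency_tsv <- function(w, path) {
  if (inherits(w, "brain_graph")) w <- w$adjacency
  utils::write.table(
    data.frame(node = rownames(w), w, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @export
read_adjacency_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  w <- as.matrix(df[, -1L, drop = FALSE])
  rownames(w) <- df[[1L]]
  w
}

#' Write a synthetic cohort to disk
#'
#' One time-series TSV and one motion TSV per subject, a design JSON, and a
#' manifest TSV (`subject`, `group`, `ts_path`, `motion_path`) tying them
#' together.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param design The [make_block_design()] the cohort was simulated under.
#' @return Path of the manifest TSV, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir, design) {
  stopifnot(inherits(cohort, "cohort"), inherits(design, "task_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    ts_path <- file.path(dir, paste0(s$id, "_ts.tsv"))
    mo_path <- file.path(dir, paste0(s$id, "_motion.tsv"))
    write_roi_timeseries_tsv(s$ts, ts_path)
    utils::write.table(data.frame(motion_mm = s$motion), mo_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    data.frame(subject = s$id, group = s$group,
               ts_path = basename(ts_path), motion_path = basename(mo_path),
               stringsAsFactors = FALSE)
  })
  jsonlite::write_json(
    design[c("n_blocks", "task_s", "rest_s", "tr_s")],
    file.path(dir, "design.json"), auto_unbox = TRUE)
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort_tsv()]
#'
#' @param dir Directory containing `manifest.tsv`, `design.json` and the
#'   per-subject files.
#' @return List with `cohort` (class `cohort`) and `design`.
#' @export
read_cohort_tsv <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  dj <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  design <- make_block_design(dj$n_blocks, dj$task_s, dj$rest_s, dj$tr_s)
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$subject[i], group = manifest$group[i],
         ts = read_roi_timeseries_tsv(file.path(dir, manifest$ts_path[i])),
         motion = utils::read.table(file.path(dir, manifest$motion_path[i]),
                                    header = TRUE)$motion_mm)
  })
  class(cohort) <- "cohort"
  list(cohort = cohort, design = design)
}

#' Write a partition / hub table as TSV
#'
#' @param partition A [modular_partition()].
#' @param hubs A [classify_nodes()] table.
#' @param path Output file.
#' @export
write_partition_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "modular_partition"))
  utils::write.table(
    data.frame(node = partition$node_names,
               module = unname(partition$affiliation)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
write_hub_table_tsv <- function(hubs, path) {
  stopifnot(inherits(hubs, "hub_table"))
  utils::write.table(hubs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
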