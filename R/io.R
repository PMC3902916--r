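# Plain-text (TSV) readers and writers for pipeline inputs and fixtures.
# Numeric matrices are serialized with 17 significant digits so that a
# write/read round trip reproduces doubles bit-exactly.

.write_matrix <- function(m, path, row_label = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  txt <- apply(m, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  if (!is.matrix(txt)) txt <- matrix(txt, nrow = nrow(m))
  lines <- c(paste(c(row_label, colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
}

#' Read a gene-by-column numeric TSV matrix
#'
#' First column holds gene ids (row names); remaining columns are numeric,
#' with `NA` as the missing-value token.
#'
#' @param path File path.
#' @param sep Field delimiter; default tab.
#' @param na Missing-value token; default `"NA"`.
#' @param dec Decimal point; default `"."`.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path, sep = "\t", na = "NA", dec = ".") {
  df <- read.delim(path, sep = sep, na.strings = na, dec = dec,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read array metadata
#'
#' Expects columns `array_id`, `time_label`, `replicate`.
#'
#' @inheritParams read_matrix_tsv
#' @return Data frame.
#' @export
read_array_metadata <- function(path, sep = "\t") {
  meta <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("array_id", "time_label", "replicate") %in% names(meta)))
  meta
}

#' Write a synthetic data set to a fixture directory
#'
#' Emits every input the pipeline consumes (Log2Ratio and sample-channel
#' matrices, array metadata, functional annotation, sigma-factor id list
#' and prior table) plus ground-truth tables (true edges with kinetic
#' parameters, planted cluster labels, planted enrichment, true noise-free
#' profiles).
#'
#' @param dataset A `synthetic_dataset` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  .write_matrix(dataset$arrays$log2ratio, fp("log2ratio.tsv"))
  .write_matrix(dataset$arrays$sample_signal, fp("sample_signal.tsv"))
  write.table(dataset$arrays$meta, fp("array_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$grid, fp("time_grid.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$annotation, fp("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(dataset$sigma_ids, fp("sigma_ids.txt"))
  if (!is.null(dataset$priors))
    write.table(dataset$priors, fp("priors.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  .write_matrix(dataset$profiles, fp("true_profiles.tsv"))
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    for (cc in c("k1", "k2", "w", "b"))
      truth[[cc]] <- sprintf("%.17g", truth[[cc]])
    write.table(truth, fp("truth_edges.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  cl <- data.frame(gene_id = names(dataset$cluster_labels),
                   cluster = ifelse(is.na(dataset$cluster_labels), "NA",
                                    dataset$cluster_labels),
                   stringsAsFactors = FALSE)
  write.table(cl, fp("truth_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$planted_enrichment, fp("truth_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()].
#' @return List mirroring the fields of a `synthetic_dataset` (without the
#'   generating spec).
#' @export
read_fixture <- function(dir) {
  fp <- function(f) file.path(dir, f)
  grid_df <- read.delim(fp("time_grid.tsv"), stringsAsFactors = FALSE)
  grid <- time_grid(grid_df$label, grid_df$hours)
  truth <- NULL
  if (file.exists(fp("truth_edges.tsv"))) {
    truth <- read.delim(fp("truth_edges.tsv"), stringsAsFactors = FALSE)
    for (cc in c("k1", "k2", "w", "b")) truth[[cc]] <- as.numeric(truth[[cc]])
  }
  cl <- read.delim(fp("truth_clusters.tsv"), na.strings = "NA",
                   stringsAsFactors = FALSE)
  priors <- if (file.exists(fp("priors.tsv")))
    read.delim(fp("priors.tsv"), stringsAsFactors = FALSE) else NULL
  list(grid = grid,
       arrays = list(log2ratio = read_matrix_tsv(fp("log2ratio.tsv")),
                     sample_signal = read_matrix_tsv(fp("sample_signal.tsv")),
                     meta = read_array_metadata(fp("array_metadata.tsv"))),
       annotation = read.delim(fp("annotation.tsv"),
                               stringsAsFactors = FALSE),
       sigma_ids = readLines(fp("sigma_ids.txt")),
       priors = priors,
       profiles = read_matrix_tsv(fp("true_profiles.tsv")),
       truth = truth,
       cluster_labels = setNames(cl$cluster, cl$gene_id),
       planted_enrichment = read.delim(fp("truth_enrichment.tsv"),
                                       stringsAsFactors = FALSE))
}

#' Write a profile set to TSV files
#'
#' Writes the profile matrix plus companion CV and replicate-count matrices
#' next to it (`<stem>.tsv`, `<stem>_cv.tsv`, `<stem>_n.tsv`).
#'
#' @param profiles A `profile_set`.
#' @param stem Path stem (without extension).
#' @return The main path, invisibly.
#' @export
write_profiles <- function(profiles, stem) {
  .write_matrix(profiles$values, paste0(stem, ".tsv"))
  if (!is.null(profiles$cv)) .write_matrix(profiles$cv,
                                           paste0(stem, "_cv.tsv"))
  if (!is.null(profiles$n_used)) {
    m <- profiles$n_used
    storage.mode(m) <- "double"
    .write_matrix(m, paste0(stem, "_n.tsv"))
  }
  invisible(paste0(stem, ".tsv"))
}
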