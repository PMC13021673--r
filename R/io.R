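# Plain-text readers/writers and the end-to-end pipeline. Dialects are
# pinned: comma-separated matrices/tables, tab-separated metadata and edge
# lists, UTF-8, LF line endings, "." decimal separator; floating values are
# printed at fixed 9-digit precision so reruns are byte-identical.

HEMI_CODE <- c(LEFT = "L", RIGHT = "R", BILATERAL = "B")

#' Read a fingerprint matrix with its region and study metadata
#'
#' The matrix file is CSV with first column `roi_id` and one column per
#' study; cells must be -1, 0 or 1. Region metadata is TSV with columns
#' `roi_id, label, hemisphere (L|R|B), tissue (GM|WM|MIXED), networks`
#' (semicolon-separated ids); study metadata is TSV with columns
#' `study_id, citation, method, design, confidence`. Headers are
#' whitespace-tolerant; cell values are not.
#'
#' @param matrix_path,roi_path,study_path Input file paths.
#' @return List with `matrix` (a validated `fingerprint_matrix`) and
#'   `scheme` (the [network_scheme()] induced by the region metadata).
#' @export
read_fingerprint <- function(matrix_path, roi_path, study_path) {
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  names(raw) <- trimws(names(raw))
  if (!identical(names(raw)[1L], "roi_id"))
    stop("matrix file must have first column header 'roi_id': ", matrix_path)
  roi_ids <- raw[[1L]]
  if (anyDuplicated(roi_ids))
    stop("duplicate roi_id in matrix file: ",
         paste(unique(roi_ids[duplicated(roi_ids)]), collapse = ", "))
  study_ids <- names(raw)[-1L]
  if (anyDuplicated(study_ids))
    stop("duplicate study_id in matrix header: ",
         paste(unique(study_ids[duplicated(study_ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  ok <- cells %in% c("-1", "0", "1")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    rc <- arrayInd(bad, dim(cells))
    stop(sprintf("non-ternary cell '%s' at line %d, column '%s' of %s",
                 cells[bad], rc[1L] + 1L, study_ids[rc[2L]], matrix_path))
  }
  entries <- matrix(as.integer(cells), nrow(cells), ncol(cells))

  roi_meta <- read_tsv_strict(roi_path,
                              c("roi_id", "label", "hemisphere", "tissue", "networks"))
  study_meta <- read_tsv_strict(study_path,
                                c("study_id", "citation", "method", "design", "confidence"))
  missing_r <- setdiff(roi_ids, roi_meta$roi_id)
  if (length(missing_r))
    stop("matrix row(s) without region metadata: ", paste(missing_r, collapse = ", "))
  missing_s <- setdiff(study_ids, study_meta$study_id)
  if (length(missing_s))
    stop("matrix column(s) without study metadata: ", paste(missing_s, collapse = ", "))
  hemi <- names(HEMI_CODE)[match(toupper(roi_meta$hemisphere), HEMI_CODE)]
  if (anyNA(hemi))
    stop("invalid hemisphere code (use L|R|B) for: ",
         paste(roi_meta$roi_id[is.na(hemi)], collapse = ", "))
  # vocabulary is taken from the file so alternative grouping schemes load;
  # the canonical seven networks are only the default annotation set
  seen <- unique(unlist(strsplit(roi_meta$networks, ";", fixed = TRUE)))
  seen <- trimws(seen[nzchar(trimws(seen))])
  regions <- region_records(roi_meta$roi_id, roi_meta$label, hemi,
                            roi_meta$tissue, roi_meta$networks,
                            vocabulary = seen)
  regions <- regions[match(roi_ids, regions$roi_id), , drop = FALSE]
  rownames(regions) <- NULL
  studies <- study_records(study_meta$study_id, study_meta$citation,
                           study_meta$method, study_meta$design,
                           study_meta$confidence)
  studies <- studies[match(study_ids, studies$study_id), , drop = FALSE]
  rownames(studies) <- NULL
  m <- fingerprint_matrix(entries, regions, studies)
  issues <- validate_matrix(m)
  errs <- issues[issues$severity == "ERROR", , drop = FALSE]
  if (nrow(errs))
    stop("invalid fingerprint matrix: ",
         paste(sprintf("[%s] %s", errs$location, errs$message), collapse = "; "))
  list(matrix = m, scheme = network_scheme(regions))
}

read_tsv_strict <- function(path, need) {
  x <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  names(x) <- trimws(names(x))
  if (!all(need %in% names(x)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x[[need[1L]]]))
    stop("duplicate ", need[1L], " in ", path, ": ",
         paste(unique(x[[need[1L]]][duplicated(x[[need[1L]]])]), collapse = ", "))
  x
}

#' Write a fingerprint matrix and its metadata to the standard three files
#'
#' @param m A `fingerprint_matrix`.
#' @param matrix_path,roi_path,study_path Output file paths.
#' @return Invisibly, the three paths.
#' @export
write_fingerprint <- function(m, matrix_path, roi_path, study_path) {
  tab <- data.frame(roi_id = rownames(m$entries), m$entries,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, matrix_path, row.names = FALSE, quote = FALSE, eol = "\n")
  roi <- m$regions
  roi_out <- data.frame(roi_id = roi$roi_id, label = roi$label,
                        hemisphere = unname(HEMI_CODE[roi$hemisphere]),
                        tissue = roi$tissue, networks = roi$networks,
                        stringsAsFactors = FALSE)
  utils::write.table(roi_out, roi_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  utils::write.table(m$studies, study_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(c(matrix_path, roi_path, study_path))
}

#' Pipeline configuration
#'
#' @param matrix_path,roi_path,study_path Input files (see
#'   [read_fingerprint()]).
#' @param out_dir Output directory (created if absent).
#' @param tau Edge threshold for the main co-alteration graph (default 2).
#' @param sweep_taus Thresholds for the sensitivity sweep (default 1:3).
#' @param n_components Principal components to retain (default 2).
#' @param n_clusters Dendrogram cut used for the cluster-vs-network agreement
#'   (default 7, the number of canonical networks).
#' @param use_centered Cluster centered rows instead of raw ternary rows.
#' @param seed Integer recorded in the run summary (the pipeline itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(matrix_path, roi_path, study_path, out_dir,
                       tau = 2L, sweep_taus = c(1L, 2L, 3L),
                       n_components = 2L, n_clusters = 7L,
                       use_centered = FALSE, seed = 1L) {
  if (tau < 1L) stop("tau must be >= 1")
  if (n_components < 1L) stop("n_components must be >= 1")
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  structure(list(matrix_path = matrix_path, roi_path = roi_path,
                 study_path = study_path, out_dir = out_dir,
                 tau = as.integer(tau), sweep_taus = as.integer(sweep_taus),
                 n_components = as.integer(n_components),
                 n_clusters = as.integer(n_clusters),
                 use_centered = isTRUE(use_centered),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full fingerprint pipeline and write the report bundle
#'
#' Executes metrics, co-alteration (with threshold sweep), PCA and Ward
#' clustering, writing: `metrics.csv`, `edge_list.tsv`, `graph.graphml`,
#' `eigen_summary.csv`, `scores.csv`, `dendrogram.newick`,
#' `merge_table.csv` and `run_summary.json` into `config$out_dir`. Progress
#' is logged to standard error with per-stage timings.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run summary list.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[snfkit] %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  loaded <- stage("read", read_fingerprint(config$matrix_path, config$roi_path,
                                           config$study_path))
  m <- loaded$matrix; scheme <- loaded$scheme
  out <- function(f) file.path(config$out_dir, f)

  tab <- stage("metrics", metrics_table(m, scheme))
  write_metrics(tab, out("metrics.csv"))

  cm <- stage("coalter", coalteration_matrix(m))
  g <- build_graph(cm, config$tau, scheme)
  write_edge_list(g, out("edge_list.tsv"))
  write_graphml(g, out("graph.graphml"))
  sweep <- stage("sweep", threshold_sweep(cm, config$sweep_taus,
                                          seed_set = character(), scheme = scheme))

  emb <- stage("embed", snf_embedding(m, config$n_components, scheme))
  eig_out <- data.frame(component = seq_along(emb$values),
                        eigenvalue = format_num(emb$values),
                        explained_variance_ratio =
                          format_num(emb$explained_variance_ratio),
                        stringsAsFactors = FALSE)
  utils::write.csv(eig_out, out("eigen_summary.csv"), row.names = FALSE,
                   quote = FALSE, eol = "\n")
  sc <- emb$scores
  sc_out <- data.frame(roi_id = rownames(sc),
                       pc1 = format_num(sc[, 1L]),
                       pc2 = if (ncol(sc) >= 2L) format_num(sc[, 2L]) else "NA",
                       dominant_network = emb$dominant_network %||%
                         rep("NA", nrow(sc)),
                       stringsAsFactors = FALSE)
  utils::write.csv(sc_out, out("scores.csv"), row.names = FALSE, quote = FALSE,
                   eol = "\n")

  cl <- stage("cluster", ward_dendrogram(m, use_centered = config$use_centered))
  export_newick(cl, out("dendrogram.newick"))
  mt <- cl$merge_table
  mt$height <- format_num(mt$height)
  utils::write.csv(mt, out("merge_table.csv"), row.names = FALSE, quote = FALSE,
                   eol = "\n")
  k <- min(config$n_clusters, length(cl$labels))
  ari <- cluster_network_agreement(cl, scheme, k)

  summary <- list(
    package_version = as.character(utils::packageVersion("snfkit")),
    config = list(tau = config$tau, sweep_taus = config$sweep_taus,
                  n_components = config$n_components,
                  n_clusters = config$n_clusters,
                  use_centered = config$use_centered, seed = config$seed),
    node_restriction = g$node_restriction,
    n_regions = nrow(m$entries), n_studies = ncol(m$entries),
    n_abnormal_entries = sum(m$entries != 0L),
    metrics = lapply(seq_len(nrow(tab)), function(i) list(
      network = tab$network[i], region_count = tab$region_count[i],
      load = tab$load[i], distinct_regions = tab$distinct_regions[i],
      per_region_index = na_null(tab$per_region_index[i]),
      mean_direction = na_null(tab$mean_direction[i]))),
    graph = list(tau = g$tau, n_nodes = as.integer(igraph::vcount(g$graph)),
                 n_edges = as.integer(igraph::ecount(g$graph)),
                 density = g$density),
    sweep = lapply(seq_len(nrow(sweep$summary)), function(i)
      as.list(sweep$summary[i, c("tau", "n_nodes", "n_edges", "density",
                                 "n_components")])),
    eigen = list(values = emb$values,
                 explained_variance_ratio = emb$explained_variance_ratio),
    clustering = list(n_clusters = k, network_agreement_ari = ari)
  )
  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

na_null <- function(x) if (is.na(x)) NULL else x
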