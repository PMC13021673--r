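#' Controlled vocabulary of canonical large-scale networks
#'
#' The seven systems used to annotate atlas regions: default mode (DMN),
#' salience (SAL), frontoparietal control (FPN), limbic/memory (LIM),
#' sensorimotor/dorsal-attention (SMN), interhemispheric/callosal (CAL) and
#' brainstem/cerebellar (BSC). Alternative groupings can be supplied as a
#' [network_scheme()] built from user files; this vector is only the default
#' vocabulary.
#'
#' @format Character vector of length 7.
#' @export
SNF_NETWORKS <- c("DMN", "SAL", "FPN", "LIM", "SMN", "CAL", "BSC")

#' Default priority order used to pick a dominant network affiliation
#'
#' Regions assigned to more than one network are colour-coded / labelled by
#' the first matching network in this order.
#'
#' @format Character vector, a permutation of [SNF_NETWORKS].
#' @export
SNF_PRIORITY <- c("DMN", "LIM", "SAL", "FPN", "SMN", "CAL", "BSC")

SNF_HEMISPHERES <- c("LEFT", "RIGHT", "BILATERAL")
SNF_TISSUES <- c("GM", "WM", "MIXED")
SNF_METHODS <- c("VBM", "VOLUMETRY", "GM_PROB", "WM_PROB", "TBM")
SNF_DESIGNS <- c("CROSS_SECTIONAL", "LONGITUDINAL")
SNF_CONFIDENCE <- c("NARRATIVE", "RECONSTRUCTED_LOW_CONFIDENCE")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a table of region (ROI) records
#'
#' @param roi_id Character vector of short stable identifiers (unique).
#' @param label Human-readable anatomical names.
#' @param hemisphere `"LEFT"`, `"RIGHT"` or `"BILATERAL"` per region.
#' @param tissue `"GM"`, `"WM"` or `"MIXED"` per region.
#' @param networks Per-region network memberships: either a list of character
#'   vectors or a character vector of `";"`-separated network ids. Must be
#'   non-empty and drawn from `vocabulary`.
#' @param vocabulary Allowed network ids (default [SNF_NETWORKS]).
#' @return A `data.frame` with columns `roi_id, label, hemisphere, tissue,
#'   networks` where `networks` is a `";"`-joined string.
#' @export
region_records <- function(roi_id, label, hemisphere, tissue, networks,
                           vocabulary = SNF_NETWORKS) {
  roi_id <- as.character(roi_id)
  if (anyDuplicated(roi_id))
    stop("duplicate roi_id: ", paste(unique(roi_id[duplicated(roi_id)]), collapse = ", "))
  hemisphere <- match_enum(hemisphere, SNF_HEMISPHERES, "hemisphere")
  tissue <- match_enum(tissue, SNF_TISSUES, "tissue")
  nets <- normalize_networks(networks, length(roi_id))
  for (i in seq_along(nets)) {
    if (length(nets[[i]]) == 0L)
      stop("region '", roi_id[i], "' has an empty network set")
    bad <- setdiff(nets[[i]], vocabulary)
    if (length(bad))
      stop("region '", roi_id[i], "' references unknown network(s): ",
           paste(bad, collapse = ", "))
  }
  data.frame(
    roi_id = roi_id,
    label = as.character(label),
    hemisphere = hemisphere,
    tissue = tissue,
    networks = vapply(nets, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Build a table of study records
#'
#' @param study_id Character vector of short stable identifiers (unique).
#' @param citation Free-text citation per study.
#' @param method Morphometric method: one of `"VBM"`, `"VOLUMETRY"`,
#'   `"GM_PROB"`, `"WM_PROB"`, `"TBM"`.
#' @param design `"CROSS_SECTIONAL"` or `"LONGITUDINAL"`.
#' @param confidence Provenance flag: `"NARRATIVE"` for studies whose regional
#'   findings are enumerated in the source text, or
#'   `"RECONSTRUCTED_LOW_CONFIDENCE"` for best-effort reconstructions.
#' @return A `data.frame` with one row per study.
#' @export
study_records <- function(study_id, citation, method, design,
                          confidence = "NARRATIVE") {
  study_id <- as.character(study_id)
  if (anyDuplicated(study_id))
    stop("duplicate study_id: ", paste(unique(study_id[duplicated(study_id)]), collapse = ", "))
  data.frame(
    study_id = study_id,
    citation = as.character(citation),
    method = match_enum(method, SNF_METHODS, "method"),
    design = match_enum(design, SNF_DESIGNS, "design"),
    confidence = match_enum(rep_len(confidence, length(study_id)),
                            SNF_CONFIDENCE, "confidence"),
    stringsAsFactors = FALSE
  )
}

match_enum <- function(x, levels, what) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")")
  x
}

normalize_networks <- function(networks, n) {
  if (is.list(networks)) {
    nets <- lapply(networks, as.character)
  } else {
    nets <- strsplit(as.character(networks), ";", fixed = TRUE)
    nets <- lapply(nets, function(x) x[nzchar(trimws(x))])
    nets <- lapply(nets, trimws)
  }
  if (length(nets) != n) stop("networks must have one entry per region")
  nets
}

#' Per-region network membership as a named list
#'
#' @param regions A region table from [region_records()].
#' @return Named list mapping `roi_id` to a character vector of network ids.
#' @export
roi_networks <- function(regions) {
  nets <- strsplit(regions$networks, ";", fixed = TRUE)
  names(nets) <- regions$roi_id
  nets
}

#' Construct a network scheme (region sets and dominant-affiliation order)
#'
#' A scheme holds the ordered network vocabulary, the ROI-to-networks mapping
#' and a priority order used to resolve a single dominant affiliation for
#' regions belonging to several networks.
#'
#' @param membership Named list: `roi_id -> character vector` of network ids,
#'   or a region table from [region_records()].
#' @param network_ids Ordered network vocabulary; defaults to the networks
#'   seen in `membership`, ordered as in [SNF_NETWORKS] (unknown ids appended).
#' @param priority Permutation of `network_ids` used for dominant affiliation;
#'   defaults to [SNF_PRIORITY] filtered to `network_ids` (then remaining ids).
#' @return An object of class `network_scheme`.
#' @export
network_scheme <- function(membership, network_ids = NULL, priority = NULL) {
  if (is.data.frame(membership)) membership <- roi_networks(membership)
  if (is.null(names(membership)) || any(!nzchar(names(membership))))
    stop("membership must be a named list (roi_id -> networks)")
  used <- unique(unlist(membership, use.names = FALSE))
  if (is.null(network_ids)) {
    network_ids <- c(intersect(SNF_NETWORKS, used), setdiff(used, SNF_NETWORKS))
  }
  missing <- setdiff(used, network_ids)
  if (length(missing))
    stop("network(s) referenced by regions but absent from network_ids: ",
         paste(missing, collapse = ", "))
  if (is.null(priority)) {
    priority <- c(intersect(SNF_PRIORITY, network_ids),
                  setdiff(network_ids, SNF_PRIORITY))
  }
  if (!setequal(priority, network_ids) || length(priority) != length(network_ids))
    stop("priority must be a permutation of network_ids")
  structure(
    list(network_ids = network_ids, membership = membership, priority = priority),
    class = "network_scheme"
  )
}

#' @export
print.network_scheme <- function(x, ...) {
  cat("<network_scheme> ", length(x$network_ids), " networks, ",
      length(x$membership), " regions\n", sep = "")
  for (k in x$network_ids)
    cat("  ", k, ": ", length(network_regions(x, k)), " regions\n", sep = "")
  invisible(x)
}

#' Regions assigned to a network (the set R_k)
#'
#' @param scheme A [network_scheme()].
#' @param network A network id in `scheme$network_ids`.
#' @return Character vector of roi_ids belonging to `network`, in membership
#'   (region) order.
#' @export
network_regions <- function(scheme, network) {
  check_network(scheme, network)
  keep <- vapply(scheme$membership, function(n) network %in% n, NA)
  names(scheme$membership)[keep]
}

check_network <- function(scheme, network) {
  if (!network %in% scheme$network_ids)
    stop("unknown network id: '", network, "'")
  invisible(network)
}

#' Dominant network affiliation of each region
#'
#' The first network in the scheme's priority order among a region's
#' memberships.
#'
#' @param scheme A [network_scheme()].
#' @param roi_ids Regions to resolve; default all regions in the scheme.
#' @return Named character vector `roi_id -> network id`.
#' @export
dominant_network <- function(scheme, roi_ids = names(scheme$membership)) {
  bad <- setdiff(roi_ids, names(scheme$membership))
  if (length(bad)) stop("unknown roi_id: ", paste(bad, collapse = ", "))
  vapply(scheme$membership[roi_ids], function(n) {
    hit <- scheme$priority[scheme$priority %in% n]
    if (!length(hit)) stop("region with no network in scheme priority")
    hit[[1L]]
  }, "")
}

#' Assemble a ternary fingerprint matrix from per-study observations
#'
#' Each observation records one direction of structural abnormality (−1 for a
#' significant decrease, +1 for a significant increase) for one (region,
#' study) pair; absence of abnormality is represented by omission. Multiple
#' same-sign reports for the same pair (e.g. several significant clusters
#' inside one atlas region) are consolidated into a single entry. Reports of
#' opposite sign for the same pair are resolved by `conflict_policy`.
#'
#' @param observations A `data.frame` with columns `roi_id, study_id,
#'   direction` (direction in `-1, +1`). May have zero rows.
#' @param regions Region table ([region_records()]); defines the row axis.
#' @param studies Study table ([study_records()]); defines the column axis.
#' @param conflict_policy `"ERROR"` (default): opposite-sign reports for one
#'   cell raise an error. `"MAJORITY"`: the more frequent sign wins; an exact
#'   tie still errors (it cannot be majority-resolved).
#' @return A `fingerprint_matrix`: list with `entries` (integer matrix in
#'   \{−1,0,+1\}, dimnames = roi_id x study_id), `regions` and `studies`.
#' @export
build_matrix <- function(observations, regions, studies,
                         conflict_policy = c("ERROR", "MAJORITY")) {
  conflict_policy <- match.arg(toupper(conflict_policy[1L]), c("ERROR", "MAJORITY"))
  obs <- as.data.frame(observations)
  if (nrow(obs)) {
    need <- c("roi_id", "study_id", "direction")
    if (!all(need %in% names(obs)))
      stop("observations must have columns roi_id, study_id, direction")
    if (!all(obs$direction %in% c(-1L, 1L)))
      stop("observation direction must be -1 or +1 (absence is omission, not 0)")
    bad_r <- setdiff(unique(obs$roi_id), regions$roi_id)
    if (length(bad_r))
      stop("observation references undeclared roi_id: ", paste(bad_r, collapse = ", "))
    bad_s <- setdiff(unique(obs$study_id), studies$study_id)
    if (length(bad_s))
      stop("observation references undeclared study_id: ", paste(bad_s, collapse = ", "))
  }
  entries <- matrix(0L, nrow = nrow(regions), ncol = nrow(studies),
                    dimnames = list(regions$roi_id, studies$study_id))
  if (nrow(obs)) {
    key <- paste(obs$roi_id, obs$study_id, sep = "\r")
    for (k in unique(key)) {
      sel <- obs[key == k, , drop = FALSE]
      n_neg <- sum(sel$direction == -1L)
      n_pos <- sum(sel$direction == 1L)
      if (n_neg > 0L && n_pos > 0L) {
        pair <- sprintf("(%s, %s)", sel$roi_id[1L], sel$study_id[1L])
        if (conflict_policy == "ERROR")
          stop("opposite-sign observations for ", pair,
               "; use conflict_policy = 'MAJORITY' to resolve by count")
        if (n_neg == n_pos)
          stop("opposite-sign tie for ", pair, " cannot be majority-resolved")
      }
      entries[sel$roi_id[1L], sel$study_id[1L]] <-
        if (n_neg > n_pos) -1L else 1L
    }
  }
  fingerprint_matrix(entries, regions, studies)
}

#' Construct a fingerprint_matrix from an entries matrix plus metadata
#'
#' @param entries Integer matrix with values in \{−1,0,+1\}; rows = regions,
#'   columns = studies (order must match the metadata tables).
#' @param regions,studies Metadata tables as in [build_matrix()].
#' @return A `fingerprint_matrix` object.
#' @export
fingerprint_matrix <- function(entries, regions, studies) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  if (nrow(entries) != nrow(regions))
    stop("entries has ", nrow(entries), " rows but regions has ", nrow(regions))
  if (ncol(entries) != nrow(studies))
    stop("entries has ", ncol(entries), " columns but studies has ", nrow(studies))
  dimnames(entries) <- list(regions$roi_id, studies$study_id)
  structure(list(entries = entries, regions = regions, studies = studies),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  nz <- sum(x$entries != 0L)
  cat("<fingerprint_matrix> ", nrow(x$entries), " regions x ",
      ncol(x$entries), " studies; ", nz, " abnormal entries (",
      sum(x$entries < 0L), " decreases, ", sum(x$entries > 0L),
      " increases)\n", sep = "")
  invisible(x)
}

#' @export
dim.fingerprint_matrix <- function(x) dim(x$entries)

#' Extract the consolidated observation set from a fingerprint matrix
#'
#' Inverse of [build_matrix()] up to consolidation: returns one row per
#' non-zero cell.
#'
#' @param m A `fingerprint_matrix`.
#' @return `data.frame` with columns `roi_id, study_id, direction`, ordered
#'   column-major (study-major) over non-zero cells.
#' @export
matrix_observations <- function(m) {
  idx <- which(m$entries != 0L, arr.ind = TRUE)
  data.frame(
    roi_id = rownames(m$entries)[idx[, 1L]],
    study_id = colnames(m$entries)[idx[, 2L]],
    direction = m$entries[idx],
    stringsAsFactors = FALSE
  )
}

#' Validate a fingerprint matrix, returning issues rather than raising
#'
#' Checks: entries inside \{−1,0,+1\}; unique region and study ids; non-empty
#' network sets; all-zero rows (reported as warnings — a region present in the
#' atlas but never reported abnormal is legal but noteworthy).
#'
#' @param m A `fingerprint_matrix`.
#' @return `data.frame` with columns `severity` (`"ERROR"`/`"WARNING"`),
#'   `location`, `message`; zero rows iff the matrix is valid.
#' @export
validate_matrix <- function(m) {
  issues <- list()
  add <- function(severity, location, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, location = location, message = message,
      stringsAsFactors = FALSE)
  }
  bad <- which(!(m$entries %in% c(-1L, 0L, 1L)))
  for (b in bad) {
    rc <- arrayInd(b, dim(m$entries))
    add("ERROR",
        sprintf("(%s, %s)", rownames(m$entries)[rc[1L]], colnames(m$entries)[rc[2L]]),
        sprintf("entry %s outside {-1, 0, +1}", m$entries[b]))
  }
  for (id in unique(m$regions$roi_id[duplicated(m$regions$roi_id)]))
    add("ERROR", id, "duplicate roi_id")
  for (id in unique(m$studies$study_id[duplicated(m$studies$study_id)]))
    add("ERROR", id, "duplicate study_id")
  nets <- roi_networks(m$regions)
  for (id in names(nets)[lengths(nets) == 0L])
    add("ERROR", id, "region has an empty network set")
  zero <- rownames(m$entries)[rowSums(m$entries != 0L, na.rm = TRUE) == 0L]
  for (id in zero)
    add("WARNING", id, "region has no abnormal report in any study")
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(), location = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Subset a fingerprint matrix by network and/or tissue class
#'
#' Restricts the region axis to the members of one network (the set R_k)
#' and/or one tissue class, preserving region and study order.
#'
#' @param m A `fingerprint_matrix`.
#' @param scheme A [network_scheme()]; required when `network` is given.
#' @param network Network id or `NULL` (no network filter).
#' @param tissue `"GM"`, `"WM"`, `"MIXED"` or `NULL` (no tissue filter).
#' @return A `fingerprint_matrix` over the selected regions (possibly 0-row).
#' @export
subset_matrix <- function(m, scheme = NULL, network = NULL, tissue = NULL) {
  keep <- rep(TRUE, nrow(m$regions))
  if (!is.null(network)) {
    if (is.null(scheme)) stop("a network_scheme is required to subset by network")
    keep <- keep & m$regions$roi_id %in% network_regions(scheme, network)
  }
  if (!is.null(tissue)) {
    tissue <- match_enum(tissue, SNF_TISSUES, "tissue")
    keep <- keep & m$regions$tissue %in% tissue
  }
  fingerprint_matrix(m$entries[keep, , drop = FALSE],
                     m$regions[keep, , drop = FALSE], m$studies)
}
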