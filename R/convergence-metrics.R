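# Network-level convergence metrics over the ternary fingerprint matrix.
# All four metrics operate on the region set R_k = {r : k in N(r)}; regions
# belonging to several networks contribute with full weight to each of them.

submatrix_rows <- function(m, scheme, k) {
  check_network(scheme, k)
  rk <- intersect(m$regions$roi_id, network_regions(scheme, k))
  m$entries[rk, , drop = FALSE]
}

#' Total abnormal load of a network (L_k)
#'
#' Number of non-zero fingerprint entries over the network's regions and all
#' studies: how often the network's regions are reported structurally
#' abnormal, irrespective of direction.
#'
#' @param m A `fingerprint_matrix`.
#' @param scheme A [network_scheme()].
#' @param k Network id.
#' @return Non-negative integer.
#' @export
total_abnormal_load <- function(m, scheme, k) {
  sum(submatrix_rows(m, scheme, k) != 0L)
}

#' Number of distinct abnormal regions in a network (N_k)
#'
#' Count of the network's regions that are reported abnormal in at least one
#' study.
#'
#' @inheritParams total_abnormal_load
#' @return Non-negative integer.
#' @export
distinct_abnormal_regions <- function(m, scheme, k) {
  x <- submatrix_rows(m, scheme, k)
  sum(rowSums(x != 0L) > 0L)
}

#' Abnormality-per-region index (A_k = L_k / N_k)
#'
#' Normalises the total load by the number of distinct abnormal regions,
#' giving the mean number of abnormal reports per affected region. Undefined
#' (NA) when the network has no abnormal region.
#'
#' @param load L_k, a non-negative integer.
#' @param distinct_regions N_k, a non-negative integer with N_k <= L_k.
#' @return Positive numeric, or `NA_real_` when `distinct_regions == 0`.
#' @export
abnormality_per_region <- function(load, distinct_regions) {
  if (distinct_regions < 0L || load < distinct_regions)
    stop("inconsistent metrics: load (", load,
         ") must be >= distinct_regions (", distinct_regions, ") >= 0")
  if (distinct_regions == 0L) return(NA_real_)
  load / distinct_regions
}

#' Mean direction of abnormality (D_k)
#'
#' Signed mean of the non-zero entries over a network's regions: −1 indicates
#' uniform volume loss, +1 uniform increase, values near 0 mixed directions.
#' Undefined (NA) when the network carries no abnormal entry.
#'
#' @inheritParams total_abnormal_load
#' @return Numeric in \[−1, 1\], or `NA_real_` when L_k = 0.
#' @export
mean_direction <- function(m, scheme, k) {
  x <- submatrix_rows(m, scheme, k)
  load <- sum(x != 0L)
  if (load == 0L) return(NA_real_)
  sum(x) / load
}

#' Per-network convergence metrics table
#'
#' One row per network in scheme order with region count |R_k|, L_k, N_k,
#' A_k = L_k/N_k, the supplementary density L_k/|R_k|, D_k, and the rank of
#' each network by A_k (ties broken by scheme order; NA ranked last).
#'
#' @param m A `fingerprint_matrix`.
#' @param scheme A [network_scheme()] covering every network referenced by
#'   `m$regions`.
#' @return `data.frame` with columns `network, region_count, load,
#'   distinct_regions, per_region_index, load_per_assigned_region,
#'   mean_direction, rank_per_region_index` plus attribute `study_count`.
#' @export
metrics_table <- function(m, scheme) {
  referenced <- unique(unlist(roi_networks(m$regions), use.names = FALSE))
  missing <- setdiff(referenced, scheme$network_ids)
  if (length(missing))
    stop("scheme is missing network(s) referenced by the matrix: ",
         paste(missing, collapse = ", "))
  rows <- lapply(scheme$network_ids, function(k) {
    rk <- intersect(m$regions$roi_id, network_regions(scheme, k))
    load <- total_abnormal_load(m, scheme, k)
    nk <- distinct_abnormal_regions(m, scheme, k)
    data.frame(
      network = k,
      region_count = length(rk),
      load = load,
      distinct_regions = nk,
      per_region_index = abnormality_per_region(load, nk),
      load_per_assigned_region = if (length(rk)) load / length(rk) else NA_real_,
      mean_direction = mean_direction(m, scheme, k),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  # rank by A_k descending; ties and NA resolved by scheme order (stable sort)
  ord <- order(-ifelse(is.na(tab$per_region_index), -Inf, tab$per_region_index))
  tab$rank_per_region_index <- NA_integer_
  tab$rank_per_region_index[ord] <- seq_len(nrow(tab))
  attr(tab, "study_count") <- ncol(m$entries)
  tab
}

#' Write a metrics table to CSV
#'
#' Missing metrics are serialized as the literal token `NA`; floating values
#' printed at fixed 9-digit precision for byte-stable regression outputs.
#'
#' @param tab Output of [metrics_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(tab, path) {
  out <- data.frame(
    network = tab$network,
    region_count = tab$region_count,
    load = tab$load,
    distinct_regions = tab$distinct_regions,
    per_region_index = format_num(tab$per_region_index),
    mean_direction = format_num(tab$mean_direction),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

format_num <- function(x, digits = 9L) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}
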