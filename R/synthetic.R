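# Planted-network generative model for validation: each region belongs to
# one synthetic network k with detection probability p_k and loss probability
# q_k; each study s scales detection by a sensitivity eta. Entries are
# independent: non-zero with probability p_k * eta, and -1 with probability
# q_k given non-zero. This is the simplest model consistent with the ternary
# coding; it emulates convergent network-organised reporting, not correlated
# reporting or publication bias.

#' Specify a planted-network synthetic corpus
#'
#' @param networks `data.frame` with columns `network` (id), `region_count`
#'   (>= 1), `detect_prob` (p_k in \[0,1\]) and `loss_prob` (q_k in \[0,1\]).
#' @param n_studies Number of study columns (>= 1).
#' @param study_sensitivity Study sensitivity eta: a scalar or length
#'   `n_studies` vector in (0, 1\], or a `networks x n_studies` matrix in
#'   \[0, 1\] (a 0 meaning the study's panel does not cover that network,
#'   enabling network-exclusive study panels).
#' @param seed Single integer seed; the realized matrix is a deterministic
#'   function of the spec including the seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(networks, n_studies, study_sensitivity = 1,
                           seed = 1L) {
  networks <- as.data.frame(networks)
  need <- c("network", "region_count", "detect_prob", "loss_prob")
  if (!all(need %in% names(networks)))
    stop("networks needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(networks$network)) stop("duplicate synthetic network ids")
  if (any(networks$region_count < 1)) stop("region_count must be >= 1")
  if (any(networks$detect_prob < 0 | networks$detect_prob > 1))
    stop("detect_prob must lie in [0, 1]")
  if (any(networks$loss_prob < 0 | networks$loss_prob > 1))
    stop("loss_prob must lie in [0, 1]")
  if (n_studies < 1) stop("n_studies must be >= 1")
  eta <- study_sensitivity
  if (is.matrix(eta)) {
    if (nrow(eta) != nrow(networks) || ncol(eta) != n_studies)
      stop("matrix study_sensitivity must be networks x n_studies")
    if (any(eta < 0 | eta > 1)) stop("matrix study_sensitivity must lie in [0, 1]")
  } else {
    eta <- rep_len(as.numeric(eta), n_studies)
    if (any(eta <= 0 | eta > 1)) stop("study_sensitivity must lie in (0, 1]")
  }
  structure(list(networks = networks, n_studies = as.integer(n_studies),
                 study_sensitivity = eta, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Read a synthetic spec from a YAML config
#'
#' Expected keys: `networks` (list of maps with `network, region_count,
#' detect_prob, loss_prob`), `n_studies`, optional `study_sensitivity`
#' (scalar or list), optional `seed`.
#'
#' @param path YAML file path.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  nets <- do.call(rbind, lapply(y$networks, function(n)
    data.frame(network = as.character(n$network),
               region_count = as.integer(n$region_count),
               detect_prob = as.numeric(n$detect_prob),
               loss_prob = as.numeric(n$loss_prob),
               stringsAsFactors = FALSE)))
  synthetic_spec(nets, n_studies = as.integer(y$n_studies),
                 study_sensitivity = if (is.null(y$study_sensitivity)) 1
                                     else unlist(y$study_sensitivity),
                 seed = as.integer(y$seed %||% 1L))
}

#' Generate a synthetic fingerprint matrix from a planted-network spec
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (a `fingerprint_matrix`; synthetic regions are
#'   bilateral GM, single-membership), `truth` (class `planted_truth`: region
#'   to network assignment, the spec, and a checksum of the realized matrix),
#'   and `scheme` (the matching [network_scheme()]).
#' @export
generate_fingerprint <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nets <- spec$networks
  k_of <- rep(seq_len(nrow(nets)), nets$region_count)
  roi_id <- unlist(lapply(seq_len(nrow(nets)), function(i)
    sprintf("%s_r%02d", nets$network[i], seq_len(nets$region_count[i]))))
  n_r <- length(roi_id)
  n_s <- spec$n_studies
  eta <- spec$study_sensitivity
  p <- if (is.matrix(eta)) {
    nets$detect_prob[k_of] * eta[k_of, , drop = FALSE]
  } else {
    outer(nets$detect_prob[k_of], eta)
  }
  q <- nets$loss_prob[k_of]
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(withr_seed)
  u_hit <- matrix(stats::runif(n_r * n_s), n_r, n_s)
  u_sign <- matrix(stats::runif(n_r * n_s), n_r, n_s)
  entries <- matrix(0L, n_r, n_s)
  hit <- u_hit < p
  entries[hit] <- ifelse(u_sign[hit] < q[row(entries)[hit]], -1L, 1L)
  study_id <- sprintf("SYN%03d", seq_len(n_s))
  regions <- region_records(roi_id, label = roi_id, hemisphere = "BILATERAL",
                            tissue = "GM", networks = nets$network[k_of],
                            vocabulary = nets$network)
  studies <- study_records(study_id, citation = "synthetic",
                           method = "VBM", design = "CROSS_SECTIONAL",
                           confidence = "NARRATIVE")
  m <- fingerprint_matrix(entries, regions, studies)
  scheme <- network_scheme(regions, network_ids = nets$network,
                           priority = nets$network)
  truth <- structure(
    list(assignment = stats::setNames(nets$network[k_of], roi_id),
         spec = spec,
         checksum = sum(as.numeric(entries) * seq_along(entries))),
    class = "planted_truth")
  list(matrix = m, truth = truth, scheme = scheme)
}

#' Estimate planted detection and loss probabilities from a realization
#'
#' Method-of-moments estimates per network: `p_hat = L_k / (|R_k| |S|
#' mean(eta_k))` (the expected number of non-zero entries scales with mean
#' sensitivity) and `q_hat = (1 - D_k) / 2` (since E\[D_k\] = 1 - 2 q_k).
#' Simple binomial standard errors accompany both.
#'
#' @param m The realized `fingerprint_matrix`.
#' @param truth The matching `planted_truth`.
#' @param scheme A [network_scheme()] consistent with the truth assignment.
#' @return `data.frame` with columns `network, region_count, load, p_hat,
#'   p_se, q_hat, q_se` (q columns NA for networks with zero load).
#' @export
recover_parameters <- function(m, truth, scheme) {
  nets <- truth$spec$networks
  eta <- truth$spec$study_sensitivity
  rows <- lapply(seq_len(nrow(nets)), function(i) {
    k <- nets$network[i]
    rk <- network_regions(scheme, k)
    if (!setequal(rk, names(truth$assignment)[truth$assignment == k]))
      stop("scheme membership for '", k, "' does not match the planted truth")
    load <- total_abnormal_load(m, scheme, k)
    mean_eta <- if (is.matrix(eta)) mean(eta[i, ]) else mean(eta)
    n_cells <- length(rk) * ncol(m$entries)
    p_hat <- load / (n_cells * mean_eta)
    p_se <- sqrt(max(p_hat * (1 - p_hat), 0) / n_cells) / mean_eta
    if (load > 0L) {
      d <- mean_direction(m, scheme, k)
      q_hat <- (1 - d) / 2
      q_se <- sqrt(max(q_hat * (1 - q_hat), 0) / load)
    } else {
      q_hat <- NA_real_; q_se <- NA_real_
    }
    data.frame(network = k, region_count = length(rk), load = load,
               p_hat = p_hat, p_se = p_se, q_hat = q_hat, q_se = q_se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
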