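# Low-dimensional structure of the fingerprint: row-centered Gram-matrix PCA
# (principal-coordinate scores) and Ward hierarchical clustering of region
# abnormality profiles, plus cluster-vs-network agreement.

#' Row-center a fingerprint matrix
#'
#' Subtracts each region's mean across studies, emphasizing relative
#' abnormality profiles rather than absolute reporting frequency.
#'
#' @param m A `fingerprint_matrix` or a plain numeric matrix (>= 2 columns).
#' @return Object of class `centered_matrix`: list with `values` (each row
#'   sums to 0) and `row_means` (adding them back reproduces the input).
#' @export
row_center <- function(m) {
  x <- fingerprint_entries(m)
  if (ncol(x) < 2L)
    stop("row centering needs at least 2 studies (columns); got ", ncol(x))
  mu <- rowMeans(x)
  structure(list(values = x - mu, row_means = mu), class = "centered_matrix")
}

fingerprint_entries <- function(m) {
  if (inherits(m, "fingerprint_matrix")) return(m$entries * 1.0)
  if (inherits(m, "centered_matrix")) return(m$values)
  as.matrix(m) * 1.0
}

#' Region-by-region Gram/covariance matrix
#'
#' Computes the |R| x |R| matrix `X~ X~' / (|S| - 1)` over the centered rows.
#' This is the Gram form of the covariance (regions as the analysis axis);
#' its non-zero eigenvalues coincide with those of the conventional |S| x |S|
#' feature covariance (see [feature_covariance()]).
#'
#' @param x A `centered_matrix` (or matrix taken as already centered).
#' @return Symmetric numeric matrix with non-negative diagonal.
#' @export
gram_covariance <- function(x) {
  v <- fingerprint_entries(x)
  if (ncol(v) < 2L) stop("need at least 2 studies (columns)")
  tcrossprod(v) / (ncol(v) - 1)
}

#' Conventional feature (study-by-study) covariance
#'
#' The |S| x |S| dual of [gram_covariance()]; shares its non-zero spectrum.
#'
#' @inheritParams gram_covariance
#' @return Symmetric numeric matrix.
#' @export
feature_covariance <- function(x) {
  v <- fingerprint_entries(x)
  if (ncol(v) < 2L) stop("need at least 2 studies (columns)")
  crossprod(v) / (ncol(v) - 1)
}

#' Eigendecomposition with deterministic ordering and sign convention
#'
#' Eigenpairs sorted by descending eigenvalue; each eigenvector is unit-norm
#' with its largest-magnitude component made positive (first such component
#' on ties), so repeated runs and plots are reproducible.
#'
#' @param sigma Symmetric matrix (asymmetry above 1e-9 is an error).
#' @return List with `values` (descending) and `vectors` (columns matching).
#' @export
eigendecompose <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) || max(abs(sigma - t(sigma))) > 1e-9)
    stop("sigma must be symmetric (tolerance 1e-9)")
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  v <- e$vectors
  for (i in seq_len(ncol(v))) {
    j <- which.max(abs(v[, i]))
    if (v[j, i] < 0) v[, i] <- -v[, i]
  }
  rownames(v) <- rownames(sigma)
  list(values = e$values, vectors = v)
}

#' Region scores on the leading principal components
#'
#' Principal-coordinate convention for the Gram formulation: the score of
#' region r on component i is `v_i[r] * sqrt(lambda_i)`, so full-dimensional
#' scores reproduce the pairwise Euclidean distances between centered rows.
#'
#' @param x A `centered_matrix` (used for dimension checks).
#' @param eig Output of [eigendecompose()] on the Gram covariance. Note the
#'   Gram normalisation 1/(|S|-1) carries into the scores.
#' @param n_components Number of leading components; must not exceed the
#'   number of numerically positive eigenvalues (tolerance 1e-9).
#' @return Numeric |R| x n_components matrix, columns `PC1..`.
#' @export
region_scores <- function(x, eig, n_components = 2L) {
  pos <- sum(eig$values > 1e-9)
  if (n_components < 1L || n_components > pos)
    stop("n_components (", n_components, ") exceeds the number of positive eigenvalues (", pos, ")")
  idx <- seq_len(n_components)
  s <- sweep(eig$vectors[, idx, drop = FALSE], 2L, sqrt(eig$values[idx]), `*`)
  colnames(s) <- paste0("PC", idx)
  s
}

#' Row-centered Gram-matrix PCA of a fingerprint matrix
#'
#' Composes [row_center()], [gram_covariance()], [eigendecompose()] and
#' [region_scores()]. In `mode = "feature"` the conventional study-by-study
#' covariance is decomposed instead and regions are projected as `X~ w_i`
#' (singular-value duality makes the two modes' non-zero spectra identical).
#'
#' @param m A `fingerprint_matrix`.
#' @param n_components Components to retain in `scores` (default 2).
#' @param scheme Optional [network_scheme()]; adds dominant-network labels.
#' @param mode `"gram"` (as-printed region-by-region form, default) or
#'   `"feature"` (conventional PCA).
#' @return Object of class `snf_embedding`: list with `sigma`, `values`,
#'   `vectors`, `explained_variance_ratio`, `scores`, `dominant_network`
#'   (or NULL), `mode`, `centered` (the `centered_matrix`).
#' @export
snf_embedding <- function(m, n_components = 2L, scheme = NULL,
                          mode = c("gram", "feature")) {
  mode <- match.arg(mode)
  xc <- row_center(m)
  sigma <- if (mode == "gram") gram_covariance(xc) else feature_covariance(xc)
  eig <- eigendecompose(sigma)
  evr_base <- pmax(eig$values, 0)
  evr <- if (sum(evr_base) > 0) evr_base / sum(evr_base) else evr_base
  scores <- if (mode == "gram") {
    region_scores(xc, eig, n_components)
  } else {
    pos <- sum(eig$values > 1e-9)
    if (n_components > pos)
      stop("n_components exceeds the number of positive eigenvalues (", pos, ")")
    s <- xc$values %*% eig$vectors[, seq_len(n_components), drop = FALSE]
    colnames(s) <- paste0("PC", seq_len(n_components))
    s
  }
  rownames(scores) <- rownames(xc$values)
  dom <- if (!is.null(scheme) && !is.null(rownames(scores)))
    unname(dominant_network(scheme, rownames(scores))) else NULL
  structure(list(sigma = sigma, values = eig$values, vectors = eig$vectors,
                 explained_variance_ratio = evr, scores = scores,
                 dominant_network = dom, mode = mode, centered = xc),
            class = "snf_embedding")
}

#' @export
print.snf_embedding <- function(x, ...) {
  cat("<snf_embedding> mode=", x$mode, "; ", nrow(x$scores), " regions, ",
      ncol(x$scores), " components; PC1 explains ",
      sprintf("%.1f%%", 100 * x$explained_variance_ratio[1L]), "\n", sep = "")
  invisible(x)
}

#' Ward hierarchical clustering of region abnormality profiles
#'
#' Agglomerates regions under Ward's criterion over Euclidean distances
#' between rows, via the Lance-Williams recurrence on squared distances
#' (merge heights are the ward.D2 convention: the height of merging two
#' singletons is their Euclidean distance). Ties are broken by the lowest
#' original-row-index pair, making the tree fully deterministic.
#'
#' @param m A `fingerprint_matrix` or numeric matrix with >= 2 rows.
#' @param use_centered If `TRUE`, cluster the row-centered matrix instead of
#'   raw ternary rows (consistency with the PCA view); default `FALSE`.
#' @return Object of class `snf_clustering`: list with `hclust` (a valid
#'   [stats::hclust] object), `merge_table` (`step, member_a, member_b,
#'   height, size`), `labels`, `use_centered`.
#' @export
ward_dendrogram <- function(m, use_centered = FALSE) {
  x <- fingerprint_entries(m)
  if (isTRUE(use_centered)) x <- row_center(x)$values
  n <- nrow(x)
  if (n < 2L) stop("clustering needs at least 2 regions (rows); got ", n)
  labels <- rownames(x) %||% paste0("r", seq_len(n))
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)            # indices into bookkeeping vectors
  code <- -seq_len(n)             # hclust merge codes: -i singleton, +t step t
  size <- rep(1L, n)
  minrow <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (t in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq((ii + 1L), length(active))) {
        a <- active[ii]; b <- active[jj]
        key <- c(d2[a, b], min(minrow[a], minrow[b]), max(minrow[a], minrow[b]))
        if (is.null(best) || ward_key_less(key, best$key))
          best <- list(key = key, a = a, b = b)
      }
    }
    a <- best$a; b <- best$b
    height[t] <- sqrt(max(best$key[1L], 0))
    merge[t, ] <- sort(c(code[a], code[b]))
    others <- setdiff(active, c(a, b))
    na <- size[a]; nb <- size[b]
    for (k in others) {
      nk <- size[k]
      d2[a, k] <- d2[k, a] <-
        ((na + nk) * d2[a, k] + (nb + nk) * d2[b, k] - nk * d2[a, b]) /
        (na + nb + nk)
    }
    # reuse slot a for the merged cluster, retire slot b
    size[a] <- na + nb
    minrow[a] <- min(minrow[a], minrow[b])
    code[a] <- t
    active <- setdiff(active, b)
  }
  hc <- structure(
    list(merge = merge, height = height, order = leaf_order(merge, n),
         labels = labels, method = "ward.D2", call = match.call(),
         dist.method = "euclidean"),
    class = "hclust")
  mt <- data.frame(step = seq_len(n - 1L),
                   member_a = merge[, 1L], member_b = merge[, 2L],
                   height = height,
                   size = merge_sizes(merge),
                   stringsAsFactors = FALSE)
  structure(list(hclust = hc, merge_table = mt, labels = labels,
                 use_centered = isTRUE(use_centered)),
            class = "snf_clustering")
}

# squared-distance comparison with a small tolerance so exact rational ties
# survive floating-point noise; tied pairs fall through to the row-index rule
ward_key_less <- function(a, b, tol = 1e-9) {
  eps <- tol * max(1, a[1L], b[1L])
  if (a[1L] < b[1L] - eps) return(TRUE)
  if (a[1L] > b[1L] + eps) return(FALSE)
  if (a[2L] != b[2L]) return(a[2L] < b[2L])
  a[3L] < b[3L]
}

leaf_order <- function(merge, n) {
  rec <- function(code) {
    if (code < 0L) return(-code)
    c(rec(merge[code, 1L]), rec(merge[code, 2L]))
  }
  rec(n - 1L)
}

merge_sizes <- function(merge) {
  sz <- integer(nrow(merge))
  gets <- function(code) if (code < 0L) 1L else sz[code]
  for (t in seq_len(nrow(merge))) sz[t] <- gets(merge[t, 1L]) + gets(merge[t, 2L])
  sz
}

#' @export
print.snf_clustering <- function(x, ...) {
  cat("<snf_clustering> ", length(x$labels), " regions, ",
      nrow(x$merge_table), " merges (Ward/Euclidean",
      if (x$use_centered) ", centered rows" else "", ")\n", sep = "")
  invisible(x)
}

#' Cut the dendrogram into k groups
#'
#' @param c A [ward_dendrogram()] result.
#' @param k Number of clusters, 1 <= k <= |R|.
#' @return Named integer vector of cluster labels per region.
#' @export
labels_at_k <- function(c, k) {
  if (k < 1L || k > length(c$labels))
    stop("k must be between 1 and ", length(c$labels))
  stats::cutree(c$hclust, k = k)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement: 1 for identical partitions,
#' expectation approximately 0 under independent random labelings.
#'
#' @param a,b Equal-length label vectors (any types coercible to factor).
#' @return Numeric in \[−1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' Agreement between a k-cluster cut and dominant-network labels
#'
#' @param c A [ward_dendrogram()] result whose `labels` are roi_ids.
#' @param scheme A [network_scheme()] covering those regions.
#' @param k Number of clusters (2 <= k <= |R|).
#' @return Adjusted Rand index in \[−1, 1\].
#' @export
cluster_network_agreement <- function(c, scheme, k) {
  if (k < 2L || k > length(c$labels))
    stop("k must be between 2 and ", length(c$labels))
  cl <- labels_at_k(c, k)
  ref <- dominant_network(scheme, c$labels)
  adjusted_rand_index(unname(cl), unname(ref))
}

#' Export a dendrogram as Newick text
#'
#' Leaves are named by roi_id; each branch length is the parent's merge
#' height minus the child's height (leaves sit at height 0), so the tree is
#' ultrametric with leaf-to-root path length equal to the root merge height.
#'
#' @param c A [ward_dendrogram()] result.
#' @param path Optional file to write (LF-terminated single line).
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(c, path = NULL) {
  merge <- c$hclust$merge
  height <- c$hclust$height
  labels <- c$labels
  node_height <- function(code) if (code < 0L) 0 else height[code]
  render <- function(code) {
    if (code < 0L) return(labels[-code])
    h <- height[code]
    kids <- vapply(merge[code, ], function(ch) {
      paste0(render(ch), ":", sprintf("%.9g", h - node_height(ch)))
    }, "")
    paste0("(", paste(kids, collapse = ","), ")")
  }
  txt <- if (nrow(merge) >= 1L) paste0(render(nrow(merge)), ";")
         else stop("malformed merge tree")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "\n")
    return(invisible(txt))
  }
  txt
}
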