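# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (triple loops, centroid-form Ward, pair-counting ARI)
# and never call the code paths they check.

toy_regions <- function() {
  region_records(c("r1", "r2", "r3"), c("region 1", "region 2", "region 3"),
                 hemisphere = "BILATERAL", tissue = "GM",
                 networks = c("k1", "k1", "k2"), vocabulary = c("k1", "k2"))
}

toy_studies <- function() {
  study_records(c("s1", "s2", "s3"), citation = "toy", method = "VBM",
                design = "CROSS_SECTIONAL")
}

toy_scheme <- function() {
  network_scheme(toy_regions(), network_ids = c("k1", "k2"),
                 priority = c("k1", "k2"))
}

# T1: r1 = (-1,-1,0), r2 = (-1,0,+1), r3 = (0,0,-1)
toy_t1 <- function() {
  obs <- data.frame(
    roi_id = c("r1", "r1", "r2", "r2", "r3"),
    study_id = c("s1", "s2", "s1", "s3", "s3"),
    direction = c(-1L, -1L, -1L, 1L, -1L))
  build_matrix(obs, toy_regions(), toy_studies())
}

# random ternary fingerprint over a random 3-network scheme
rand_fingerprint <- function(nr, ns, p_nonzero = 0.3, nets = c("A", "B", "C")) {
  roi <- sprintf("r%02d", seq_len(nr))
  assign <- sample(nets, nr, replace = TRUE)
  regions <- region_records(roi, roi, "BILATERAL", "GM", assign,
                            vocabulary = nets)
  studies <- study_records(sprintf("s%02d", seq_len(ns)), "x", "VBM",
                           "CROSS_SECTIONAL")
  entries <- matrix(sample(c(-1L, 0L, 1L), nr * ns, replace = TRUE,
                           prob = c(p_nonzero / 2, 1 - p_nonzero, p_nonzero / 2)),
                    nr, ns)
  list(matrix = fingerprint_matrix(entries, regions, studies),
       scheme = network_scheme(regions, network_ids = nets, priority = nets))
}

# --- naive metric references (direct transcription of the definitions) ----

naive_load <- function(m, scheme, k) {
  rk <- network_regions(scheme, k)
  tot <- 0L
  for (r in rk) for (s in colnames(m$entries))
    if (m$entries[r, s] != 0L) tot <- tot + 1L
  tot
}

naive_distinct <- function(m, scheme, k) {
  rk <- network_regions(scheme, k)
  n <- 0L
  for (r in rk) {
    hit <- FALSE
    for (s in colnames(m$entries)) if (m$entries[r, s] != 0L) hit <- TRUE
    if (hit) n <- n + 1L
  }
  n
}

naive_direction <- function(m, scheme, k) {
  rk <- network_regions(scheme, k)
  tot <- 0L; load <- 0L
  for (r in rk) for (s in colnames(m$entries)) {
    v <- m$entries[r, s]
    if (v != 0L) { tot <- tot + v; load <- load + 1L }
  }
  if (load == 0L) NA_real_ else tot / load
}

naive_coalteration <- function(m) {
  rs <- rownames(m$entries)
  C <- matrix(0L, length(rs), length(rs), dimnames = list(rs, rs))
  for (r1 in rs) for (r2 in rs) for (s in colnames(m$entries))
    if (m$entries[r1, s] != 0L && m$entries[r2, s] != 0L)
      C[r1, r2] <- C[r1, r2] + 1L
  C
}

# --- centroid-form Ward oracle (direct evaluation of the merge objective) --

oracle_ward <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), function(i) i)  # original row indices
  heights <- numeric(n - 1L)
  partitions <- list()  # cluster membership after each merge
  for (t in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        d2 <- 2 * length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        key <- c(d2, min(a, b), max(min(a), min(b)))
        if (is.null(best) || key_less(key, best$key))
          best <- list(key = key, i = i, j = j)
      }
    }
    heights[t] <- sqrt(max(best$key[1L], 0))
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[t]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

key_less <- function(a, b, tol = 1e-9) {
  eps <- tol * max(1, a[1L], b[1L])
  if (a[1L] < b[1L] - eps) return(TRUE)
  if (a[1L] > b[1L] + eps) return(FALSE)
  if (a[2L] != b[2L]) return(a[2L] < b[2L])
  a[3L] < b[3L]
}

# --- pair-counting ARI reference -----------------------------------------

pair_count_ari <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) return(1)
  2 * (s11 * s00 - s10 * s01) / den
}
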