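#' Adjacency graph over channels or voxels
#'
#' @param x a [sensor_layout()] (channel adjacency from its stored relation)
#'   or a `source_grid` (26-connectivity between lattice neighbors).
#' @return object of class `adjacency_graph`: `n`, `neighbors` (list of
#'   integer vectors, symmetric, no self edges), `labels`.
#' @export
adjacency_graph <- function(x) {
  if (inherits(x, "sensor_layout")) {
    nb <- lapply(seq_along(x$labels), function(i) which(x$adjacency[i, ]))
    labels <- x$labels
  } else if (inherits(x, "source_grid")) {
    key <- function(ijk) ijk[, 1] + 4096 * (ijk[, 2] + 4096 * ijk[, 3])
    tab <- new.env(hash = TRUE, size = nrow(x$ijk))
    ks <- key(x$ijk + 2000L)
    for (i in seq_along(ks)) assign(as.character(ks[i]), i, envir = tab)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0, ]
    nb <- lapply(seq_len(nrow(x$ijk)), function(i) {
      cand <- key(sweep(off, 2, as.integer(x$ijk[i, ] + 2000L), `+`))
      hits <- vapply(as.character(cand), function(k)
        if (exists(k, envir = tab, inherits = FALSE))
          get(k, envir = tab) else NA_integer_, 0L)
      sort(unname(hits[!is.na(hits)]))
    })
    labels <- as.character(seq_len(nrow(x$ijk)))
  } else stopf("cannot build adjacency from class %s", class(x)[1])
  structure(list(n = length(nb), neighbors = nb, labels = labels),
            class = "adjacency_graph")
}

#' Element-wise statistic map across subjects
#'
#' Units of observation are participants; the statistic is computed per cell
#' of a flattened (node x frequency x time) map.
#'
#' @param a subjects x cells matrix (condition A, or the only condition).
#' @param b subjects x cells matrix for `paired_t`/`independent_t`.
#' @param scores per-subject scores for `pearson_r`.
#' @param kind one of `"one_sample_t"`, `"paired_t"`, `"independent_t"`,
#'   `"pearson_r"`. `independent_t` is the pooled-variance two-sample t.
#' @return list with `stat` (per-cell statistic), `df`, and `flagged`
#'   (zero-variance cells, statistic set to 0).
#' @export
stat_map <- function(a, b = NULL, scores = NULL,
                     kind = c("one_sample_t", "paired_t", "independent_t",
                              "pearson_r")) {
  kind <- match.arg(kind)
  a <- as.matrix(a)
  if (kind == "paired_t") {
    if (is.null(b) || !all(dim(b) == dim(a))) stopf("paired_t needs matching b")
    a <- a - as.matrix(b)
    kind <- "one_sample_t"
  }
  if (kind == "one_sample_t") {
    n <- nrow(a)
    if (n < 3) stopf("need >= 3 units")
    m <- colMeans(a)
    v <- colSums(a^2) - n * m^2
    flagged <- v <= 0
    se <- sqrt(pmax(v, 0) / (n - 1) / n)
    stat <- ifelse(flagged, 0, m / se)
    return(list(stat = stat, df = n - 1, flagged = flagged))
  }
  if (kind == "independent_t") {
    b <- as.matrix(b)
    n1 <- nrow(a); n2 <- nrow(b)
    if (min(n1, n2) < 2 || n1 + n2 < 3) stopf("need >= 3 units")
    m1 <- colMeans(a); m2 <- colMeans(b)
    ss <- (colSums(a^2) - n1 * m1^2) + (colSums(b^2) - n2 * m2^2)
    flagged <- ss <= 0
    sp <- sqrt(pmax(ss, 0) / (n1 + n2 - 2))
    se <- sp * sqrt(1 / n1 + 1 / n2)
    stat <- ifelse(flagged, 0, (m1 - m2) / se)
    return(list(stat = stat, df = n1 + n2 - 2, flagged = flagged))
  }
  # pearson_r
  n <- nrow(a)
  if (n < 4) stopf("need >= 4 units for correlation")
  if (length(scores) != n) stopf("scores length mismatch")
  zs <- scores - mean(scores)
  ss <- sum(zs^2)
  za <- sweep(a, 2, colMeans(a))
  va <- colSums(za^2)
  flagged <- va <= 0 | ss <= 0
  denom <- sqrt(pmax(va, .Machine$double.eps) * max(ss, .Machine$double.eps))
  stat <- ifelse(flagged, 0, as.vector(crossprod(zs, za)) / denom)
  list(stat = stat, df = n - 2, flagged = flagged)
}

# parametric two-sided cluster-forming threshold at cluster_alpha
.cluster_threshold <- function(kind, df, cluster_alpha) {
  tq <- qt(1 - cluster_alpha / 2, df)
  if (kind == "pearson_r") tq / sqrt(df + tq^2) else tq
}

#' Form signed clusters from a thresholded statistic map
#'
#' Connected components over (channel-neighbor, adjacent-frequency,
#' adjacent-bin) links among same-sign suprathreshold cells; the cluster
#' statistic is the mass (sum of the statistic over members).
#'
#' @param stat numeric statistic vector, length `prod(dims)`, laid out
#'   node-fastest then frequency then time.
#' @param threshold positive cluster-forming threshold.
#' @param adjacency an [adjacency_graph()].
#' @param dims `c(n_nodes, n_freq, n_time)`.
#' @param freq_adj,time_adj link neighboring frequencies / time bins.
#' @return list with `labels` (0 = subthreshold), `mass`, `sign` per cluster.
#' @export
form_clusters <- function(stat, threshold, adjacency, dims,
                          freq_adj = TRUE, time_adj = TRUE) {
  if (length(stat) != prod(dims)) stopf("stat length != prod(dims)")
  if (adjacency$n != dims[1]) stopf("adjacency does not cover all nodes")
  sgn <- as.integer(sign(stat) * (abs(stat) > threshold))
  lab <- label_clusters_cpp(sgn, dims[1], dims[2], dims[3],
                            adjacency$neighbors, freq_adj, time_adj)
  k <- max(lab)
  if (k == 0) return(list(labels = lab, mass = numeric(0), sign = integer(0)))
  mass <- as.vector(rowsum(stat[lab > 0], lab[lab > 0]))
  list(labels = lab, mass = mass, sign = as.integer(sign(mass)))
}

.perm_stats_one_sample <- function(X, flips) {
  n <- nrow(X)
  M <- (flips %*% X) / n
  SS <- colSums(X^2)
  V <- sweep(-n * M^2, 2, SS, `+`) / (n - 1)
  Tm <- M / sqrt(pmax(V, 0) / n)
  Tm[!is.finite(Tm)] <- 0
  Tm
}

#' Cluster-based permutation test
#'
#' Thresholds the observed statistic map at the two-sided parametric quantile
#' of the cluster-forming alpha, groups same-sign suprathreshold neighbors
#' into clusters, and compares each observed cluster's |mass| against the
#' permutation null of the maximum |mass| over both signs (family-wise exact
#' by the max-statistic argument). Permutation schemes: sign flips of
#' within-subject values (one-sample/paired), group-label reshuffles
#' (independent), score permutation (correlation).
#'
#' @inheritParams stat_map
#' @param adjacency an [adjacency_graph()].
#' @param dims `c(n_nodes, n_freq, n_time)`; cells of `a` must be laid out
#'   node-fastest.
#' @param cluster_alpha cluster-forming alpha (two-sided).
#' @param n_perm number of randomizations.
#' @param seed integer seed (permutation indices are reproducible).
#' @param freq_adj,time_adj axis adjacency toggles.
#' @return object of class `cluster_result`.
#' @export
permutation_p <- function(a, b = NULL, scores = NULL,
                          kind = c("one_sample_t", "paired_t", "independent_t",
                                   "pearson_r"),
                          adjacency, dims, cluster_alpha = 0.05,
                          n_perm = 1000, seed = 1L,
                          freq_adj = TRUE, time_adj = TRUE) {
  kind <- match.arg(kind)
  obs <- stat_map(a, b, scores, kind)
  thr <- .cluster_threshold(kind, obs$df, cluster_alpha)
  cl <- form_clusters(obs$stat, thr, adjacency, dims, freq_adj, time_adj)

  X <- as.matrix(a)
  if (kind == "paired_t") X <- X - as.matrix(b)
  S <- nrow(X)

  max_mass <- function(stat) {
    cc <- form_clusters(stat, thr, adjacency, dims, freq_adj, time_adj)
    if (!length(cc$mass)) c(0, 0) else c(max(c(cc$mass, 0)), min(c(cc$mass, 0)))
  }

  null_pos <- null_neg <- numeric(n_perm)
  exhaustive <- FALSE
  with_seed(seed, {
    if (kind %in% c("one_sample_t", "paired_t")) {
      if (2^S <= n_perm) {
        warnf("only %d distinct sign flips; enumerating exhaustively", 2^S)
        exhaustive <- TRUE
        flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
        n_perm <- nrow(flips)
        null_pos <- null_neg <- numeric(n_perm)
      } else {
        flips <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
      }
      Tm <- .perm_stats_one_sample(X, flips)
      for (p in seq_len(n_perm)) {
        mm <- max_mass(Tm[p, ])
        null_pos[p] <- mm[1]; null_neg[p] <- mm[2]
      }
    } else if (kind == "independent_t") {
      Xb <- as.matrix(b)
      pool <- rbind(X, Xb)
      n1 <- nrow(X)
      for (p in seq_len(n_perm)) {
        idx <- sample(nrow(pool))
        st <- stat_map(pool[idx[seq_len(n1)], , drop = FALSE],
                       pool[idx[-seq_len(n1)], , drop = FALSE],
                       kind = "independent_t")$stat
        mm <- max_mass(st)
        null_pos[p] <- mm[1]; null_neg[p] <- mm[2]
      }
    } else { # pearson_r
      for (p in seq_len(n_perm)) {
        st <- stat_map(X, scores = sample(scores), kind = "pearson_r")$stat
        mm <- max_mass(st)
        null_pos[p] <- mm[1]; null_neg[p] <- mm[2]
      }
    }
  })
  null_maxabs <- pmax(null_pos, -null_neg)
  p_perm <- if (length(cl$mass))
    vapply(abs(cl$mass), function(m)
      (1 + sum(null_maxabs >= m - 1e-12)) / (n_perm + 1), 0) else numeric(0)

  clusters <- data.frame(id = seq_along(cl$mass), mass = cl$mass,
                         sign = cl$sign, p_perm = p_perm)
  members <- lapply(seq_along(cl$mass), function(k) which(cl$labels == k))
  structure(list(clusters = clusters, members = members, labels = cl$labels,
                 stat = obs$stat, df = obs$df, threshold = thr, dims = dims,
                 kind = kind, cluster_alpha = cluster_alpha,
                 n_perm = n_perm, exhaustive = exhaustive, seed = seed,
                 null_pos = null_pos, null_neg = null_neg,
                 null_maxabs = null_maxabs),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s), %d randomizations, threshold |%s| > %.3f\n",
              x$kind, x$n_perm, if (x$kind == "pearson_r") "r" else "t",
              x$threshold))
  if (!nrow(x$clusters)) cat("  no suprathreshold clusters\n")
  else {
    o <- x$clusters[order(x$clusters$p_perm), ]
    for (i in seq_len(min(5, nrow(o))))
      cat(sprintf("  cluster %d: %d cells, mass %.2f, p = %.4f\n",
                  o$id[i], length(x$members[[o$id[i]]]), o$mass[i], o$p_perm[i]))
    if (nrow(o) > 5) cat(sprintf("  ... and %d more\n", nrow(o) - 5))
  }
  invisible(x)
}

#' Smallest cluster p-value (1 if no clusters)
#' @param x a `cluster_result`.
#' @export
min_cluster_p <- function(x)
  if (nrow(x$clusters)) min(x$clusters$p_perm) else 1

#' Serialize a cluster result to JSON
#' @param x a `cluster_result`.
#' @param path output file.
#' @export
write_cluster_result <- function(x, path) {
  jsonlite::write_json(list(
    kind = x$kind, n_perm = x$n_perm, cluster_alpha = x$cluster_alpha,
    threshold = x$threshold, seed = x$seed, dims = x$dims,
    clusters = x$clusters, members = x$members), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
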