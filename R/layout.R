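# Standard 64-channel 10-10 montage (actiCAP-style label set) on the unit
# sphere; x = right, y = anterior, z = superior.
.montage64 <- local({
  m <- matrix(c(
    -0.308829, 0.950477, -0.034899,  0.308829, 0.950477, -0.034899,
    -0.808524, 0.587427, -0.034899, -0.545007, 0.673028, 0.500000,
     0.000000, 0.719340, 0.694658,  0.545007, 0.673028, 0.500000,
     0.808524, 0.587427, -0.034899, -0.887888, 0.340828, 0.309017,
    -0.374710, 0.374710, 0.848048,  0.374710, 0.374710, 0.848048,
     0.887888, 0.340828, 0.309017, -0.999391, 0.000000, -0.034899,
    -0.719340, 0.000000, 0.694658,  0.000000, 0.000000, 1.000000,
     0.719340, 0.000000, 0.694658,  0.999391, 0.000000, -0.034899,
    -0.861950, -0.280065, -0.422618, -0.887888, -0.340828, 0.309017,
    -0.374710, -0.374710, 0.848048,  0.374710, -0.374710, 0.848048,
     0.887888, -0.340828, 0.309017,  0.861950, -0.280065, -0.422618,
    -0.808524, -0.587427, -0.034899, -0.545007, -0.673028, 0.500000,
     0.000000, -0.719340, 0.694658,  0.545007, -0.673028, 0.500000,
     0.808524, -0.587427, -0.034899, -0.532714, -0.733218, -0.422618,
    -0.308829, -0.950477, -0.034899,  0.000000, -0.999391, -0.034899,
     0.308829, -0.950477, -0.034899,  0.532714, -0.733218, -0.422618,
    -0.587427, 0.808524, -0.034899, -0.406247, 0.871199, 0.275637,
     0.406247, 0.871199, 0.275637,  0.587427, 0.808524, -0.034899,
    -0.728993, 0.633704, 0.258819, -0.286965, 0.710264, 0.642788,
     0.286965, 0.710264, 0.642788,  0.728993, 0.633704, 0.258819,
    -0.861950, 0.280065, -0.422618, -0.950477, 0.308829, -0.034899,
    -0.669792, 0.434968, 0.601815,  0.669792, 0.434968, 0.601815,
     0.950477, 0.308829, -0.034899,  0.861950, 0.280065, -0.422618,
    -0.933580, 0.000000, 0.358368, -0.390731, 0.000000, 0.920505,
     0.390731, 0.000000, 0.920505,  0.933580, 0.000000, 0.358368,
    -0.950477, -0.308829, -0.034899, -0.660881, -0.429181, 0.615661,
     0.000000, -0.390731, 0.920505,  0.660881, -0.429181, 0.615661,
     0.950477, -0.308829, -0.034899, -0.728993, -0.633704, 0.258819,
    -0.286965, -0.710264, 0.642788,  0.286965, -0.710264, 0.642788,
     0.728993, -0.633704, 0.258819, -0.587427, -0.808524, -0.034899,
    -0.406247, -0.871199, 0.275637,  0.000000, -0.933580, 0.358368,
     0.406247, -0.871199, 0.275637,  0.587427, -0.808524, -0.034899),
    ncol = 3, byrow = TRUE)
  rownames(m) <- c("Fp1","Fp2","F7","F3","Fz","F4","F8","FC5","FC1","FC2",
    "FC6","T7","C3","Cz","C4","T8","TP9","CP5","CP1","CP2","CP6","TP10",
    "P7","P3","Pz","P4","P8","PO9","O1","Oz","O2","PO10","AF7","AF3","AF4",
    "AF8","F5","F1","F2","F6","FT9","FT7","FC3","FC4","FT8","FT10","C5",
    "C1","C2","C6","TP7","CP3","CPz","CP4","TP8","P5","P1","P2","P6","PO7",
    "PO3","POz","PO4","PO8")
  colnames(m) <- c("x", "y", "z")
  m
})

#' Sensor layout: labels, unit-sphere positions and channel adjacency
#'
#' The default layout is the full standard 64-channel 10-10 set; a subset of
#' channels can be selected (by count or by name) for reduced-scale analyses.
#' Adjacency links channels whose great-circle separation falls below a
#' threshold chosen so the median neighbor count is close to `target_degree`.
#'
#' @param channels either a channel count (taken from the front of the standard
#'   ordering) or a character vector of labels; default all 64.
#' @param target_degree desired median number of neighbors (default 6).
#' @return object of class `sensor_layout` with elements `labels`,
#'   `positions` (n x 3 unit vectors) and `adjacency` (logical n x n).
#' @export
sensor_layout <- function(channels = 64, target_degree = 6) {
  if (is.numeric(channels)) {
    if (channels < 2 || channels > nrow(.montage64))
      stopf("channels must be in 2..%d", nrow(.montage64))
    if (channels == nrow(.montage64)) labels <- rownames(.montage64)
    else {
      # spatially spread subset: greedy farthest-point sampling from Cz
      P <- .montage64
      sel <- which(rownames(P) == "Cz")
      mind <- acos(pmin(1, pmax(-1, as.vector(P %*% P[sel, ]))))
      while (length(sel) < channels) {
        nxt <- which.max(mind)
        sel <- c(sel, nxt)
        d2 <- acos(pmin(1, pmax(-1, as.vector(P %*% P[nxt, ]))))
        mind <- pmin(mind, d2)
      }
      labels <- rownames(P)[sort(sel)]
    }
  } else {
    miss <- setdiff(channels, rownames(.montage64))
    if (length(miss)) stopf("unknown channels: %s", paste(miss, collapse = ", "))
    labels <- channels
  }
  pos <- .montage64[labels, , drop = FALSE]
  cosang <- tcrossprod(pos)
  ang <- acos(matrix(pmin(1, pmax(-1, cosang)), nrow(pos)))
  diag(ang) <- Inf
  # pick the angular threshold whose induced median degree is nearest target
  cand <- sort(unique(as.vector(ang[is.finite(ang)])))
  cand <- cand[cand <= median(cand)]
  deg <- vapply(cand, function(th) median(rowSums(ang < th + 1e-12)), 0)
  thr <- cand[which.min(abs(deg - target_degree))]
  adj <- ang < thr + 1e-12
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  if (any(rowSums(adj) == 0)) { # guarantee every channel has a neighbor
    for (i in which(rowSums(adj) == 0)) {
      j <- which.min(ang[i, ])
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  dimnames(adj) <- list(labels, labels)
  structure(list(labels = labels, positions = pos, adjacency = adj),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("Sensor layout: %d channels, median degree %g\n",
              length(x$labels), median(rowSums(x$adjacency))))
  invisible(x)
}
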