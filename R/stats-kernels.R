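#' Two-sample t test from raw data
#'
#' Two-sided test of mean difference (A minus B). The pooled variant uses
#' \code{df = nA + nB - 2}; the Welch variant uses the Welch-Satterthwaite
#' degrees of freedom. Degenerate inputs follow explicit conventions: zero
#' variance in both groups with equal means gives \code{t = 0, p = 1}; zero
#' variance with unequal means gives an infinite t with \code{p = 0},
#' flagged via attribute \code{"degenerate"}.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return named list \code{t}, \code{df}, \code{p}.
#' @export
twoSampleT <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopIf(length(a) < 2 || length(b) < 2, "each group needs n >= 2")
  tTestFromSummary(mean(a), stats::sd(a), length(a),
                   mean(b), stats::sd(b), length(b), variant = variant)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: with sorted p-values, reject the hypotheses at or
#' below the largest rank i with \code{p(i) <= (i/m) * alpha}; q-values are
#' the monotone BH-adjusted p-values, so rejection is \code{q <= alpha}.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list \code{q} (adjusted p-values) and \code{reject} (logical).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  stopIf(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference (A minus B) over the pooled SD with
#' \code{(n - 1)} weights.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries; \code{sd >= 0},
#'   \code{n >= 2}, not both SDs zero.
#' @return the effect size d.
#' @export
cohensD <- function(meanA, sdA, nA, meanB, sdB, nB) {
  stopIf(sdA < 0 || sdB < 0, "SDs must be >= 0")
  stopIf(nA < 2 || nB < 2, "each group needs n >= 2")
  stopIf(sdA == 0 && sdB == 0, "both SDs are zero; d is undefined")
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  (meanA - meanB) / sp
}

# Offsets of the "positive" half of a 3D neighborhood.
connectivityOffsets <- function(connectivity) {
  stopIf(!connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  deg <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = deg == 1, "18" = deg <= 2, "26" = deg <= 3)
  off <- off[keep, , drop = FALSE]
  # keep one of each +/- pair: edges are undirected
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
       (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighborhood).
#' @return 3D integer array; 0 outside the mask, component id inside.
#' @export
labelComponents3D <- function(mask, connectivity = 26) {
  stopIf(length(dim(mask)) != 3, "mask must be 3D")
  dims <- dim(mask)
  lab <- array(0L, dims)
  vox <- which(mask)
  if (!length(vox)) return(lab)
  id <- array(0L, dims)
  id[vox] <- seq_along(vox)
  coord <- arrayInd(vox, dims)
  off <- connectivityOffsets(connectivity)
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- coord + matrix(off[r, ], nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nbIdx <- id[nb[ok, , drop = FALSE]]
    hit <- nbIdx > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nbIdx[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(vox), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[vox] <- as.integer(comp)
  lab
}

#' Cluster-extent filtering of a 3D significance mask
#'
#' Removes connected components whose size is not strictly greater than
#' \code{minSize} voxels, and tabulates the surviving clusters. Peak
#' locations use 0-based voxel indices; when a statistic array is supplied
#' the peak is its in-cluster maximum (by absolute value), otherwise the
#' first voxel in array order.
#'
#' @param mask 3D logical array.
#' @param minSize minimum extent; survival requires size \code{> minSize}.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param stat optional 3D numeric array for peak localization.
#' @return list: \code{mask} (filtered logical array) and \code{clusters}
#'   (data.frame \code{cluster}, \code{size}, \code{peak_x/y/z} 0-based).
#' @export
clusterExtentFilter <- function(mask, minSize = 40, connectivity = 26,
                                stat = NULL) {
  lab <- labelComponents3D(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > minSize)
  out <- array(FALSE, dim(mask))
  rows <- lapply(seq_along(keep), function(i) {
    k <- keep[i]
    vox <- which(lab == k)
    out[vox] <<- TRUE
    peak <- if (is.null(stat)) vox[1] else vox[which.max(abs(stat[vox]))]
    pc <- arrayInd(peak, dim(mask)) - 1L
    data.frame(cluster = i, size = sizes[k],
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0))
  list(mask = out, clusters = clusters)
}
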