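#' Searchlight specification
#'
#' @param radius sphere radius in mm (default 10).
#' @param voxel_size voxel size in mm, scalar or per-axis 3-vector.
#' @param mask logical/0-1 3-D array of voxels to analyse.
#' @param min_voxels_per_sphere spheres with fewer in-mask voxels are
#'   flagged missing (default 2).
#' @return an object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius = 10, voxel_size = 1.5, mask,
                             min_voxels_per_sphere = 2L) {
  if (radius < 0) stop("radius must be >= 0")
  voxel_size <- rep(voxel_size, length.out = 3)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty")
  structure(list(radius = radius, voxel_size = voxel_size, mask = mask,
                 min_voxels_per_sphere = as.integer(min_voxels_per_sphere)),
            class = "searchlight_spec")
}

# integer voxel offsets with ||offset * voxel_size|| <= radius
sphere_offsets <- function(radius, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = 3)
  r <- pmax(0L, floor(radius / voxel_size))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
    (g$dz * voxel_size[3])^2
  as.matrix(g[d2 <= radius^2 + 1e-9, , drop = FALSE])
}

#' Voxels inside a searchlight sphere
#'
#' All mask voxels whose centre-to-centre Euclidean distance from the
#' centre voxel is at most the radius (the centre itself included),
#' clipped to the grid and mask.
#'
#' @param spec a [searchlight_spec()].
#' @param center integer 3-vector voxel index (1-based).
#' @return matrix of voxel indices (rows), including the centre.
#' @export
sphere_neighbors <- function(spec, center) {
  stopifnot(inherits(spec, "searchlight_spec"), length(center) == 3)
  dims <- dim(spec$mask)
  if (!spec$mask[center[1], center[2], center[3]])
    stop("center voxel is outside the mask")
  off <- sphere_offsets(spec$radius, spec$voxel_size)
  pts <- sweep(off, 2, as.integer(center), "+")
  ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts <- pts[ok, , drop = FALSE]
  inmask <- spec$mask[pts]
  pts[inmask, , drop = FALSE]
}

#' Searchlight map of corrected decoding accuracies
#'
#' At every mask voxel, runs the full condition-wise corrected-accuracy
#' procedure ([roi_decoding_table()]) on the voxels of the surrounding
#' sphere, and writes per-condition corrected accuracies plus the
#' context contrast (mean corrected `CS` accuracy minus mean corrected
#' `NS` accuracy across complexities) into 3-D maps.
#'
#' Defaults are desk-scale: 100 permutations and 10 neutral subsampling
#' repetitions per sphere (overridable).  With `reuse_chance = TRUE`, the
#' chance level of each condition is estimated once (at the first valid
#' centre) and reused across centres; chance depends on label counts, not
#' sphere location, so this is a fast approximation.
#'
#' @param betas a `beta_series` carrying voxel grid information.
#' @param spec a [searchlight_spec()]; its mask must live on the beta
#'   grid.
#' @param n_perm,n_rep,svm decoding settings, see [roi_decoding_table()].
#' @param seed master seed; per-centre sub-seeds are derived from it.
#' @param reuse_chance reuse one chance estimate per condition.
#' @return an object of class `accuracy_maps`: a named list of 3-D maps
#'   (`NA` outside the mask or where the sphere is too small) —
#'   one per condition plus `"contrast"` — and the grid metadata.
#' @export
run_searchlight <- function(betas, spec, n_perm = 100L, n_rep = 10L,
                            seed = 1L, svm = svm_config(),
                            reuse_chance = FALSE) {
  stopifnot(inherits(betas, "beta_series"), inherits(spec, "searchlight_spec"))
  if (is.null(betas$voxel_index))
    stop("beta series carries no voxel grid information")
  dims <- dim(spec$mask)
  # map grid coordinates -> beta column
  key <- function(m) (m[, 3] - 1L) * dims[1] * dims[2] +
    (m[, 2] - 1L) * dims[1] + m[, 1]
  col_of <- rep(NA_integer_, prod(dims))
  col_of[key(betas$voxel_index)] <- seq_len(ncol(betas$betas))
  centers <- which(spec$mask)
  centers_xyz <- arrayInd(centers, dims)
  cond_names <- c("reinforced.simple", "reinforced.complex",
                  "neutral.simple", "neutral.complex")
  maps <- c(stats::setNames(
    replicate(4, array(NA_real_, dims), simplify = FALSE), cond_names),
    list(contrast = array(NA_real_, dims)))
  seeds <- derive_seeds(seed, length(centers))
  shared_chance <- NULL
  for (ci in seq_along(centers)) {
    ctr <- centers_xyz[ci, ]
    nb <- sphere_neighbors(spec, ctr)
    cols <- col_of[key(nb)]
    cols <- cols[!is.na(cols)]
    if (length(cols) < spec$min_voxels_per_sphere) next
    tab <- roi_decoding_table(betas, voxels = cols,
                              n_perm = if (reuse_chance && !is.null(shared_chance)) 1L else n_perm,
                              n_rep = n_rep, seed = seeds[ci], svm = svm)
    if (reuse_chance) {
      if (is.null(shared_chance)) shared_chance <- tab$chance_accuracy
      tab$corrected_accuracy <- tab$raw_accuracy - shared_chance
    }
    corr <- tab$corrected_accuracy
    names(corr) <- paste(tab$context, tab$complexity, sep = ".")
    for (nm in cond_names)
      maps[[nm]][ctr[1], ctr[2], ctr[3]] <- corr[[nm]]
    cs <- mean(corr[c("reinforced.simple", "reinforced.complex")])
    ns <- mean(corr[c("neutral.simple", "neutral.complex")])
    maps$contrast[ctr[1], ctr[2], ctr[3]] <- cs - ns
  }
  structure(list(maps = maps, mask = spec$mask, radius = spec$radius,
                 voxel_size = spec$voxel_size),
            class = "accuracy_maps")
}

#' Group-level searchlight inference by sign-flip permutation
#'
#' Voxel-wise one-sample t statistics across subjects, with family-wise
#' error control by the max-statistic null over random sign flips of the
#' subject maps (exact under symmetric exchangeability of the per-subject
#' contrast).  Suprathreshold voxels are grouped into 6-connected
#' clusters reported with peak voxel, peak mm coordinate, and volume.
#'
#' @param maps list of per-subject 3-D contrast maps on a common grid
#'   (`NA` outside the analysis mask), or a subjects-by-voxel matrix plus
#'   `dims`.
#' @param n_flips number of sign flips (default 1000; the identity flip
#'   is always included).
#' @param alpha family-wise error level (default 0.05).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param voxel_size voxel size in mm for cluster volumes.
#' @param seed RNG seed for the flips.
#' @param dims grid dimensions when `maps` is a matrix.
#' @return an object of class `group_searchlight` with the t map, the
#'   FWE-corrected threshold, and a cluster table.
#' @export
group_searchlight_inference <- function(maps, n_flips = 1000L, alpha = 0.05,
                                        alternative = c("greater", "two.sided"),
                                        voxel_size = 1.5, seed = 1L,
                                        dims = NULL) {
  alternative <- match.arg(alternative)
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    if (any(!vapply(maps, function(m) identical(dim(m), dims), logical(1))))
      stop("subject maps are not on a common grid")
    M <- do.call(rbind, lapply(maps, as.vector))
  } else {
    M <- as.matrix(maps)
    if (is.null(dims)) stop("supply dims when maps is a matrix")
  }
  n_subj <- nrow(M)
  if (n_subj < 2) stop("need at least 2 subjects")
  invox <- colSums(is.na(M)) == 0 & apply(M, 2, function(v) var(v) > 0)
  if (!any(invox)) {
    return(structure(list(t_map = array(NA_real_, dims), threshold = Inf,
                          alpha = alpha, alternative = alternative,
                          n_flips = n_flips,
                          clusters = label_clusters(array(FALSE, dims),
                                                    array(NA_real_, dims),
                                                    voxel_size),
                          max_null = numeric(0)),
                     class = "group_searchlight"))
  }
  X <- M[, invox, drop = FALSE]
  tstat <- function(Z) {
    mu <- colMeans(Z)
    se <- sqrt(apply(Z, 2, var) / nrow(Z))
    mu / pmax(se, .Machine$double.eps)
  }
  t_obs <- tstat(X)
  stat <- if (alternative == "greater") identity else abs
  flips <- with_seed(seed, matrix(sample(c(-1, 1), (n_flips - 1L) * n_subj,
                                         replace = TRUE), n_flips - 1L, n_subj))
  max_null <- c(max(stat(t_obs)),
                vapply(seq_len(n_flips - 1L),
                       function(i) max(stat(tstat(flips[i, ] * X))),
                       numeric(1)))
  thr <- quantile(max_null, 1 - alpha, type = 1, names = FALSE)
  t_map <- array(NA_real_, dims)
  t_map[which(invox)] <- t_obs
  sig <- !is.na(t_map) & stat(t_map) > thr
  clusters <- label_clusters(sig, t_map, voxel_size)
  structure(list(t_map = t_map, threshold = thr, alpha = alpha,
                 alternative = alternative, n_flips = n_flips,
                 clusters = clusters, max_null = max_null),
            class = "group_searchlight")
}

# 6-connectivity connected components over a logical array
label_clusters <- function(sig, t_map, voxel_size) {
  dims <- dim(sig)
  voxel_size <- rep(voxel_size, length.out = 3)
  lab <- array(0L, dims)
  nxt <- 0L
  idx <- which(sig)
  out <- list()
  for (v in idx) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    members <- integer(0)
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      xyz <- arrayInd(cur, dims)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- xyz
        nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1L || nb[ax] > dims[ax]) next
        li <- (nb[3] - 1L) * dims[1] * dims[2] + (nb[2] - 1L) * dims[1] + nb[1]
        if (sig[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
    pk <- members[which.max(abs(t_map[members]))]
    pk_xyz <- as.integer(arrayInd(pk, dims))
    out[[nxt]] <- data.frame(
      cluster = nxt, n_voxels = length(members),
      volume_cm3 = length(members) * prod(voxel_size) / 1000,
      peak_t = t_map[pk],
      peak_x = pk_xyz[1], peak_y = pk_xyz[2], peak_z = pk_xyz[3],
      peak_mm_x = (pk_xyz[1] - 1) * voxel_size[1],
      peak_mm_y = (pk_xyz[2] - 1) * voxel_size[2],
      peak_mm_z = (pk_xyz[3] - 1) * voxel_size[3])
  }
  if (!length(out))
    return(data.frame(cluster = integer(), n_voxels = integer(),
                      volume_cm3 = numeric(), peak_t = numeric(),
                      peak_x = integer(), peak_y = integer(),
                      peak_z = integer(), peak_mm_x = numeric(),
                      peak_mm_y = numeric(), peak_mm_z = numeric()))
  do.call(rbind, out)
}

#' @export
print.group_searchlight <- function(x, ...) {
  cat(sprintf("<group_searchlight> FWE threshold (alpha %.2f, %s): t > %.3f; %d cluster(s)\n",
              x$alpha, x$alternative, x$threshold, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
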