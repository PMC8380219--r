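#' Grey-level texture matrices
#'
#' Builders for the 3D texture matrices computed from a discretized ROI over
#' the 26-connected neighbourhood at distance 1: co-occurrence (GLCM),
#' run-length (GLRLM), size-zone (GLSZM), distance-zone (GLDZM),
#' neighbourhood grey-tone difference (NGTDM) and neighbouring grey-level
#' dependence (NGLDM). Exposed so tests can compare them against brute-force
#' enumeration.
#'
#' @param d a `discretized_roi` from [discretize()].
#' @param direction integer length-3 displacement vector.
#' @name texture_matrices
NULL

#' @describeIn texture_matrices Symmetric co-occurrence count matrix for one
#'   direction (both orderings of each voxel pair counted).
#' @export
glcm_matrix <- function(d, direction) {
  g <- d$values
  G <- d$n_bins
  b <- shift_array(g, as.integer(direction))
  ok <- !is.na(g) & !is.na(b)
  if (!any(ok)) return(matrix(0, G, G))
  m <- matrix(tabulate((g[ok] - 1L) * G + b[ok], nbins = G * G), G, G, byrow = TRUE)
  m + t(m)
}

#' @describeIn texture_matrices Run counts for one direction as a data frame
#'   with columns `i` (grey level), `j` (run length) and `n` (count).
#' @export
glrlm_counts <- function(d, direction) {
  g <- d$values
  n <- dim(g)
  dvec <- as.integer(direction)
  prev <- shift_array(g, -dvec)  # value at v - d
  is_start <- !is.na(g) & (is.na(prev) | prev != g)
  starts <- which(is_start, arr.ind = TRUE)
  res_i <- integer(0); res_j <- integer(0)
  if (nrow(starts) > 0) {
    for (s in seq_len(nrow(starts))) {
      v <- starts[s, ]
      lev <- g[v[1], v[2], v[3]]
      len <- 1L
      nxt <- v + dvec
      while (all(nxt >= 1L) && all(nxt <= n) &&
             !is.na(g[nxt[1], nxt[2], nxt[3]]) &&
             g[nxt[1], nxt[2], nxt[3]] == lev) {
        len <- len + 1L
        nxt <- nxt + dvec
      }
      res_i <- c(res_i, lev); res_j <- c(res_j, len)
    }
  }
  count_pairs(res_i, res_j)
}

# Aggregate (i, j) observations into count triples.
count_pairs <- function(i, j) {
  if (length(i) == 0) return(data.frame(i = integer(0), j = integer(0), n = integer(0)))
  mj <- max(j)
  key <- (i - 1L) * mj + j
  n <- tabulate(key, nbins = max(key))
  keep <- which(n > 0)
  data.frame(i = (keep - 1L) %/% mj + 1L, j = (keep - 1L) %% mj + 1L, n = n[keep])
}

# Label 26-connected zones of constant grey level. Returns a data frame with
# one row per zone: grey level `i`, zone size `size`, and minimal city-block
# distance of the zone to the ROI edge (`distance`, used by GLDZM).
#' @describeIn texture_matrices Connected zones of constant grey level with
#'   sizes and minimal ROI-edge distances.
#' @export
glszm_zones <- function(d) {
  g <- d$values
  n <- dim(g)
  roi_lin <- which(!is.na(g))
  rank_of <- integer(length(g))
  rank_of[roi_lin] <- seq_along(roi_lin)
  # Union-find over same-grey 26-neighbour pairs.
  parent <- seq_along(roi_lin)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  dirs <- unique_directions_3d()
  for (k in seq_len(nrow(dirs))) {
    d3 <- dirs[k, ]
    b <- shift_array(g, d3)
    same <- which(!is.na(g) & !is.na(b) & g == b)
    if (length(same) == 0) next
    doff <- d3[1] + d3[2] * n[1] + d3[3] * n[1] * n[2]
    a_r <- rank_of[same]; b_r <- rank_of[same + doff]
    for (e in seq_along(a_r)) {
      ra <- find(a_r[e]); rb <- find(b_r[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_along(roi_lin), find, integer(1))
  dmap <- roi_distance_map(!is.na(g))
  zid <- match(root, unique(root))
  sizes <- tabulate(zid)
  lev <- g[roi_lin][match(unique(root), root)]
  dist_min <- vapply(split(dmap[roi_lin], zid), min, integer(1))
  data.frame(i = as.integer(lev), size = sizes,
             distance = as.integer(dist_min))
}

# Minimal number of 6-connected steps from each ROI voxel to a voxel outside
# the ROI (grid border counts as outside); border-adjacent voxels get 1.
roi_distance_map <- function(roi) {
  n <- dim(roi)
  dmap <- array(NA_integer_, dim = n)
  outside_adj <- array(FALSE, dim = n)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    d <- c(0L, 0L, 0L); d[ax] <- s
    outside_adj <- outside_adj | !shift_array(roi, d, fill = FALSE)
  }
  frontier <- roi & outside_adj
  k <- 1L
  while (any(frontier)) {
    dmap[frontier] <- k
    assigned <- !is.na(dmap)
    nxt <- array(FALSE, dim = n)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L); d[ax] <- s
      nxt <- nxt | shift_array(frontier, d, fill = FALSE)
    }
    frontier <- roi & !assigned & nxt
    k <- k + 1L
  }
  dmap
}

#' @describeIn texture_matrices Neighbourhood grey-tone difference table:
#'   per grey level, occupancy `n_i` and summed absolute difference `s_i`
#'   between the level and the mean of each voxel's in-ROI 26-neighbours.
#' @export
ngtdm_table <- function(d) {
  g <- d$values
  G <- d$n_bins
  roi <- !is.na(g)
  gz <- g; gz[!roi] <- 0
  nb_sum <- array(0, dim = dim(g)); nb_cnt <- array(0, dim = dim(g))
  offs <- all_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    nb_sum <- nb_sum + shift_array(gz * 1.0, offs[k, ], 0)
    nb_cnt <- nb_cnt + shift_array(roi * 1.0, offs[k, ], 0)
  }
  valid <- roi & nb_cnt > 0
  abar <- nb_sum[valid] / nb_cnt[valid]
  lev <- g[valid]
  s <- vapply(1:G, function(i) sum(abs(i - abar)[lev == i]), numeric(1))
  ni <- tabulate(lev, nbins = G)
  data.frame(i = 1:G, n = ni, s = s)[ni > 0 | s > 0, , drop = FALSE]
}

#' @describeIn texture_matrices Neighbouring grey-level dependence counts
#'   (coarseness 0): for each ROI voxel, the number of in-ROI 26-neighbours
#'   sharing its grey level; returned as counts over (grey level `i`,
#'   dependence `j` = neighbours + 1).
#' @export
ngldm_counts <- function(d) {
  g <- d$values
  roi <- !is.na(g)
  dep <- array(0L, dim = dim(g))
  offs <- all_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    nb <- shift_array(g, offs[k, ])
    dep <- dep + (!is.na(nb) & !is.na(g) & nb == g)
  }
  count_pairs(g[roi], dep[roi] + 1L)
}
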