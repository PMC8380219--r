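#' Texture features (137 per image)
#'
#' Assembles the texture block from the six matrix families: GLCM with
#' directional-average (26 features, including the maximal correlation
#' coefficient) and merged (25) aggregations, GLRLM with both aggregations
#' (16 each), GLSZM (16), GLDZM (16), NGTDM (5) and NGLDM (17) -- 137 in
#' total. Degenerate single-grey-level ROIs yield 0 for scale-free
#' quantities instead of NaN.
#'
#' @param d a `discretized_roi` from [discretize()].
#' @param prefix name prefix (subband features pass their own).
#' @return Named numeric vector of length 137.
#' @export
texture_features <- function(d, prefix = "texture/") {
  stopifnot(inherits(d, "discretized_roi"))
  dirs <- unique_directions_3d()
  Nv <- sum(!is.na(d$values))
  G <- d$n_bins

  glcm_list <- lapply(seq_len(nrow(dirs)), function(k) glcm_matrix(d, dirs[k, ]))
  nonzero <- vapply(glcm_list, sum, numeric(1)) > 0
  per_dir <- lapply(glcm_list[nonzero], function(m) glcm_features(m / sum(m), mcc = TRUE))
  glcm_avg <- if (length(per_dir)) Reduce(`+`, per_dir) / length(per_dir) else
    stats::setNames(numeric(26), names(glcm_features(matrix(1, 1, 1), mcc = TRUE)))
  merged <- Reduce(`+`, glcm_list)
  glcm_mrg <- if (sum(merged) > 0) glcm_features(merged / sum(merged), mcc = FALSE) else
    stats::setNames(numeric(25), names(glcm_features(matrix(1, 1, 1), mcc = FALSE)))

  rlm_list <- lapply(seq_len(nrow(dirs)), function(k) glrlm_counts(d, dirs[k, ]))
  rlm_per_dir <- lapply(rlm_list, function(cc) rlm_core(cc, Nv, denom_dirs = 1))
  glrlm_avg <- Reduce(`+`, rlm_per_dir) / length(rlm_per_dir)
  rlm_all <- do.call(rbind, rlm_list)
  rlm_all <- stats::aggregate(n ~ i + j, data = rlm_all, FUN = sum)
  glrlm_mrg <- rlm_core(rlm_all, Nv, denom_dirs = nrow(dirs))

  zones <- glszm_zones(d)
  szm <- rlm_core(data.frame(i = zones$i, j = zones$size, n = 1L), Nv, denom_dirs = 1)
  dzm <- rlm_core(data.frame(i = zones$i, j = zones$distance, n = 1L), Nv, denom_dirs = 1)

  ngtdm <- ngtdm_features(ngtdm_table(d), Nv)
  ngldm <- ngldm_features(ngldm_counts(d), Nv)

  out <- c(
    stats::setNames(glcm_avg, paste0(prefix, "glcm_avg/", names(glcm_avg))),
    stats::setNames(glcm_mrg, paste0(prefix, "glcm_mrg/", names(glcm_mrg))),
    stats::setNames(glrlm_avg, paste0(prefix, "glrlm_avg/", rlm_names("run", "run_length"))),
    stats::setNames(glrlm_mrg, paste0(prefix, "glrlm_mrg/", rlm_names("run", "run_length"))),
    stats::setNames(szm, paste0(prefix, "glszm/", rlm_names("zone", "zone_size"))),
    stats::setNames(dzm, paste0(prefix, "gldzm/", rlm_names("distance", "zone_distance"))),
    stats::setNames(ngtdm, paste0(prefix, "ngtdm/", names(ngtdm))),
    stats::setNames(ngldm, paste0(prefix, "ngldm/", names(ngldm)))
  )
  out
}

# ---- GLCM ------------------------------------------------------------------

# Features of a probability-normalized symmetric co-occurrence matrix.
glcm_features <- function(P, mcc = FALSE) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  pm <- rowSums(P)                      # marginal (symmetric)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  sig <- sqrt(sig2)

  kdiff <- 0:(G - 1)
  pd <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * G)
  ps <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(kdiff * pd)
  sa <- sum(ksum * ps)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  hx <- ent(pm)
  pipj <- outer(pm, pm)
  hxy1 <- -sum(P[pipj > 0] * log2(pipj[pipj > 0]))
  hxy2 <- ent(pipj)
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy) * log(2))) else 0

  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  off <- i != j
  inv_var <- if (any(off)) sum(P[off] / (i[off] - j[off])^2) else 0

  out <- c(
    joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sig2,
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((kdiff - da)^2 * pd),
    difference_entropy = ent(pd),
    sum_average = sa,
    sum_variance = sum((ksum - sa)^2 * ps),
    sum_entropy = ent(ps),
    angular_second_moment = sum(P^2),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_normalised = sum(P / (1 + abs(i - j) / G)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_normalised = sum(P / (1 + (i - j)^2 / G^2)),
    inverse_variance = inv_var,
    correlation = corr,
    autocorrelation = sum(i * j * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    information_correlation_1 = ic1,
    information_correlation_2 = ic2
  )
  if (mcc) out <- c(out, maximal_correlation_coefficient = glcm_mcc(P, pm))
  out
}

glcm_mcc <- function(P, pm) {
  keep <- pm > 0
  if (sum(keep) < 2) return(0)
  Pk <- P[keep, keep, drop = FALSE]
  mk <- pm[keep]
  Q <- matrix(0, nrow(Pk), nrow(Pk))
  for (kk in seq_len(ncol(Pk))) {
    Q <- Q + outer(Pk[, kk] / mk, Pk[, kk]) / mk[kk]
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2) return(0)
  sqrt(max(min(ev[2], 1), 0))
}

# ---- run/zone/dependence length families ----------------------------------

# Sixteen standard quantities shared by GLRLM / GLSZM / GLDZM from count
# triples (grey level i, length j, count n). Order matches rlm_names().
rlm_core <- function(cc, Nv, denom_dirs = 1) {
  if (nrow(cc) == 0 || sum(cc$n) == 0) return(numeric(16))
  Ns <- sum(cc$n)
  p <- cc$n / Ns
  i <- cc$i; j <- cc$j
  gl_marg <- tapply(cc$n, cc$i, sum)
  rl_marg <- tapply(cc$n, cc$j, sum)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  pe <- p[p > 0]
  c(
    sum(p / j^2),                      # short emphasis
    sum(p * j^2),                      # long emphasis
    sum(p / i^2),                      # low grey level
    sum(p * i^2),                      # high grey level
    sum(p / (i^2 * j^2)),              # short low
    sum(p * i^2 / j^2),                # short high
    sum(p * j^2 / i^2),                # long low
    sum(p * i^2 * j^2),                # long high
    sum(gl_marg^2) / Ns,               # grey level non-uniformity
    sum(gl_marg^2) / Ns^2,             # ... normalised
    sum(rl_marg^2) / Ns,               # length non-uniformity
    sum(rl_marg^2) / Ns^2,             # ... normalised
    Ns / (Nv * denom_dirs),            # percentage
    sum(p * (i - mu_i)^2),             # grey level variance
    sum(p * (j - mu_j)^2),             # length variance
    -sum(pe * log2(pe))                # entropy
  )
}

rlm_names <- function(short_word, length_word) {
  sw <- switch(short_word, run = c("short_runs", "long_runs", "run"),
               zone = c("small_zone", "large_zone", "zone"),
               distance = c("small_distance", "large_distance", "zone"))
  c(paste0(sw[1], "_emphasis"),
    paste0(sw[2], "_emphasis"),
    paste0("low_grey_level_", sw[3], "_emphasis"),
    paste0("high_grey_level_", sw[3], "_emphasis"),
    paste0(sw[1], "_low_grey_level_emphasis"),
    paste0(sw[1], "_high_grey_level_emphasis"),
    paste0(sw[2], "_low_grey_level_emphasis"),
    paste0(sw[2], "_high_grey_level_emphasis"),
    "grey_level_non_uniformity",
    "grey_level_non_uniformity_normalised",
    paste0(length_word, "_non_uniformity"),
    paste0(length_word, "_non_uniformity_normalised"),
    if (short_word == "run") "run_percentage" else "zone_percentage",
    "grey_level_variance",
    paste0(length_word, "_variance"),
    paste0(length_word, "_entropy"))
}

# ---- NGTDM -----------------------------------------------------------------

ngtdm_features <- function(tab, Nv) {
  pres <- tab[tab$n > 0, , drop = FALSE]
  pi_ <- pres$n / Nv
  si <- pres$s
  ii <- pres$i
  Ngp <- nrow(pres)
  coars_den <- sum(pi_ * si)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  if (Ngp > 1) {
    pij_grid <- expand.grid(a = seq_len(Ngp), b = seq_len(Ngp))
    ia <- ii[pij_grid$a]; ib <- ii[pij_grid$b]
    pa <- pi_[pij_grid$a]; pb <- pi_[pij_grid$b]
    sa <- si[pij_grid$a]; sb <- si[pij_grid$b]
    contrast <- sum(pa * pb * (ia - ib)^2) / (Ngp * (Ngp - 1)) * sum(si) / Nv
    bus_den <- sum(abs(ia * pa - ib * pb)[pij_grid$a != pij_grid$b])
    busyness <- if (bus_den > 0) sum(pi_ * si) / bus_den else 0
    complexity <- sum(abs(ia - ib) * (pa * sa + pb * sb) / (pa + pb)) / Nv
    strength <- if (sum(si) > 0) sum((pa + pb) * (ia - ib)^2) / sum(si) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

# ---- NGLDM -----------------------------------------------------------------

ngldm_features <- function(cc, Nv) {
  Ns <- sum(cc$n)
  p <- cc$n / Ns
  i <- cc$i; j <- cc$j
  gl_marg <- tapply(cc$n, cc$i, sum)
  dc_marg <- tapply(cc$n, cc$j, sum)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  pe <- p[p > 0]
  c(
    low_dependence_emphasis = sum(p / j^2),
    high_dependence_emphasis = sum(p * j^2),
    low_grey_level_count_emphasis = sum(p / i^2),
    high_grey_level_count_emphasis = sum(p * i^2),
    low_dependence_low_grey_level_emphasis = sum(p / (i^2 * j^2)),
    low_dependence_high_grey_level_emphasis = sum(p * i^2 / j^2),
    high_dependence_low_grey_level_emphasis = sum(p * j^2 / i^2),
    high_dependence_high_grey_level_emphasis = sum(p * i^2 * j^2),
    grey_level_non_uniformity = sum(gl_marg^2) / Ns,
    grey_level_non_uniformity_normalised = sum(gl_marg^2) / Ns^2,
    dependence_count_non_uniformity = sum(dc_marg^2) / Ns,
    dependence_count_non_uniformity_normalised = sum(dc_marg^2) / Ns^2,
    dependence_count_percentage = Ns / Nv,
    grey_level_variance = sum(p * (i - mu_i)^2),
    dependence_count_variance = sum(p * (j - mu_j)^2),
    dependence_count_entropy = -sum(pe * log2(pe)),
    dependence_count_energy = sum(pe^2)
  )
}
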