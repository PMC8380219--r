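# Independent oracles used across the suite. These deliberately use naive
# enumeration / first-principles formulas, never the package's own code path.

# Wrap an integer 3D array (0 = outside ROI) as a discretized ROI.
toy_droi <- function(arr, bin_size = 1, spacing = c(1, 1, 1)) {
  arr <- as.array(arr)
  vals <- array(NA_integer_, dim = dim(arr))
  vals[arr > 0] <- as.integer(arr[arr > 0])
  structure(list(values = vals, n_bins = max(vals, na.rm = TRUE),
                 bin_size = bin_size, spacing_mm = spacing),
            class = "discretized_roi")
}

# Brute-force symmetric co-occurrence counts by looping over every voxel pair.
oracle_glcm <- function(arr, direction) {
  n <- dim(arr)
  G <- max(arr)
  M <- matrix(0, G, G)
  for (x in 1:n[1]) for (y in 1:n[2]) for (z in 1:n[3]) {
    if (arr[x, y, z] == 0) next
    p <- c(x, y, z) + direction
    if (any(p < 1) || any(p > n)) next
    if (arr[p[1], p[2], p[3]] == 0) next
    a <- arr[x, y, z]; b <- arr[p[1], p[2], p[3]]
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# Brute-force run-length counts: walk every maximal run along `direction`.
oracle_glrlm <- function(arr, direction) {
  n <- dim(arr)
  runs <- list()
  for (x in 1:n[1]) for (y in 1:n[2]) for (z in 1:n[3]) {
    v <- c(x, y, z)
    if (arr[x, y, z] == 0) next
    prev <- v - direction
    if (all(prev >= 1) && all(prev <= n) &&
        arr[prev[1], prev[2], prev[3]] == arr[x, y, z]) next
    len <- 1
    nxt <- v + direction
    while (all(nxt >= 1) && all(nxt <= n) &&
           arr[nxt[1], nxt[2], nxt[3]] == arr[x, y, z]) {
      len <- len + 1
      nxt <- nxt + direction
    }
    runs[[length(runs) + 1]] <- c(arr[x, y, z], len)
  }
  m <- do.call(rbind, runs)
  out <- as.data.frame(table(i = m[, 1], j = m[, 2]), stringsAsFactors = FALSE)
  out <- out[out$Freq > 0, ]
  data.frame(i = as.integer(out$i), j = as.integer(out$j), n = out$Freq)
}

# Brute-force neighbouring grey-level dependence counts.
oracle_ngldm <- function(arr) {
  n <- dim(arr)
  res <- list()
  for (x in 1:n[1]) for (y in 1:n[2]) for (z in 1:n[3]) {
    if (arr[x, y, z] == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1) || any(p > n)) next
      if (arr[p[1], p[2], p[3]] == arr[x, y, z]) dep <- dep + 1
    }
    res[[length(res) + 1]] <- c(arr[x, y, z], dep + 1)
  }
  m <- do.call(rbind, res)
  out <- as.data.frame(table(i = m[, 1], j = m[, 2]), stringsAsFactors = FALSE)
  out <- out[out$Freq > 0, ]
  data.frame(i = as.integer(out$i), j = as.integer(out$j), n = out$Freq)
}

sort_triples <- function(df) {
  df <- df[order(df$i, df$j), c("i", "j", "n")]
  rownames(df) <- NULL
  df
}

# ICC oracle from explicit ANOVA sums of squares.
oracle_icc <- function(m, form) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - gm)^2)
  ss_cols <- n * sum((colMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_within <- ss_tot - ss_rows
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  wms <- ss_within / (n * (k - 1))
  ems <- ss_err / ((n - 1) * (k - 1))
  switch(form,
         ICC_1_1 = (bms - wms) / (bms + (k - 1) * wms),
         ICC_3_1 = (bms - ems) / (bms + (k - 1) * ems),
         ICC_3_k = (bms - ems) / bms)
}

# Exhaustive pairwise-concordance AUC.
oracle_auc <- function(x, labels) {
  cases <- x[labels == 1]; controls <- x[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Small heterogeneous phantom used where full-size extraction would be slow.
small_phantom <- function(seed = 7) {
  phantom_spec(seed = seed, grid_shape = c(28L, 28L, 28L),
               voxel_spacing_mm = c(3, 3, 3), tumour_radii_mm = c(18, 16, 15))
}
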