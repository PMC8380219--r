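# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage seed derived from one master seed; kept below 2^31.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(master)) * 48271 + offs * 1009 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_petrad <- function(...) stop(..., call. = FALSE)

# 13 unique displacement vectors covering the 26-connected 3D neighbourhood
# (each opposite pair counted once).
unique_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# All 26 neighbour offsets.
all_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

# Shift a 3D array by integer offset d, filling exposed planes with `fill`.
# out[i] corresponds to x[i + d] (values pulled from the offset position).
shift_array <- function(x, d, fill = NA_real_) {
  n <- dim(x)
  out <- array(fill, dim = n)
  src_from <- pmax(1L, 1L + d)
  src_to <- pmin(n, n + d)
  if (any(src_from > src_to)) return(out)
  dst_from <- pmax(1L, 1L - d)
  dst_to <- dst_from + (src_to - src_from)
  out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2], dst_from[3]:dst_to[3]] <-
    x[src_from[1]:src_to[1], src_from[2]:src_to[2], src_from[3]:src_to[3]]
  out
}
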