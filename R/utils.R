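# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Validation helpers: stop with the offending field named, as the
# synthetic-data contracts require.
check_that <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             allow_na = FALSE) {
  check_that(is.numeric(x) && length(x) == 1L, field, "must be a numeric scalar")
  if (!allow_na) check_that(is.finite(x), field, "must be finite")
  check_that(is.na(x) || (x >= lower && x <= upper), field,
             sprintf("must be in [%g, %g]", lower, upper))
  invisible(x)
}

# Shift a matrix by (dr, dc), padding with `fill`. Used for vectorized
# neighborhood operations on binary images.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Offsets of the 8-neighborhood.
NEIGH8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1,  0,  1, -1, 1, -1, 0, 1))

# Count of set 8-neighbors for every pixel of a logical matrix.
neighbor_count8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  acc <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(nrow(NEIGH8)))
    acc <- acc + shift_mat(m, NEIGH8[k, 1L], NEIGH8[k, 2L])
  acc
}

# 8-connected component labeling of a logical matrix. EBImage::bwlabel is
# 4-connected, so components are taken from the pixel-adjacency graph.
# Returns an integer matrix (0 = background), labels in first-pixel order.
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  edges <- adjacency_pairs8(mask)
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(edges$a, idx), to = match(edges$b, idx)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  comp <- igraph::components(g)$membership
  # idx is ascending, so first-appearance order gives deterministic labels
  lab[idx] <- as.integer(factor(comp, levels = unique(comp)))
  lab
}

# All 8-adjacent pixel pairs (linear indices a < b in scan order of the four
# forward directions) within a logical mask.
adjacency_pairs8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  lin <- which(mask)
  res_a <- integer(0); res_b <- integer(0); diagw <- logical(0)
  dirs <- cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))
  inmask <- mask
  for (k in seq_len(nrow(dirs))) {
    dr <- dirs[k, 1L]; dc <- dirs[k, 2L]
    r2 <- idx[, 1L] + dr; c2 <- idx[, 2L] + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (!any(ok)) next
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- inmask[lin2]
    res_a <- c(res_a, lin[ok][hit])
    res_b <- c(res_b, lin2[hit])
    diagw <- c(diagw, rep(dr != 0 & dc != 0, sum(hit)))
  }
  list(a = res_a, b = res_b, diagonal = diagw)
}

# Total centerline length (in pixel units) of a thin binary skeleton:
# orthogonal links count 1, diagonal links sqrt(2), and diagonal links that
# shortcut a corner (both pixels share an orthogonally adjacent common
# skeleton pixel) are dropped so a staircase path is not double counted.
centerline_length_px <- function(mask) {
  e <- pruned_edges8(mask)
  if (!length(e$a)) return(0)
  sum(ifelse(e$diagonal, sqrt(2), 1))
}

# Adjacency pairs with triangle-shortcut diagonals removed.
pruned_edges8 <- function(mask) {
  e <- adjacency_pairs8(mask)
  if (!length(e$a)) return(e)
  nr <- nrow(mask)
  keep <- rep(TRUE, length(e$a))
  d <- which(e$diagonal)
  if (length(d)) {
    ra <- (e$a[d] - 1L) %% nr + 1L; ca <- (e$a[d] - 1L) %/% nr + 1L
    rb <- (e$b[d] - 1L) %% nr + 1L; cb <- (e$b[d] - 1L) %/% nr + 1L
    # the two orthogonal "via" pixels of the unit square
    v1 <- (ca - 1L) * nr + rb  # (rb, ca)
    v2 <- (cb - 1L) * nr + ra  # (ra, cb)
    keep[d] <- !(mask[v1] | mask[v2])
  }
  list(a = e$a[keep], b = e$b[keep], diagonal = e$diagonal[keep])
}

# Pixel graph of a thin skeleton on the shortcut-pruned adjacency:
# orthogonal links always count; a diagonal link is dropped when an
# orthogonal two-step path exists through a common neighbor (it is a
# triangle shortcut, not a separate connection). Degrees on this graph
# give the topological valence of each centerline pixel — free of the
# spurious +1s that raw 8-neighbor counts pick up next to junctions.
# Returns linear indices, an adjacency list (by position in `idx`,
# values are linear indices), and the degree of every pixel.
skeleton_pixel_graph <- function(mask) {
  idx <- which(mask)
  adj <- vector("list", length(idx))
  if (length(idx)) {
    e <- pruned_edges8(mask)
    if (length(e$a)) {
      pa <- match(e$a, idx); pb <- match(e$b, idx)
      for (k in seq_along(pa)) {
        adj[[pa[k]]] <- c(adj[[pa[k]]], e$b[k])
        adj[[pb[k]]] <- c(adj[[pb[k]]], e$a[k])
      }
    }
  }
  deg <- matrix(0L, nrow(mask), ncol(mask))
  deg[idx] <- lengths(adj)
  list(idx = idx, adj = adj, deg = deg)
}

# Sample moments used by the morphometry module.
sample_skewness <- function(x) e1071::skewness(x, type = 2)
sample_kurtosis <- function(x) e1071::kurtosis(x, type = 2)
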