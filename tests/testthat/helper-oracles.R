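# Independent oracles and tiny fixture builders. These deliberately use
# different algorithms (and no pamvasc internals) from the code they check.

# Exhaustive nearest-background distance for each query pixel of `mask`
# (TRUE = foreground). Chunked vectorized O(n_query * n_background).
# With `boundary_only`, candidates are restricted to background pixels
# that touch foreground; this is exact, not approximate: the nearest
# background pixel b to a foreground query q always has a foreground
# 8-neighbor (step from b one pixel toward q — that pixel is strictly
# closer to q, so it cannot be background).
brute_nearest_background <- function(mask, query_idx, boundary_only = FALSE) {
  cand <- !mask
  if (boundary_only) {
    nr <- nrow(mask); nc <- ncol(mask)
    touch <- matrix(FALSE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      touch[rs, cs] <- touch[rs, cs] | mask[rs - dr, cs - dc]
    }
    cand <- cand & touch
  }
  bg <- which(cand, arr.ind = TRUE)
  qr <- (query_idx - 1L) %% nrow(mask) + 1L
  qc <- (query_idx - 1L) %/% nrow(mask) + 1L
  out <- numeric(length(query_idx))
  chunk <- 200L
  for (s in seq(1L, length(query_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(query_idx))
    d2 <- outer(qr[s:e], bg[, 1L], "-")^2 + outer(qc[s:e], bg[, 2L], "-")^2
    out[s:e] <- sqrt(apply(d2, 1L, min))
  }
  out
}

# Flood fill (8-connectivity) from scratch with an explicit stack;
# returns an integer label matrix.
flood_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    stack <- p
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[q] > 0L) next
      lab[q] <- cur
      r <- (q - 1L) %% nr + 1L; c <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          q2 <- (c2 - 1L) * nr + r2
          if (mask[q2] && lab[q2] == 0L) stack <- c(stack, q2)
        }
      }
    }
  }
  lab
}

# Pruned neighbors of pixel (r, c): all orthogonal skeleton neighbors,
# plus diagonal neighbors that are NOT shortcut by an orthogonal two-step
# path (neither shared orthogonal "via" pixel is set). Explicitly looped,
# independent of the package's vectorized edge machinery.
oracle_neighbors <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  inb <- function(r2, c2) r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
    mask[r2, c2]
  out <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (!inb(r2, c2)) next
    if (dr != 0 && dc != 0) {
      via1 <- inb(r, c2); via2 <- inb(r2, c)
      if (via1 || via2) next
    }
    out <- rbind(out, c(r2, c2))
  }
  out
}

loop_pruned_degree <- function(mask) {
  nr <- nrow(mask)
  out <- matrix(0L, nr, ncol(mask))
  for (p in which(mask)) {
    r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
    nb <- oracle_neighbors(mask, r, c)
    out[p] <- if (is.null(nb)) 0L else nrow(nb)
  }
  out
}

# Flood fill restricted to a pixel subset, walking pruned adjacency.
flood_label_pruned <- function(mask, subset) {
  nr <- nrow(mask)
  lab <- matrix(0L, nr, ncol(mask))
  cur <- 0L
  for (p in which(subset)) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    stack <- p
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[q] > 0L) next
      lab[q] <- cur
      r <- (q - 1L) %% nr + 1L; c <- (q - 1L) %/% nr + 1L
      nb <- oracle_neighbors(mask, r, c)
      if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
        q2 <- (nb[k, 2] - 1L) * nr + nb[k, 1]
        if (subset[q2] && lab[q2] == 0L) stack <- c(stack, q2)
      }
    }
  }
  lab
}

# Independent skeleton element counts: endpoints (pruned degree 1),
# merged branch-node clusters (flood fill over pixels with pruned degree
# >= 3), and segments (slab-chain components plus direct pruned
# adjacencies between distinct node clusters).
oracle_skeleton_counts <- function(skel) {
  deg <- loop_pruned_degree(skel)
  endpoints <- sum(skel & deg == 1L)
  branch_px <- skel & deg >= 3L
  branch_lab <- flood_label8(branch_px)
  n_branch_nodes <- max(branch_lab, 0L)

  # node id per pixel: branch clusters, then endpoints as singletons
  nr <- nrow(skel)
  node_id <- branch_lab
  eps <- which(skel & deg == 1L)
  node_id[eps] <- n_branch_nodes + seq_along(eps)

  slab <- skel & deg == 2L
  n_slab_comp <- max(flood_label_pruned(skel, slab), 0L)

  n_direct <- 0L
  for (p in which(node_id > 0L)) {
    r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
    nb <- oracle_neighbors(skel, r, c)
    if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
      q <- (nb[k, 2] - 1L) * nr + nb[k, 1]
      if (node_id[q] > 0L && node_id[q] != node_id[p] && q > p)
        n_direct <- n_direct + 1L
    }
  }
  list(n_endpoints = endpoints, n_branch_nodes = n_branch_nodes,
       n_segments = n_slab_comp + n_direct)
}

# Two-sided Welch p-value by numerical quadrature of the t density
# (independent of pt()).
quadrature_welch_p <- function(tstat, df) {
  if (!is.finite(tstat)) return(0)
  upper <- stats::integrate(function(x) stats::dt(x, df), abs(tstat), Inf,
                            rel.tol = 1e-12)$value
  2 * upper
}

# AUC by exhaustive positive-negative pair counting (ties = 1/2).
pair_count_auc <- function(probs, labels) {
  lab <- factor(labels)
  pos <- which(lab == levels(lab)[2L])
  neg <- which(lab == levels(lab)[1L])
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
  tot / (length(pos) * length(neg))
}

# Fixture masks -------------------------------------------------------

# Horizontal bar of given height centered in a padded frame.
make_bar_mask <- function(height = 11L, width = 60L, pad = 10L) {
  nr <- height + 2L * pad; nc <- width + 2L * pad
  m <- matrix(FALSE, nr, nc)
  m[pad + seq_len(height), pad + seq_len(width)] <- TRUE
  m
}

# Perfect "Y": three straight arms meeting at one junction pixel.
make_y_skeleton <- function(arm = 20L, pad = 5L) {
  n <- 2L * (arm + pad) + 1L
  m <- matrix(FALSE, n, n)
  cx <- arm + pad + 1L
  m[cx, cx:(cx + arm)] <- TRUE                      # east arm
  for (k in seq_len(arm)) {                         # two diagonal arms
    m[cx - k, cx - k] <- TRUE
    m[cx + k, cx - k] <- TRUE
  }
  m[cx, cx] <- TRUE
  m
}

# "H": two vertical bars joined by a horizontal crossbar of `cross` steps.
make_h_skeleton <- function(arm = 12L, cross = 40L, pad = 5L) {
  nr <- 2L * arm + 2L * pad + 1L
  nc <- cross + 2L * pad + 1L
  m <- matrix(FALSE, nr, nc)
  mid <- arm + pad + 1L
  c1 <- pad + 1L; c2 <- pad + 1L + cross
  m[(mid - arm):(mid + arm), c1] <- TRUE
  m[(mid - arm):(mid + arm), c2] <- TRUE
  m[mid, c1:c2] <- TRUE
  m
}

# Small random blob mask for property tests (seeded).
random_blob_mask <- function(seed, nr = 48L, nc = 48L, p = 0.4,
                             smooth = TRUE) {
  set.seed(seed)
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (smooth) {
    img <- EBImage::Image(m * 1)
    m <- EBImage::imageData(EBImage::closing(
      EBImage::opening(img, EBImage::makeBrush(3, "box")),
      EBImage::makeBrush(3, "box"))) > 0.5
  }
  m
}

# Small phantom used across suites (kept light for test speed).
small_phantom <- function(seed, ...) {
  generate_vessel_phantom(vessel_network_spec(
    seed = seed, image_size_px = c(128L, 128L), ...))
}
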