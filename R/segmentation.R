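#' Enhance vessel contrast and subtract background
#'
#' Removes slowly varying background by grayscale morphological opening
#' with a disc structuring element (the rolling-ball analogue: the opening
#' is the background estimate, and subtracting it flattens illumination
#' and absorbs any constant offset exactly), then applies contrast-limited
#' adaptive histogram equalization (CLAHE) to the normalized residual.
#'
#' @param mip an [mip_image()].
#' @param clahe_clip CLAHE clip limit (`limit` of [EBImage::clahe()]);
#'   higher values allow stronger local amplification.
#' @param ball_radius_px radius (px) of the background disc; must be
#'   smaller than the image and larger than a vessel radius to avoid
#'   eroding vessels into the background estimate.
#' @param clahe_grid number of CLAHE tiles along each axis.
#' @return An [mip_image()] with nonnegative enhanced intensities.
#' @export
enhance_and_subtract <- function(mip, clahe_clip = 2, ball_radius_px = 25,
                                 clahe_grid = 8) {
  if (!inherits(mip, "mip_image"))
    stop("`mip` must be a mip_image", call. = FALSE)
  check_scalar_num(clahe_clip, "clahe_clip", lower = 1e-12)
  check_scalar_num(ball_radius_px, "ball_radius_px", lower = 1)
  img <- mip$intensity
  check_that(2 * ball_radius_px + 1 < min(dim(img)), "ball_radius_px",
             "must be smaller than the image")
  brush <- EBImage::makeBrush(2 * round(ball_radius_px) + 1, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(img), brush))
  res <- pmax(img - bg, 0)
  if (max(res) > 0) {
    res <- res / max(res)
    # CLAHE needs tiles at least a few pixels wide
    nx <- max(2L, min(clahe_grid, floor(min(dim(img)) / 8)))
    res <- EBImage::imageData(EBImage::clahe(EBImage::Image(res), nx = nx,
                                             ny = nx, limit = clahe_clip))
    res <- pmax(res, 0)
  }
  mip_image(matrix(res, nrow(img), ncol(img)),
            pixel_size_um = mip$pixel_size_um,
            dynamic_range_db = mip$dynamic_range_db)
}

#' Binarize an enhanced MIP into a vessel mask
#'
#' Global Otsu thresholding (on a 256-bin histogram of the normalized
#' image) or locally adaptive mean thresholding, followed by removal of
#' connected components (8-connectivity) smaller than `min_area_px`.
#'
#' @param img an [mip_image()].
#' @param method `"otsu"` or `"adaptive"`.
#' @param min_area_px remove objects with fewer pixels than this
#'   (0 disables despeckling).
#' @param adaptive_width window half-width for the adaptive method.
#' @param adaptive_offset offset above the local mean for the adaptive
#'   method (on the normalized 0-1 scale).
#' @return A [vessel_mask()].
#' @export
binarize <- function(img, method = c("otsu", "adaptive"), min_area_px = 10,
                     adaptive_width = 15, adaptive_offset = 0.02) {
  if (!inherits(img, "mip_image"))
    stop("`img` must be a mip_image", call. = FALSE)
  method <- match.arg(method)
  check_scalar_num(min_area_px, "min_area_px", lower = 0)
  x <- img$intensity
  rng <- range(x)
  if (method == "otsu") {
    if (diff(rng) <= 0) stop("degenerate histogram", call. = FALSE)
    xn <- (x - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256)
    mask <- xn > thr
  } else {
    xn <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
    w <- 2 * round(adaptive_width) + 1
    mask <- EBImage::imageData(
      EBImage::thresh(EBImage::Image(xn), w = w, h = w,
                      offset = adaptive_offset)) > 0.5
  }
  mask <- matrix(as.logical(mask), nrow(x), ncol(x))
  if (min_area_px > 0 && any(mask)) {
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_px)
    mask <- matrix(lab %in% keep, nrow(x), ncol(x))
  }
  vessel_mask(mask, pixel_size_um = img$pixel_size_um)
}

# Guo-Hall two-subiteration thinning step, vectorized over the image.
# Neighbor naming: p2 = N, p3 = NE, p4 = E, p5 = SE, p6 = S, p7 = SW,
# p8 = W, p9 = NW (row index increases to the south, col to the east).
guo_hall_step <- function(m, odd) {
  p2 <- shift_mat(m,  1,  0); p6 <- shift_mat(m, -1,  0)
  p4 <- shift_mat(m,  0, -1); p8 <- shift_mat(m,  0,  1)
  p3 <- shift_mat(m,  1, -1); p5 <- shift_mat(m, -1, -1)
  p7 <- shift_mat(m, -1,  1); p9 <- shift_mat(m,  1,  1)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N <- pmin(N1, N2)
  m2 <- if (odd) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
  del <- m & (C == 1) & (N >= 2) & (N <= 3) & !m2
  m & !del
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving medial-axis thinning (Guo-Hall two-subiteration
#' algorithm) down to one-pixel-wide centerlines under 8-connectivity.
#' Connected components are preserved; an empty mask yields an empty
#' skeleton.
#'
#' @param mask a [vessel_mask()].
#' @return A [skeleton_mask()] (a pixelwise subset of `mask`).
#' @export
skeletonize_mask <- function(mask) {
  if (!inherits(mask, "vessel_mask"))
    stop("`mask` must be a vessel_mask", call. = FALSE)
  m <- mask$mask
  mode(m) <- "logical"
  repeat {
    m1 <- guo_hall_step(m, odd = TRUE)
    m2 <- guo_hall_step(m1, odd = FALSE)
    if (identical(m2, m)) break
    m <- m2
  }
  m <- clear_square_blocks(m)
  skeleton_mask(m, pixel_size_um = mask$pixel_size_um)
}

# Guo-Hall's connectivity number of pixel (r, c): 1 means deleting the
# pixel cannot split its neighborhood.
gh_connectivity <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(dr, dc) {
    r2 <- r + dr; c2 <- c + dc
    r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && m[r2, c2]
  }
  p2 <- at(-1, 0); p3 <- at(-1, 1); p4 <- at(0, 1); p5 <- at(1, 1)
  p6 <- at(1, 0); p7 <- at(1, -1); p8 <- at(0, -1); p9 <- at(-1, -1)
  (!p2 && (p3 || p4)) + (!p4 && (p5 || p6)) +
    (!p6 && (p7 || p8)) + (!p8 && (p9 || p2))
}

# BFS check that all `cells` (linear indices) lie in one 8-connected
# component of `m`; early exit once every target is reached.
cells_connected <- function(m, cells) {
  if (length(cells) <= 1L) return(TRUE)
  nr <- nrow(m); nc <- ncol(m)
  target <- rep(FALSE, length(cells))
  seen <- new.env(hash = TRUE)
  stack <- cells[1L]
  while (length(stack)) {
    q <- stack[length(stack)]; stack <- stack[-length(stack)]
    key <- as.character(q)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    target[cells == q] <- TRUE
    if (all(target)) return(TRUE)
    r <- (q - 1L) %% nr + 1L; c <- (q - 1L) %/% nr + 1L
    for (k in seq_len(nrow(NEIGH8))) {
      r2 <- r + NEIGH8[k, 1L]; c2 <- c + NEIGH8[k, 2L]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        q2 <- (c2 - 1L) * nr + r2
        if (m[q2] && is.null(seen[[as.character(q2)]]))
          stack <- c(stack, q2)
      }
    }
  }
  all(target)
}

# The parallel thinning passes can occasionally leave a fully set 2x2
# square (typically the core of a multi-way junction); remove square
# pixels one at a time, only when deletion provably preserves
# connectivity — by the local connectivity number when it is decisive,
# otherwise by an explicit global check that the deleted pixel's
# neighbors stay mutually connected.
clear_square_blocks <- function(m) {
  nr <- nrow(m)
  guard <- 0L
  repeat {
    blk <- m & shift_mat(m, 0, -1) & shift_mat(m, -1, 0) &
      shift_mat(m, -1, -1)
    if (!any(blk) || guard > 1024L) return(m)
    guard <- guard + 1L
    a <- which(blk)[1L]
    r <- (a - 1L) %% nr + 1L; c <- (a - 1L) %/% nr + 1L
    cand <- list(c(r, c), c(r, c + 1L), c(r + 1L, c), c(r + 1L, c + 1L))
    changed <- FALSE
    for (p in cand) {
      if (!m[p[1], p[2]]) next
      if (gh_connectivity(m, p[1], p[2]) == 1) {
        m[p[1], p[2]] <- FALSE; changed <- TRUE; break
      }
    }
    if (!changed) for (p in cand) {
      if (!m[p[1], p[2]]) next
      lin <- (p[2] - 1L) * nr + p[1]
      m2 <- m; m2[lin] <- FALSE
      nb <- NEIGH8
      nbr <- p[1] + nb[, 1L]; nbc <- p[2] + nb[, 2L]
      ok <- nbr >= 1 & nbr <= nr & nbc >= 1 & nbc <= ncol(m)
      cells <- (nbc[ok] - 1L) * nr + nbr[ok]
      cells <- cells[m2[cells]]
      if (cells_connected(m2, cells)) {
        m <- m2; changed <- TRUE; break
      }
    }
    if (!changed) return(m)  # genuinely irreducible; leave as is
  }
}
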