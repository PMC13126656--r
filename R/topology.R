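# Branch-node clusters of a thin skeleton: pixels with >= 3 pruned-graph
# neighbors, merged by 8-connected labeling (thinning can emit multi-px
# junction clusters). Returns the label matrix and one representative
# (rounded centroid) per cluster.
branch_clusters <- function(skel, deg = skeleton_pixel_graph(skel)$deg) {
  bp <- skel & deg >= 3
  lab <- label8(bp)
  n <- max(lab)
  if (n == 0)
    return(list(label = lab,
                nodes = data.frame(row = numeric(0), col = numeric(0),
                                   n_px = integer(0))))
  idx <- which(bp, arr.ind = TRUE)
  l <- lab[bp]
  nodes <- data.frame(
    row = round(tapply(idx[, 1L], l, mean)),
    col = round(tapply(idx[, 2L], l, mean)),
    n_px = as.integer(tabulate(l, n)))
  list(label = lab, nodes = nodes)
}

#' Build the skeleton graph of a thin centerline mask
#'
#' Classifies skeleton pixels by their neighbor count (1 = endpoint,
#' 2 = slab, >= 3 = branch-node pixel; adjacent branch-node pixels are
#' merged into a single node), traces the slab chains between nodes into
#' segments, and labels connected components. A component is *isolated*
#' iff it contains no branch node. Centerline length sums one-pixel and
#' `sqrt(2)` diagonal steps, scaled by the pixel size.
#'
#' Neighbor counts are degrees on the shortcut-pruned pixel adjacency
#' graph: a diagonal link between two pixels that are already joined by
#' an orthogonal two-step path is a triangle shortcut and does not count.
#' Raw 8-neighbor counts would misclassify the chain pixels diagonally
#' adjacent to a junction as branch pixels and absorb them into the
#' junction cluster, biasing segment lengths (an "H" of two junctions
#' joined by a 40-step crossbar must yield a 40-step branching interval).
#'
#' @param skel a [skeleton_mask()] (thin: no 2x2 block fully set).
#' @return An object of class `skeleton_graph` with elements
#'   \describe{
#'     \item{nodes}{data.frame `id`, `row`, `col`, `kind` (`endpoint`,
#'       `branch_node`, `isolated_point`).}
#'     \item{segments}{data.frame `node_a`, `node_b` (`NA` for closed
#'       loops), `length_um`, `n_px`, `component`, `both_branch`,
#'       `any_branch`.}
#'     \item{paths}{list of integer vectors (linear pixel indices) per
#'       segment.}
#'     \item{components}{data.frame `component`, `is_isolated`,
#'       `length_um`.}
#'     \item{pixel_size_um}{physical pixel size.}
#'   }
#' @export
build_skeleton_graph <- function(skel) {
  if (!inherits(skel, "skeleton_mask"))
    stop("`skel` must be a skeleton_mask", call. = FALSE)
  m <- skel$mask
  px <- skel$pixel_size_um
  nr <- nrow(m)
  blk <- m & shift_mat(m, 0, -1) & shift_mat(m, -1, 0) & shift_mat(m, -1, -1)
  if (any(blk)) stop("skeleton not thin", call. = FALSE)
  pg <- skeleton_pixel_graph(m)
  deg <- pg$deg

  bc <- branch_clusters(m, deg = deg)
  n_branch <- nrow(bc$nodes)
  node_of <- matrix(0L, nr, ncol(m))
  node_of[bc$label > 0] <- bc$label[bc$label > 0]
  kinds <- rep("branch_node", n_branch)
  rows <- bc$nodes$row; cols <- bc$nodes$col

  ep <- which(m & deg == 1)
  iso <- which(m & deg == 0)
  extra <- c(ep, iso)
  if (length(extra)) {
    ids <- n_branch + seq_along(extra)
    node_of[extra] <- ids
    rows <- c(rows, (extra - 1L) %% nr + 1L)
    cols <- c(cols, (extra - 1L) %/% nr + 1L)
    kinds <- c(kinds, rep(c("endpoint", "isolated_point"),
                          c(length(ep), length(iso))))
  }
  nodes <- data.frame(id = seq_along(kinds), row = as.numeric(rows),
                      col = as.numeric(cols), kind = kinds)

  neighbors_of <- function(lin) pg$adj[[match(lin, pg$idx)]]
  step_len <- function(a, b) {
    if (abs((a - 1L) %% nr - (b - 1L) %% nr) +
        abs((a - 1L) %/% nr - (b - 1L) %/% nr) == 2L) sqrt(2) else 1
  }

  visited <- matrix(FALSE, nr, ncol(m))
  seg_a <- integer(0); seg_b <- integer(0); seg_len <- numeric(0)
  paths <- list()

  node_px <- which(node_of > 0L)
  for (np in node_px) {
    for (q in neighbors_of(np)) {
      if (node_of[q] > 0L || visited[q]) next
      path <- c(np, q); len <- step_len(np, q)
      prev <- np; cur <- q
      repeat {
        visited[cur] <- TRUE
        nxt <- setdiff(neighbors_of(cur), prev)
        if (length(nxt) == 0L) break  # dangling slab end (shouldn't occur)
        nxt <- nxt[1L]
        len <- len + step_len(cur, nxt)
        path <- c(path, nxt)
        if (node_of[nxt] > 0L) break
        prev <- cur; cur <- nxt
      }
      endpx <- path[length(path)]
      seg_a <- c(seg_a, node_of[np])
      seg_b <- c(seg_b, if (node_of[endpx] > 0L) node_of[endpx] else NA_integer_)
      seg_len <- c(seg_len, len)
      paths[[length(paths) + 1L]] <- path
    }
  }

  # direct node-node adjacencies across distinct nodes (no slab between)
  e <- pruned_edges8(m)
  na_ <- node_of[e$a]; nb_ <- node_of[e$b]
  direct <- which(na_ > 0L & nb_ > 0L & na_ != nb_)
  for (k in direct) {
    seg_a <- c(seg_a, na_[k]); seg_b <- c(seg_b, nb_[k])
    seg_len <- c(seg_len, if (e$diagonal[k]) sqrt(2) else 1)
    paths[[length(paths) + 1L]] <- c(e$a[k], e$b[k])
  }

  # closed loops: slab-only cycles never reached from a node
  left <- which(m & deg == 2 & !visited & node_of == 0L)
  for (start in left) {
    if (visited[start]) next
    nb <- neighbors_of(start)
    path <- start; len <- 0
    prev <- start; cur <- nb[1L]
    len <- len + step_len(start, cur)
    path <- c(path, cur)
    while (cur != start) {
      visited[cur] <- TRUE
      nxt <- setdiff(neighbors_of(cur), prev)[1L]
      len <- len + step_len(cur, nxt)
      if (nxt != start) path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    visited[start] <- TRUE
    seg_a <- c(seg_a, NA_integer_); seg_b <- c(seg_b, NA_integer_)
    seg_len <- c(seg_len, len)
    paths[[length(paths) + 1L]] <- path
  }

  comp <- label8(m)
  seg_comp <- vapply(paths, function(p) comp[p[1L]], integer(1))
  kind_of <- function(id) ifelse(is.na(id), NA_character_, nodes$kind[id])
  both_branch <- !is.na(seg_a) & !is.na(seg_b) &
    kind_of(seg_a) == "branch_node" & kind_of(seg_b) == "branch_node"
  any_branch <- (!is.na(seg_a) & kind_of(seg_a) == "branch_node") |
    (!is.na(seg_b) & kind_of(seg_b) == "branch_node")

  ncomp <- max(comp, 0)
  comp_iso <- logical(ncomp); comp_len <- numeric(ncomp)
  if (ncomp > 0) {
    branch_comp <- unique(comp[m & deg >= 3L])
    for (ci in seq_len(ncomp)) {
      cm <- comp == ci
      comp_iso[ci] <- !(ci %in% branch_comp)
      comp_len[ci] <- centerline_length_px(cm) * px
    }
  }

  structure(list(
    nodes = nodes,
    segments = data.frame(node_a = seg_a, node_b = seg_b,
                          length_um = seg_len * px,
                          n_px = vapply(paths, length, integer(1)),
                          component = seg_comp,
                          both_branch = both_branch,
                          any_branch = any_branch),
    paths = paths,
    components = data.frame(component = seq_len(ncomp),
                            is_isolated = comp_iso,
                            length_um = comp_len),
    pixel_size_um = px), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d nodes (%d branch, %d endpoint), %d segments, %d components (%d isolated)\n",
    nrow(x$nodes), sum(x$nodes$kind == "branch_node"),
    sum(x$nodes$kind == "endpoint"), nrow(x$segments),
    nrow(x$components), sum(x$components$is_isolated)))
  invisible(x)
}

#' ROI area from image dimensions
#'
#' @param dims integer vector `c(rows, cols)` of the mask/image.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return Area in um^2 (`rows * cols * pixel_size_um^2`).
#' @examples
#' roi_area(c(1000, 1000), 3) / 1e6  # mm^2
#' @export
roi_area <- function(dims, pixel_size_um) {
  check_that(is.numeric(dims) && length(dims) == 2L && all(dims >= 1),
             "dims", "must be two positive integers")
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  prod(dims) * pixel_size_um^2
}

#' Area-normalized topology feature set
#'
#' Counts and lengths from the skeleton graph, normalized by ROI area so
#' images of different sizes are comparable. A *branch* is a segment with
#' at least one branch-node end (bifurcation-bifurcation or
#' bifurcation-terminal); the *branching interval* is the mean centerline
#' length of segments joining two branch nodes; the *normalized isolated
#' branch length* is the total centerline length of isolated components
#' (no branch node) divided by ROI area — a fragmentation surrogate.
#'
#' @param graph a [build_skeleton_graph()] result.
#' @param roi_area_um2 ROI area in um^2.
#' @return One-row data.frame: `n_branches_per_mm2`,
#'   `total_branch_length_mm_per_mm2`, `normalized_isolated_branch_length`
#'   (um per um^2), `branching_interval_um` (`NA` with a warning when no
#'   branch-to-branch segment exists), `n_branch_nodes_per_mm2`, plus the
#'   inventory extras `n_endpoints_per_mm2`, `n_segments_per_mm2`,
#'   `total_skeleton_length_mm_per_mm2`, `mean_segment_length_um`,
#'   `n_isolated_components_per_mm2`.
#' @export
topology_features <- function(graph, roi_area_um2) {
  if (!inherits(graph, "skeleton_graph"))
    stop("`graph` must be a skeleton_graph", call. = FALSE)
  check_scalar_num(roi_area_um2, "roi_area_um2", lower = 1e-12)
  mm2 <- roi_area_um2 / 1e6
  seg <- graph$segments
  iso_len <- sum(graph$components$length_um[graph$components$is_isolated])
  bb <- seg$length_um[seg$both_branch %in% TRUE]
  if (length(bb) == 0L) {
    warning("no branch-to-branch segment: branching interval is missing")
    bi <- NA_real_
  } else bi <- mean(bb)
  data.frame(
    n_branches_per_mm2 = sum(seg$any_branch %in% TRUE) / mm2,
    total_branch_length_mm_per_mm2 =
      sum(seg$length_um[seg$any_branch %in% TRUE]) / 1e3 / mm2,
    normalized_isolated_branch_length = iso_len / roi_area_um2,
    branching_interval_um = bi,
    n_branch_nodes_per_mm2 = sum(graph$nodes$kind == "branch_node") / mm2,
    n_endpoints_per_mm2 = sum(graph$nodes$kind == "endpoint") / mm2,
    n_segments_per_mm2 = nrow(seg) / mm2,
    total_skeleton_length_mm_per_mm2 =
      sum(graph$components$length_um) / 1e3 / mm2,
    mean_segment_length_um = if (nrow(seg)) mean(seg$length_um) else NA_real_,
    n_isolated_components_per_mm2 = sum(graph$components$is_isolated) / mm2)
}
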