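#' Specification for a synthetic vascular phantom
#'
#' Describes a tree-structured vascular network to be grown by stochastic
#' directed walks and rendered as a grayscale MIP-like image. The phantom
#' is a statistical stand-in for OR-PAM endometrial vasculature: it
#' controls the diameter distribution, branching density, and the fraction
#' of centerline length in isolated fragments, but does not simulate
#' acoustic or optical physics.
#'
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param image_size_px integer vector `c(rows, cols)`.
#' @param pixel_size_um physical pixel size (um); 3 um matches the scanner
#'   step the package targets.
#' @param n_trees number of vessel trees.
#' @param mean_diameter_um,sd_diameter_um mean and SD of the per-segment
#'   diameter distribution (truncated normal, lower bound
#'   `2 * pixel_size_um` so vessels stay resolvable).
#' @param branch_prob_per_step probability of spawning a side branch per
#'   one-pixel step of growth, in `[0, 1]`.
#' @param mean_branch_length_um mean length of a vessel segment (walker
#'   lifetime is exponential with this mean).
#' @param isolated_fragment_fraction target fraction of total centerline
#'   length contributed by short isolated fragments, in `[0, 1)`.
#' @param background_noise_sd SD of additive Gaussian background noise on
#'   the rendered image (vessel intensity is 1).
#' @return An object of class `vessel_network_spec`.
#' @seealso [generate_vessel_phantom()]
#' @export
vessel_network_spec <- function(seed = 1L,
                                image_size_px = c(256L, 256L),
                                pixel_size_um = 3,
                                n_trees = 3L,
                                mean_diameter_um = 30,
                                sd_diameter_um = 5,
                                branch_prob_per_step = 0.03,
                                mean_branch_length_um = 200,
                                isolated_fragment_fraction = 0.1,
                                background_noise_sd = 0.01) {
  check_scalar_num(seed, "seed")
  check_that(is.numeric(image_size_px) && length(image_size_px) == 2L &&
               all(image_size_px >= 16), "image_size_px",
             "must be two integers >= 16")
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  check_scalar_num(n_trees, "n_trees", lower = 1)
  check_scalar_num(mean_diameter_um, "mean_diameter_um", lower = 1e-9)
  check_that(mean_diameter_um >= 2 * pixel_size_um, "mean_diameter_um",
             "must be >= 2 * pixel_size_um (vessels must be resolvable)")
  check_scalar_num(sd_diameter_um, "sd_diameter_um", lower = 0)
  check_scalar_num(branch_prob_per_step, "branch_prob_per_step",
                   lower = 0, upper = 1)
  check_scalar_num(mean_branch_length_um, "mean_branch_length_um",
                   lower = 1e-9)
  check_scalar_num(isolated_fragment_fraction, "isolated_fragment_fraction",
                   lower = 0, upper = 1)
  check_that(isolated_fragment_fraction < 1, "isolated_fragment_fraction",
             "must be < 1")
  check_scalar_num(background_noise_sd, "background_noise_sd", lower = 0)
  structure(list(seed = as.integer(seed),
                 image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_trees = as.integer(n_trees),
                 mean_diameter_um = mean_diameter_um,
                 sd_diameter_um = sd_diameter_um,
                 branch_prob_per_step = branch_prob_per_step,
                 mean_branch_length_um = mean_branch_length_um,
                 isolated_fragment_fraction = isolated_fragment_fraction,
                 background_noise_sd = background_noise_sd),
            class = "vessel_network_spec")
}

# Truncated-normal diameter draw (rejection; lower bound keeps vessels
# resolvable at the pixel grid).
draw_diameter <- function(spec) {
  lo <- 2 * spec$pixel_size_um
  if (spec$sd_diameter_um == 0) return(max(spec$mean_diameter_um, lo))
  repeat {
    d <- rnorm(1, spec$mean_diameter_um, spec$sd_diameter_um)
    if (d >= lo) return(d)
  }
}

# Walk a single vessel segment; returns its deduplicated pixel chain and
# any branch events (position + inherited state for the spawned walker).
# The walk stops at the frame edge and on two collision rules: a hard
# rule against the rendered vasculature (`tube`, after `hard_grace`
# steps that let a child's start pixel round off its parent's wall) so
# vessels never run invisibly through each other, and a soft spacing
# rule against the dilated exclusion zone (`excl`, after `grace` steps
# that let a child clear its parent's zone) so non-branching vessels
# keep about one vessel diameter of clearance and do not merge into
# wide slabs.
walk_segment <- function(start, angle, length_px, spec, allow_branch = TRUE,
                         tube = NULL, excl = NULL, grace = 0L,
                         hard_grace = 2L, angle_sd = 0.15) {
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  pos <- start
  px <- integer(ceiling(length_px) + 1L)
  npx <- 0L
  spawns <- list()
  steps <- max(1L, ceiling(length_px))
  for (s in seq_len(steps)) {
    r <- round(pos[1]); c <- round(pos[2])
    if (r < 1 || r > nr || c < 1 || c > nc) break
    lin <- (c - 1L) * nr + r
    if (!is.null(tube) && s > hard_grace && tube[lin]) break
    if (!is.null(excl) && s > grace && excl[lin]) break
    if (npx == 0L || px[npx] != lin) { npx <- npx + 1L; px[npx] <- lin }
    if (allow_branch && spec$branch_prob_per_step > 0 &&
        runif(1) < spec$branch_prob_per_step) {
      side <- sample(c(-1, 1), 1)
      spawns[[length(spawns) + 1L]] <-
        list(pos = pos, angle = angle + side * runif(1, 0.5, 1.1),
             at = c(r, c))
    }
    angle <- angle + rnorm(1, 0, angle_sd)
    pos <- pos + c(sin(angle), cos(angle))
  }
  list(pixels = px[seq_len(npx)], spawns = spawns)
}

# Precompute disk stamp offsets (linear-index deltas) for a tube of the
# given continuous radius: pixel-center sampling of the disk (pixels
# whose centers lie within `radius_px` of the centerline), so the exact
# Euclidean distance transform at a centerline pixel reads back the
# smallest lattice distance exceeding the radius — i.e. ~radius with no
# systematic offset.
disk_offsets <- function(radius_px, nr) {
  # quarter-pixel shrink: the lattice distance that the distance
  # transform reads back overshoots a continuous radius by ~0.25 px on
  # average, so sampling the disk at (r - 0.25) centers the readback on r
  q <- max(radius_px - 0.25, 0.6)
  w <- floor(q)
  dd <- expand.grid(dr = -w:w, dc = -w:w)
  dd <- dd[dd$dr^2 + dd$dc^2 <= q^2, , drop = FALSE]
  list(dr = dd$dr, dc = dd$dc)
}

stamp_tube <- function(tube, pixels, radius_px) {
  nr <- nrow(tube); nc <- ncol(tube)
  off <- disk_offsets(radius_px, nr)
  r0 <- (pixels - 1L) %% nr + 1L
  c0 <- (pixels - 1L) %/% nr + 1L
  for (k in seq_along(off$dr)) {
    r <- r0 + off$dr[k]; c <- c0 + off$dc[k]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    if (any(ok)) tube[cbind(r[ok], c[ok])] <- TRUE
  }
  tube
}

#' Generate a synthetic vascular phantom with ground truth
#'
#' Grows `n_trees` vessel trees by stochastic directed walks (branching
#' with probability `branch_prob_per_step` per one-pixel step, per-segment
#' diameters from a truncated normal), adds short isolated fragments until
#' their share of total centerline length reaches
#' `isolated_fragment_fraction`, and renders the network by stamping disks
#' of the local radius along each centerline (so the distance-transform
#' diameter map has an exact target). Gaussian background noise is added
#' on top of unit-intensity vessels.
#'
#' The returned ground truth records the *realized* statistics of the
#' generated network (computed from the rasterized centerlines and the
#' drawn diameters), not the nominal spec parameters, so recovery tests are
#' free of sampling error.
#'
#' @param spec a [vessel_network_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{image}{[mip_image()] — rendered grayscale phantom.}
#'     \item{truth}{list with `true_mean_diameter_um`,
#'       `true_sd_diameter_um`, `true_n_branch_nodes`,
#'       `true_total_centerline_length_um`, `true_isolated_length_um`,
#'       `centerline_mask` (logical matrix), `tube_mask` (logical matrix,
#'       noise-free rendered vessels), and `diameters` (data.frame of
#'       per-centerline-pixel diameters in um).}
#'   }
#' @examples
#' ph <- generate_vessel_phantom(vessel_network_spec(seed = 7))
#' ph$truth$true_mean_diameter_um
#' @export
generate_vessel_phantom <- function(spec) {
  if (!inherits(spec, "vessel_network_spec"))
    stop("`spec` must be a vessel_network_spec", call. = FALSE)
  with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    px_um <- spec$pixel_size_um
    mean_len_px <- spec$mean_branch_length_um / px_um

    walkers_px <- list()     # pixel chains per walker
    walkers_d <- numeric(0)  # diameter (um) per walker
    branch_nodes <- matrix(numeric(0), ncol = 2)
    tube <- matrix(FALSE, nr, nc)     # rendered vessels, grown incrementally
    excl <- matrix(FALSE, nr, nc)     # tube dilated by ~one radius: keeps
                                      # non-branching vessels from merging
                                      # into wide slabs side by side
    cl_mask <- matrix(FALSE, nr, nc)  # rasterized centerlines
    mean_r_px <- spec$mean_diameter_um / 2 / px_um

    # Tree size is capped (scaled to image area) so that default phantoms
    # keep a realistic vessel area fraction instead of saturating the
    # frame when the branching process is supercritical.
    max_walkers <- max(5L, round(36 * nr * nc / 65536 / spec$n_trees))

    # Grow one tree against the vasculature rendered so far (`tube0`);
    # rendering happens during growth so walkers can stop where they
    # meet existing vessels instead of running invisibly through them.
    grow_tree <- function(tube0, excl0) {
      tube_t <- tube0
      excl_t <- excl0
      start <- c(runif(1, 0.2 * nr, 0.8 * nr), runif(1, 0.2 * nc, 0.8 * nc))
      queue <- list(list(pos = start, angle = runif(1, 0, 2 * pi),
                         len = rexp(1, 1 / mean_len_px) + 0.5 * mean_len_px,
                         d = draw_diameter(spec), at = NULL))
      chains <- list(); dias <- numeric(0); nodes <- matrix(numeric(0), ncol = 2)
      nw <- 0L
      while (length(queue) && nw < max_walkers) {
        w <- queue[[1]]; queue <- queue[-1]; nw <- nw + 1L
        r_px <- w$d / 2 / px_um
        # children get a few collision-free steps to clear their parent's
        # exclusion zone before the spacing rule applies
        grace <- if (is.null(w$at)) 0L
                 else ceiling(r_px + mean_r_px) + 2L
        # thicker vessels are straighter at the pixel scale: their
        # curvature radius should exceed their own radius, so heading
        # noise shrinks with caliber (wiggles of sub-diameter wavelength
        # would just render as boundary bumps)
        seg <- walk_segment(w$pos, w$angle, w$len, spec,
                            tube = tube_t, excl = excl_t, grace = grace,
                            hard_grace = if (is.null(w$at)) 0L else 2L,
                            angle_sd = min(0.15, 0.45 / r_px))
        # a vessel segment shorter than its own diameter is a
        # sub-resolvable stub: it would render as a blob with no
        # observable centerline, so it is not grown
        if (length(seg$pixels) < max(4L, ceiling(w$d / px_um))) next
        chains[[length(chains) + 1L]] <- seg$pixels
        dias <- c(dias, w$d)
        # a spawn position becomes a branch node only once its child
        # walker is actually grown
        if (!is.null(w$at)) nodes <- rbind(nodes, w$at)
        tube_t <- stamp_tube(tube_t, seg$pixels, r_px)
        excl_t <- stamp_tube(excl_t, seg$pixels, r_px + mean_r_px)
        for (sp in seg$spawns) {
          # children emerge at the parent's wall: their visible centerline
          # starts one parent-radius away from the parent centerline, so
          # ground-truth length matches what thinning can observe
          child_start <- sp$pos + r_px * c(sin(sp$angle), cos(sp$angle))
          queue[[length(queue) + 1L]] <-
            list(pos = child_start, angle = sp$angle,
                 len = rexp(1, 1 / mean_len_px),
                 d = draw_diameter(spec), at = sp$at)
        }
      }
      list(chains = chains, dias = dias, nodes = nodes, tube = tube_t,
           excl = excl_t)
    }

    for (t in seq_len(spec$n_trees)) {
      tree <- grow_tree(tube, excl)
      if (spec$branch_prob_per_step > 0) {
        # a tree should be a genuine branched network, not a midget that
        # left the frame: retry until it has at least two branch nodes
        # and a couple of segment lengths of total extent
        ok <- function(tr)
          nrow(tr$nodes) >= 2L &&
            sum(vapply(tr$chains, length, integer(1))) >= 2 * mean_len_px
        tries <- 0L
        while (!ok(tree) && tries < 20L) {
          tree <- grow_tree(tube, excl); tries <- tries + 1L
        }
      }
      tube <- tree$tube
      excl <- tree$excl
      walkers_px <- c(walkers_px, tree$chains)
      walkers_d <- c(walkers_d, tree$dias)
      branch_nodes <- rbind(branch_nodes, tree$nodes)
    }
    for (ch in walkers_px) cl_mask[ch] <- TRUE
    tree_len_px <- centerline_length_px(cl_mask)

    # isolated fragments: short unbranched walks placed clear of the network
    frag_px <- list(); frag_d <- numeric(0)
    f <- spec$isolated_fragment_fraction
    if (f > 0) {
      target <- f / (1 - f) * tree_len_px
      iso_len <- 0; tries <- 0L
      while (iso_len < target && tries < 300L) {
        tries <- tries + 1L
        d <- draw_diameter(spec)
        r_px <- d / 2 / px_um
        # fragments stay elongated (length >= 1.5 diameters) so their
        # rendered capsules thin back to a measurable centerline
        len <- max(runif(1, 0.25, 0.5) * mean_len_px, 3 * r_px)
        start <- c(runif(1, r_px + 2, nr - r_px - 2),
                   runif(1, r_px + 2, nc - r_px - 2))
        seg <- walk_segment(start, runif(1, 0, 2 * pi), len, spec,
                            allow_branch = FALSE,
                            angle_sd = min(0.15, 0.45 / r_px))
        if (length(seg$pixels) < 2L) next
        # reject placements whose (margin-dilated) footprint touches anything
        probe <- stamp_tube(matrix(FALSE, nr, nc), seg$pixels, r_px + 2)
        if (any(probe & tube)) next
        frag <- matrix(FALSE, nr, nc); frag[seg$pixels] <- TRUE
        iso_len <- iso_len + centerline_length_px(frag)
        frag_px[[length(frag_px) + 1L]] <- seg$pixels
        frag_d <- c(frag_d, d)
        tube <- stamp_tube(tube, seg$pixels, r_px)
        cl_mask[seg$pixels] <- TRUE
      }
      iso_len_px <- iso_len
    } else iso_len_px <- 0

    # realized per-centerline-pixel diameter records
    all_chains <- c(walkers_px, frag_px)
    all_d <- c(walkers_d, frag_d)
    rows <- unlist(lapply(all_chains, function(p) (p - 1L) %% nr + 1L))
    cols <- unlist(lapply(all_chains, function(p) (p - 1L) %/% nr + 1L))
    dvec <- rep(all_d, times = vapply(all_chains, length, integer(1)))

    img <- matrix(0, nr, nc)
    img[tube] <- 1
    if (spec$background_noise_sd > 0)
      img <- pmax(img + matrix(rnorm(nr * nc, 0, spec$background_noise_sd),
                               nr, nc), 0)

    truth <- list(
      true_mean_diameter_um = mean(dvec),
      true_sd_diameter_um = sd(dvec),
      true_n_branch_nodes = nrow(branch_nodes),
      true_total_centerline_length_um = centerline_length_px(cl_mask) * px_um,
      true_isolated_length_um = iso_len_px * px_um,
      centerline_mask = cl_mask,
      tube_mask = tube,
      diameters = data.frame(row = rows, col = cols, diameter_um = dvec))
    check_that(truth$true_isolated_length_um <=
                 truth$true_total_centerline_length_um + 1e-9,
               "isolated_fragment_fraction",
               "realized isolated length exceeded total length")
    list(image = mip_image(img, pixel_size_um = px_um), truth = truth)
  })
}
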