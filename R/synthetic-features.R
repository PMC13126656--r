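#' Canonical selected-feature names
#'
#' The five features the separability framework is built on: spectral mean
#' frequency, mean and SD of vessel diameter, area-normalized isolated
#' branch length, and branching interval.
#' @return Character vector of length 5.
#' @export
selected_feature_names <- function() {
  c("mean_frequency_mhz", "mean_diameter_um", "sd_diameter_um",
    "normalized_isolated_branch_length", "branching_interval_um")
}

#' Default two-class effect specification for synthetic feature tables
#'
#' Class means and SDs for the five selected features. Effect directions
#' follow the biology of tumor-associated vascular remodeling: malignant /
#' premalignant (ec_ein) tissue has a *lower* spectral mean frequency
#' (larger effective absorbers) and *higher* vessel diameter mean and SD,
#' isolated branch length, and branching interval (enlarged, heterogeneous,
#' fragmented networks).
#'
#' @param separation effect size in within-class SD units applied along
#'   those directions; `0` gives a null (no class difference) table. The
#'   default of 2 SD produces clearly separated but overlapping classes.
#' @return data.frame with columns `feature`, `mean_normal_benign`,
#'   `mean_ec_ein`, `sd`.
#' @export
default_effect_spec <- function(separation = 2) {
  check_scalar_num(separation, "separation")
  base <- data.frame(
    feature = selected_feature_names(),
    mean_normal_benign = c(38, 28, 9, 0.05, 65),
    sd = c(2.5, 7, 3.5, 0.035, 15),
    direction = c(-1, 1, 1, 1, 1))
  base$mean_ec_ein <- base$mean_normal_benign +
    base$direction * separation * base$sd
  base[, c("feature", "mean_normal_benign", "mean_ec_ein", "sd")]
}

#' Generate a labeled two-class synthetic feature table
#'
#' Draws per-class multivariate normal feature vectors (exchangeable
#' correlation `correlation` between features on the correlation scale),
#' truncated at zero by rejection sampling since all features are
#' physically nonnegative, and labels rows `normal_benign` / `ec_ein`.
#'
#' @param n_per_class named integer vector
#'   `c(normal_benign = ..., ec_ein = ...)`; the study-sized default is 10
#'   normal/benign and 30 EC/EIN images.
#' @param effect_spec data.frame as returned by [default_effect_spec()]:
#'   columns `feature`, `mean_normal_benign`, `mean_ec_ein`, `sd` (all
#'   `sd` > 0).
#' @param correlation exchangeable between-feature correlation in
#'   `[0, 0.9]`.
#' @param seed integer RNG seed; seeded calls are reproducible.
#' @return data.frame with one column per feature plus a `label` factor.
#' @examples
#' tab <- generate_feature_table(seed = 1)
#' table(tab$label)
#' @export
generate_feature_table <- function(n_per_class = c(normal_benign = 10,
                                                   ec_ein = 30),
                                   effect_spec = default_effect_spec(),
                                   correlation = 0.2,
                                   seed = 1L) {
  check_scalar_num(seed, "seed")
  check_that(is.numeric(n_per_class) && length(n_per_class) == 2L &&
               all(n_per_class >= 1) &&
               all(c("normal_benign", "ec_ein") %in% names(n_per_class)),
             "n_per_class",
             "must be c(normal_benign = n1, ec_ein = n2), both >= 1")
  check_that(is.data.frame(effect_spec) &&
               all(c("feature", "mean_normal_benign", "mean_ec_ein", "sd")
                   %in% names(effect_spec)),
             "effect_spec",
             "must have feature, mean_normal_benign, mean_ec_ein, sd")
  check_that(all(effect_spec$sd > 0), "effect_spec",
             "all sd values must be positive")
  check_scalar_num(correlation, "correlation", lower = 0, upper = 0.9)

  p <- nrow(effect_spec)
  R <- matrix(correlation, p, p); diag(R) <- 1
  S <- diag(effect_spec$sd) %*% R %*% diag(effect_spec$sd)

  draw_class <- function(n, mu) {
    out <- matrix(NA_real_, n, p)
    filled <- 0L
    while (filled < n) {
      cand <- MASS::mvrnorm(n - filled, mu = mu, Sigma = S)
      cand <- matrix(cand, ncol = p)
      ok <- apply(cand >= 0, 1L, all)
      k <- sum(ok)
      if (k) {
        out[filled + seq_len(k), ] <- cand[ok, , drop = FALSE]
        filled <- filled + k
      }
    }
    out
  }

  with_seed(seed, {
    a <- draw_class(n_per_class[["normal_benign"]],
                    effect_spec$mean_normal_benign)
    b <- draw_class(n_per_class[["ec_ein"]], effect_spec$mean_ec_ein)
    tab <- as.data.frame(rbind(a, b))
    names(tab) <- effect_spec$feature
    tab$label <- factor(rep(c("normal_benign", "ec_ein"),
                            c(nrow(a), nrow(b))),
                        levels = c("normal_benign", "ec_ein"))
    rownames(tab) <- sprintf("img%02d", seq_len(nrow(tab)))
    tab
  })
}
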