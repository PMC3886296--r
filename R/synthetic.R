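#' Plant a latent appropriateness truth over a scenario space
#'
#' Assigns each indication of the space a planted category drawn from
#' `mix` and a latent appropriateness score on the 9-point scale:
#' category centres sit at the band midpoints (appropriate 8, uncertain
#' 5, inappropriate 2).  `split` indications model a divided panel: they
#' carry the inappropriate centre 2 plus an opposed centre 8, so that a
#' bimodal rating mixture triggers the disagreement rule and the intended
#' classified category is uncertain.
#'
#' @param space A [ruam_space].
#' @param mix Named proportions over
#'   `c("appropriate", "uncertain", "inappropriate", "split")`, summing
#'   to 1.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A `ruam_truth` data frame with one row per indication:
#'   `population`, `scenario_id`, `treatment`, `planted` (the drawn
#'   label), `intended` (the category a perfect classifier should
#'   return: `split` maps to `uncertain`), `theta`, `theta_alt` (`NA`
#'   except for split indications); attribute `space`.
#' @export
plant_truth <- function(space,
                        mix = c(appropriate = 0.5, uncertain = 0.3,
                                inappropriate = 0.15, split = 0.05),
                        seed = NULL) {
  stopifnot(inherits(space, "ruam_space"))
  labs <- c("appropriate", "uncertain", "inappropriate", "split")
  if (is.null(names(mix))) names(mix) <- labs[seq_along(mix)]
  if (!all(names(mix) %in% labs)) {
    stop("`mix` names must be among: ", paste(labs, collapse = ", "),
         call. = FALSE)
  }
  mix <- mix[labs]
  mix[is.na(mix)] <- 0
  names(mix) <- labs
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("`mix` proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  ind <- enumerate_indications(space)
  if (!is.null(seed)) set.seed(seed)
  planted <- sample(labs, nrow(ind), replace = TRUE, prob = mix)
  centres <- c(appropriate = 8, uncertain = 5, inappropriate = 2, split = 2)
  ind$planted <- planted
  ind$intended <- ifelse(planted == "split", "uncertain", planted)
  ind$theta <- unname(centres[planted])
  ind$theta_alt <- ifelse(planted == "split", 8, NA_real_)
  structure(ind, space = space, class = c("ruam_truth", "data.frame"))
}

#' Generate a complete synthetic panel rating round
#'
#' Emulates P panellists independently rating every indication: each
#' rating is the latent score plus rater bias plus Gaussian noise,
#' rounded and clamped to the integer 1-9 scale.  For split indications a
#' fixed number `round(split_fraction * P)` of panellists (chosen at
#' random per indication) rate from the opposed latent score instead,
#' producing a bimodal vector.  A single seeded RNG stream makes the
#' table reproducible: identical (truth, parameters, seed) give an
#' identical table.
#'
#' @param truth A `ruam_truth` object from [plant_truth()].
#' @param panel_size Number of raters P (default 16).
#' @param sigma Rater noise standard deviation on the 9-point scale
#'   (default 0.5).
#' @param bias Per-rater additive bias, a scalar or length-P vector
#'   (default 0, keeping the noise-free limit exact).
#' @param split_fraction Fraction of raters drawn from the opposed score
#'   for split indications (default 5/16, the smallest fraction that
#'   triggers disagreement on a 16-member panel).
#' @param seed Optional integer seed.
#' @param round Round tag for the generated records (default 2).
#' @return A complete `ruam_ratings` table with panel
#'   `R01 ... R<P>`.
#' @examples
#' sp <- default_space()
#' tr <- plant_truth(sp, seed = 1)
#' tab <- generate_ratings(tr, panel_size = 16, sigma = 0, seed = 1)
#' @export
generate_ratings <- function(truth, panel_size = 16L, sigma = 0.5,
                             bias = 0, split_fraction = 5 / 16,
                             seed = NULL, round = 2L) {
  stopifnot(inherits(truth, "ruam_truth"))
  P <- as.integer(panel_size)
  if (P < 1L) stop("`panel_size` must be >= 1", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (split_fraction < 0 || split_fraction > 1) {
    stop("`split_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length(bias) == 1L) bias <- rep(bias, P)
  if (length(bias) != P) {
    stop("`bias` must be a scalar or length-P vector", call. = FALSE)
  }
  n <- nrow(truth)
  panel <- sprintf("R%02d", seq_len(P))
  if (!is.null(seed)) set.seed(seed)

  theta <- matrix(rep(truth$theta, each = P), nrow = P)  # P x n
  k_split <- as.integer(round(split_fraction * P))
  split_idx <- which(truth$planted == "split")
  if (k_split > 0L) {
    for (i in split_idx) {
      theta[sample.int(P, k_split), i] <- truth$theta_alt[i]
    }
  }
  eps <- if (sigma > 0) matrix(stats::rnorm(P * n, sd = sigma), nrow = P)
         else matrix(0, nrow = P, ncol = n)
  ratings <- pmin(9L, pmax(1L, as.integer(round(theta + bias + eps))))

  records <- data.frame(
    rater_id = rep(panel, times = n),
    scenario_id = rep(truth$scenario_id, each = P),
    treatment = rep(truth$treatment, each = P),
    rating = as.integer(ratings),  # column-major: raters fastest
    round = as.integer(round),
    stringsAsFactors = FALSE)
  ruam_ratings(records, attr(truth, "space"), panel = panel)
}

#' Simulate a full synthetic round
#'
#' Convenience wrapper: [plant_truth()] then [generate_ratings()], both
#' driven by one seed.
#'
#' @inheritParams plant_truth
#' @inheritParams generate_ratings
#' @return A list with elements `truth` and `ratings`.
#' @export
simulate_round <- function(space,
                           mix = c(appropriate = 0.5, uncertain = 0.3,
                                   inappropriate = 0.15, split = 0.05),
                           panel_size = 16L, sigma = 0.5, bias = 0,
                           split_fraction = 5 / 16, seed = NULL) {
  truth <- plant_truth(space, mix = mix, seed = seed)
  ratings <- generate_ratings(truth, panel_size = panel_size, sigma = sigma,
                              bias = bias, split_fraction = split_fraction,
                              seed = NULL)  # continue the same RNG stream
  list(truth = truth, ratings = ratings)
}

#' Compare classified categories with the planted truth
#'
#' @param truth A `ruam_truth` object.
#' @param results The `ruam_results` from classifying the generated
#'   round; must cover the same indications.
#' @return A `ruam_recovery` list: `confusion` (planted label x
#'   classified category contingency table), `recovery` (percentage of
#'   indications whose classified category equals the intended label) and
#'   `recovery_nonsplit` (the same, restricted to non-split plants).
#' @export
recovery_report <- function(truth, results) {
  stopifnot(inherits(truth, "ruam_truth"), inherits(results, "ruam_results"))
  tkey <- paste(truth$scenario_id, truth$treatment, sep = "\r")
  rkey <- paste(results$scenario_id, results$treatment, sep = "\r")
  if (!setequal(tkey, rkey) || length(tkey) != length(rkey)) {
    stop("truth and results cover different indication sets", call. = FALSE)
  }
  cls <- results$category[match(tkey, rkey)]
  confusion <- table(
    planted = factor(truth$planted,
                     levels = c("appropriate", "uncertain",
                                "inappropriate", "split")),
    classified = factor(cls, levels = c("appropriate", "uncertain",
                                        "inappropriate")))
  hit <- cls == truth$intended
  nonsplit <- truth$planted != "split"
  structure(list(confusion = confusion,
                 recovery = 100 * mean(hit),
                 recovery_nonsplit =
                   if (any(nonsplit)) 100 * mean(hit[nonsplit]) else NA_real_),
            class = "ruam_recovery")
}

#' @export
print.ruam_recovery <- function(x, ...) {
  cat(sprintf("Planted-label recovery: %.1f%% (non-split: %.1f%%)\n",
              x$recovery, x$recovery_nonsplit))
  print(x$confusion)
  invisible(x)
}
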