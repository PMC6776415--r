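#' Specify a synthetic subject cohort
#'
#' Defines a two-group cohort of weighted 90-node structural networks built
#' from one small-world template. The patient group's pathology model removes
#' weak connections and attenuates the remaining ones — fewer and weaker
#' low-weight edges with the strong backbone largely intact, the disruption
#' pattern structural-network studies of chronic disease report.
#'
#' @param n_controls,n_patients Subjects per group.
#' @param n_nodes Network size (default 90 regions, >= 3).
#' @param base_density Target edge density of the template, in (0, 1].
#' @param rewire_prob Watts–Strogatz rewiring probability of the template.
#' @param weak_edge_deletion_prob Per-subject probability that each
#'   weak-quartile template edge is deleted in a patient network, in \[0, 1\].
#' @param weight_attenuation Multiplicative factor applied to all patient
#'   edge weights, in (0, 1].
#' @param subject_noise_sd Lognormal sigma of per-subject, per-edge weight
#'   noise (>= 0).
#' @param weight_sdlog Lognormal sigma of the template weight distribution.
#' @param distance_decay Scale (in ring-distance hops) of the exponential
#'   decay of template log-weights; heavier long-range edges are rarer and
#'   weaker, as in tractography-derived networks.
#' @param covariate_effects Optional named list of linear slopes on
#'   log-weights for `age` (per year) and `tiv` (per 1000 mm^3); off by
#'   default.
#' @param cognition Also simulate cognitive/disease-severity columns (with
#'   group shifts and patient-only measures).
#' @param missing_prob Probability that each cognitive/disease cell is
#'   missing.
#' @param seed Integer seed.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 25L, n_patients = 25L, n_nodes = 90L,
                        base_density = 0.15, rewire_prob = 0.1,
                        weak_edge_deletion_prob = 0,
                        weight_attenuation = 1,
                        subject_noise_sd = 0.25,
                        weight_sdlog = 0.5,
                        distance_decay = 15,
                        covariate_effects = NULL,
                        cognition = FALSE,
                        missing_prob = 0,
                        seed = 1L) {
  if (n_nodes < 3L) abort("`n_nodes` must be >= 3.")
  if (n_controls < 1L || n_patients < 1L) abort("both groups need subjects.")
  if (base_density <= 0 || base_density > 1) abort("`base_density` in (0, 1].")
  probs <- c(weak_edge_deletion_prob, rewire_prob, missing_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  if (weight_attenuation <= 0 || weight_attenuation > 1) {
    abort("`weight_attenuation` must lie in (0, 1].")
  }
  if (subject_noise_sd < 0) abort("`subject_noise_sd` must be >= 0.")
  structure(
    list(n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients),
         n_nodes = as.integer(n_nodes), base_density = base_density,
         rewire_prob = rewire_prob,
         weak_edge_deletion_prob = weak_edge_deletion_prob,
         weight_attenuation = weight_attenuation,
         subject_noise_sd = subject_noise_sd,
         weight_sdlog = weight_sdlog, distance_decay = distance_decay,
         covariate_effects = covariate_effects,
         cognition = cognition, missing_prob = missing_prob,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Watts-Strogatz backbone with distance-decaying lognormal weights
make_template_network <- function(spec) {
  n <- spec$n_nodes
  nei <- max(1L, round(spec$base_density * (n - 1) / 2))
  g <- igraph::sample_smallworld(1, n, nei, spec$rewire_prob,
                                 loops = FALSE, multiple = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  a <- (a > 0) * 1
  w <- matrix(0, n, n)
  pairs <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  ring_d <- pmin(abs(pairs[, 1] - pairs[, 2]),
                 n - abs(pairs[, 1] - pairs[, 2]))
  mu <- -ring_d / spec$distance_decay
  ws <- rlnorm(nrow(pairs), meanlog = mu, sdlog = spec$weight_sdlog)
  w[pairs] <- ws
  w[pairs[, c(2, 1), drop = FALSE]] <- ws
  w
}

#' Simulate a two-group cohort of connectomes
#'
#' Draws one small-world weighted template, then perturbs it per subject with
#' lognormal edge noise. Patient subjects additionally lose each
#' weak-quartile template edge with probability `weak_edge_deletion_prob` and
#' have all remaining weights multiplied by `weight_attenuation`. Covariates
#' (age, sex, total intracranial volume, pre-morbid IQ) are drawn to resemble
#' an elderly patient–control cohort; optional linear covariate effects act
#' on log-weights.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `connectomes` (list of [connectome()] objects holding
#'   weight matrices), `covariates` (tibble: id, group, age, sex, tiv,
#'   premorbid_iq, plus optional cognitive/disease columns), and `template`
#'   (the template weight matrix).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  template <- make_template_network(spec)
  n <- spec$n_nodes
  n_sub <- spec$n_controls + spec$n_patients
  group <- factor(rep(c("control", "patient"),
                      c(spec$n_controls, spec$n_patients)),
                  levels = c("control", "patient"))

  pos <- template[upper.tri(template)] > 0
  wvals <- template[upper.tri(template)][pos]
  weak_cut <- unname(quantile(wvals, 0.25, type = 7))
  pairs <- upper_pairs(n)
  edge_on <- template[pairs] > 0
  weak_edge <- edge_on & template[pairs] <= weak_cut

  covs <- tibble::tibble(
    id = sprintf("sub%03d", seq_len(n_sub)),
    group = group,
    age = runif(n_sub, 51, 84),
    sex = as.integer(rep_len(c(0L, 1L), n_sub)[sample.int(n_sub)]),
    tiv = rnorm(n_sub, 1430, 90) * 1000,
    premorbid_iq = rnorm(n_sub, 106, 12)
  )

  eff <- spec$covariate_effects %||% list()
  connectomes <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    wv <- template[pairs]
    keep <- edge_on
    if (group[s] == "patient" && spec$weak_edge_deletion_prob > 0) {
      drop <- weak_edge & (runif(length(keep)) < spec$weak_edge_deletion_prob)
      keep <- keep & !drop
    }
    log_fac <- if (spec$subject_noise_sd > 0) {
      rnorm(length(wv), 0, spec$subject_noise_sd)
    } else {
      numeric(length(wv))
    }
    if (!is.null(eff$age)) log_fac <- log_fac + eff$age * (covs$age[s] - 67)
    if (!is.null(eff$tiv)) {
      log_fac <- log_fac + eff$tiv * (covs$tiv[s] - 1.43e6) / 1000
    }
    if (any(log_fac != 0)) wv <- wv * exp(log_fac)
    if (group[s] == "patient") wv <- wv * spec$weight_attenuation
    wv[!keep] <- 0
    wmat <- matrix(0, n, n)
    wmat[pairs] <- wv
    wmat[pairs[, c(2, 1), drop = FALSE]] <- wv
    connectomes[[s]] <- connectome(n, weights = wmat, strategy = "synthetic")
  }

  if (spec$cognition) {
    is_pat <- group == "patient"
    draw <- function(mu_c, mu_p, sdv) {
      x <- rnorm(n_sub, ifelse(is_pat, mu_p, mu_c), sdv)
      if (spec$missing_prob > 0) {
        x[runif(n_sub) < spec$missing_prob] <- NA_real_
      }
      x
    }
    covs$executive <- draw(12.3, 9.4, 2.6)
    covs$episodic_memory <- draw(10.9, 9.3, 2.8)
    covs$processing_speed <- draw(108, 90, 20)
    covs$working_memory <- draw(106, 94, 14)
    covs$mmse <- pmin(30, round(draw(29.5, 28, 1.2)))
    pat_only <- function(mu, sdv) {
      x <- rep(NA_real_, n_sub)
      x[is_pat] <- rnorm(sum(is_pat), mu, sdv)
      if (spec$missing_prob > 0) {
        x[is_pat][runif(sum(is_pat)) < spec$missing_prob] <- NA_real_
      }
      x
    }
    covs$fsrp <- draw(6.1, 7.2, 3.6)
    covs$pack_years <- pat_only(53.5, 20)
    covs$fev1_pct <- pat_only(52.5, 21.1)
    covs$fvc_pct <- pat_only(86.0, 32.1)
    covs$sgrq <- pat_only(53.7, 30.0)
  }

  list(connectomes = connectomes, covariates = covs, template = template)
}

#' Named covariate presets
#'
#' Returns the covariate set the analysis plan prescribes: age and sex
#' always; total intracranial volume added under the length-adjusted
#' weighting (which carries no head-size correction of its own); pre-morbid
#' IQ added for within-group cognition correlations.
#'
#' @param strategy `"length_adjusted"`, `"volume_adjusted"`, or
#'   `"synthetic"`.
#' @param cognition Correlating against cognitive measures?
#' @return Character vector of covariate column names.
#' @export
covariate_preset <- function(strategy = c("volume_adjusted", "length_adjusted",
                                          "synthetic"),
                             cognition = FALSE) {
  strategy <- match.arg(strategy)
  covs <- c("age", "sex")
  if (strategy == "length_adjusted") covs <- c(covs, "tiv")
  if (cognition) covs <- c(covs, "premorbid_iq")
  covs
}
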