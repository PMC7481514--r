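#' Logistic regrowth curve
#'
#' Area regrowth after defoliation follows a logistic law
#' \deqn{A(t) = \frac{K A_0}{A_0 + (K - A_0) e^{-rt}}}
#' starting from the residual area `A0` left by cutting to stubble height and
#' saturating at the nitrogen-limited asymptote `K`. This law is used as the
#' generative model for synthetic trials because its absolute growth rate
#' dA/dt is unimodal (rises, peaks, falls when `A0 < K/2`) and its relative
#' growth rate decays monotonically — the qualitative pattern observed in
#' regrowing pasture grass.
#'
#' @param t time since the phase's defoliation cut, days (vectorized).
#' @param K asymptotic projected area, pixels.
#' @param A0 residual projected area immediately after the cut, pixels.
#' @param r intrinsic logistic rate, per day.
#' @return projected area in pixels, same length as `t`.
#' @export
logistic_regrowth <- function(t, K, A0, r) {
  check_positive(K, "K"); check_positive(A0, "A0"); check_positive(r, "r")
  K * A0 / (A0 + (K - A0) * exp(-r * t))
}

#' Ground-truth parameters for a synthetic NUE trial
#'
#' Draws the latent biology of a trial: per-genotype intrinsic growth
#' multipliers (log-normal, median 1), per-treatment logistic asymptotes `K`,
#' genotype-by-treatment interaction multipliers, additive replicate (block)
#' effects, and the observation / biomass-coupling noise levels. The defaults
#' encode the screening conditions of a two-N-level ryegrass trial: the
#' moderate-N asymptote is double the low-N asymptote, phase-level area
#' growth rates fall near 2500 (low N) and 5000 (moderate N) pixels per day,
#' and dry matter works out near 1.3 g (0.5 mM) and 2.6 g (5 mM) per
#' four-week phase.
#'
#' @param design a design table from [generate_design()].
#' @param K named numeric vector of asymptotes (pixels), names = treatment
#'   levels as character. Default: 80000 px at 0.5 mM, 160000 px at 5 mM;
#'   for other treatment sets, evenly spaced over the same range.
#' @param A0 residual area after cutting to 5 cm stubble, pixels.
#' @param r logistic rate, per day.
#' @param sd_genotype SD of log genotype multipliers.
#' @param sd_interaction SD of log genotype-by-treatment multipliers.
#' @param sd_replicate SD of the additive replicate effect on `K`, pixels.
#' @param sd_obs SD of the multiplicative log-normal observation noise on
#'   each imaged view area.
#' @param sd_fm SD of the log-normal coupling noise between end-of-phase
#'   area gain and fresh biomass. The default is calibrated so that the
#'   realized Pearson correlation between end-of-phase MPPA and FM across a
#'   full default trial is approximately 0.95.
#' @param sd_dm SD of the extra log-normal noise on the dry-matter fraction.
#' @param fm_per_px fresh biomass per pixel of end-of-phase area gain, g/px.
#' @param dm_fraction named vector of dry-matter fractions by treatment.
#' @param top_ratio ratio of top-view to side-view projected area.
#' @param seed integer seed for the latent draws.
#' @return an object of class `growth_truth` (a list).
#' @export
growth_truth <- function(design,
                         K = NULL,
                         A0 = 8000,
                         r = 0.22,
                         sd_genotype = 0.30,
                         sd_interaction = 0.08,
                         sd_replicate = 3000,
                         sd_obs = 0.05,
                         sd_fm = 0.13,
                         sd_dm = 0.05,
                         fm_per_px = 9e-5,
                         dm_fraction = NULL,
                         top_ratio = 0.8,
                         seed = 1L) {
  genos <- levels(factor(design$genotype))
  trts <- sort(unique(design$treatment))
  reps <- sort(unique(design$replicate))
  if (is.null(K)) {
    K <- if (identical(trts, c(0.5, 5))) c(80000, 160000) else
      seq(80000, 160000, length.out = length(trts))
  }
  if (length(K) != length(trts)) stop("`K` needs one value per treatment", call. = FALSE)
  names(K) <- as.character(trts)
  if (any(K <= A0)) stop("every asymptote K must exceed the residual area A0", call. = FALSE)
  if (is.null(dm_fraction)) dm_fraction <- rep(0.20, length(trts))
  if (length(dm_fraction) != length(trts)) {
    stop("`dm_fraction` needs one value per treatment", call. = FALSE)
  }
  names(dm_fraction) <- as.character(trts)
  check_positive(A0, "A0"); check_positive(r, "r"); check_positive(fm_per_px, "fm_per_px")

  with_seed(seed, {
    # log-normals centred to mean 1 so multipliers average out of the yield scale
    g_mult <- exp(rnorm(length(genos), -sd_genotype^2 / 2, sd_genotype))
    names(g_mult) <- genos
    gt_mult <- matrix(exp(rnorm(length(genos) * length(trts),
                                -sd_interaction^2 / 2, sd_interaction)),
                      nrow = length(genos),
                      dimnames = list(genos, as.character(trts)))
    rep_eff <- rnorm(length(reps), 0, sd_replicate)
    names(rep_eff) <- as.character(reps)
    structure(list(
      genotype_mult = g_mult, K = K, gt_mult = gt_mult, rep_effect = rep_eff,
      A0 = A0, r = r, sd_obs = sd_obs, sd_fm = sd_fm, sd_dm = sd_dm,
      fm_per_px = fm_per_px, dm_fraction = dm_fraction, top_ratio = top_ratio,
      sd_genotype = sd_genotype, sd_interaction = sd_interaction,
      sd_replicate = sd_replicate, seed = seed
    ), class = "growth_truth")
  })
}

# Effective asymptote for one pot in one phase. During the acclimation phase
# the treatment effect is suppressed (all pots share the mean K and no
# interaction), encoding the observed N-level equivalence before residual
# root N is exhausted.
effective_K <- function(truth, genotype, treatment, replicate, phase) {
  g <- truth$genotype_mult[as.character(genotype)]
  b <- truth$rep_effect[as.character(replicate)]
  K <- if (phase == "AP") {
    mean(truth$K) * g
  } else {
    truth$K[as.character(treatment)] * g *
      truth$gt_mult[cbind(as.character(genotype), as.character(treatment))]
  }
  pmax(unname(K + b), truth$A0 * 1.1)
}

#' Simulate per-pot regrowth trajectories for a multi-phase trial
#'
#' Each pot regrows logistically from the residual area `A0` after every
#' defoliation cut; the trajectory resets to `A0` at each cut. The first
#' regrowth period (acclimation phase, AP) shares one asymptote across
#' treatments; the experimental phases EP-1 and EP-2 apply the full
#' genotype x treatment x block structure of `truth`. Observed view areas
#' (side 0 degrees, side 90 degrees, top) carry independent multiplicative
#' log-normal noise around the true area.
#'
#' @param design design table from [generate_design()].
#' @param truth a [growth_truth()] object.
#' @param cut_dates strictly increasing defoliation days (3 cuts for the
#'   standard AP / EP-1 / EP-2 trial), counted from experiment start (day 0).
#' @param imaging_interval days between imaging dates (default 3.5 = twice
#'   weekly, giving 8 imaging dates per 28-day phase).
#' @param seed integer seed for observation noise.
#' @return a `data.frame` with columns `pot_id`, `genotype`, `treatment`,
#'   `replicate`, `day`, `phase`, `t_in_phase`, `true_area`, `area_side0`,
#'   `area_side90`, `area_top`; attribute `phase_end` holds the noiseless
#'   true area at each phase's cut together with the phase duration, and
#'   attribute `cut_dates` the cut schedule.
#' @export
simulate_growth <- function(design, truth, cut_dates = c(28, 56, 84),
                            imaging_interval = 3.5, seed = 1L) {
  if (any(diff(cut_dates) <= 0)) {
    stop("`cut_dates` must be strictly increasing", call. = FALSE)
  }
  check_positive(imaging_interval, "imaging_interval")
  days <- seq(0, max(cut_dates), by = imaging_interval)
  days <- days[days < max(cut_dates)]
  phase_of <- assign_phases(days, cut_dates)
  starts <- c(0, cut_dates[-length(cut_dates)])
  names(starts) <- phase_levels(length(cut_dates))
  t_in_phase <- days - starts[as.character(phase_of)]

  n_pots <- nrow(design)
  n_days <- length(days)
  phases <- phase_levels(length(cut_dates))

  # true area grid: pots x days
  Keff <- sapply(phases, function(ph)
    effective_K(truth, design$genotype, design$treatment, design$replicate, ph))
  if (n_pots == 1L) Keff <- matrix(Keff, nrow = 1, dimnames = list(NULL, phases))
  true_area <- matrix(NA_real_, n_pots, n_days)
  for (j in seq_len(n_days)) {
    ph <- as.character(phase_of[j])
    true_area[, j] <- logistic_regrowth(t_in_phase[j], Keff[, ph], truth$A0, truth$r)
  }

  with_seed(seed, {
    noise <- function() {
      if (truth$sd_obs == 0) 1 else
        exp(matrix(rnorm(n_pots * n_days, -truth$sd_obs^2 / 2, truth$sd_obs),
                   n_pots, n_days))
    }
    s0 <- true_area * noise()
    s90 <- true_area * noise()
    top <- truth$top_ratio * true_area * noise()

    out <- data.frame(
      pot_id = rep(design$pot_id, times = n_days),
      genotype = rep(design$genotype, times = n_days),
      treatment = rep(design$treatment, times = n_days),
      replicate = rep(design$replicate, times = n_days),
      day = rep(days, each = n_pots),
      phase = rep(phase_of, each = n_pots),
      t_in_phase = rep(t_in_phase, each = n_pots),
      true_area = as.vector(true_area),
      area_side0 = as.vector(s0),
      area_side90 = as.vector(s90),
      area_top = as.vector(top),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$pot_id, out$day), ]
    rownames(out) <- NULL

    durations <- diff(c(0, cut_dates))
    phase_end <- do.call(rbind, lapply(seq_along(phases), function(i) {
      data.frame(
        pot_id = design$pot_id,
        genotype = design$genotype,
        treatment = design$treatment,
        replicate = design$replicate,
        phase = phases[i],
        phase_duration = durations[i],
        true_end_area = logistic_regrowth(durations[i], Keff[, phases[i]],
                                          truth$A0, truth$r),
        stringsAsFactors = FALSE
      )
    }))
    attr(out, "phase_end") <- phase_end
    attr(out, "cut_dates") <- cut_dates
    out
  })
}

#' Simulate destructive harvest records
#'
#' At each defoliation cut the regrown material above stubble height is
#' harvested: fresh biomass is proportional to the pot's true end-of-phase
#' area gain (`true area at the cut` - `A0`) with multiplicative log-normal
#' coupling noise, and dry biomass applies a treatment-specific dry-matter
#' fraction with additional log-normal noise. With all noise SDs at zero the
#' area-gain-to-FM map is exactly linear, so the area/biomass correlation
#' is 1 by construction.
#'
#' @param trajectories output of [simulate_growth()] (its `phase_end`
#'   attribute supplies the true end-of-phase areas).
#' @param truth the [growth_truth()] object used to simulate growth.
#' @param seed integer seed for harvest noise.
#' @return a `data.frame` of harvest records: `pot_id`, `phase`, `treatment`,
#'   `genotype`, `replicate`, `FM` (g), `DM` (g), `phase_duration` (days).
#' @export
simulate_harvests <- function(trajectories, truth, seed = 1L) {
  pe <- attr(trajectories, "phase_end")
  if (is.null(pe)) stop("`trajectories` must come from simulate_growth()", call. = FALSE)
  phases <- phase_levels(3L)
  if (!all(phases %in% pe$phase)) {
    stop("trajectories must span all three phases (AP, EP-1, EP-2)", call. = FALSE)
  }
  n <- nrow(pe)
  with_seed(seed, {
    fm_noise <- if (truth$sd_fm == 0) 1 else exp(rnorm(n, -truth$sd_fm^2 / 2, truth$sd_fm))
    dm_noise <- if (truth$sd_dm == 0) 1 else exp(rnorm(n, -truth$sd_dm^2 / 2, truth$sd_dm))
    FM <- truth$fm_per_px * (pe$true_end_area - truth$A0) * fm_noise
    DM <- FM * truth$dm_fraction[as.character(pe$treatment)] * dm_noise
    data.frame(
      pot_id = pe$pot_id, phase = pe$phase, treatment = pe$treatment,
      genotype = pe$genotype, replicate = pe$replicate,
      FM = FM, DM = pmin(DM, FM), phase_duration = pe$phase_duration,
      stringsAsFactors = FALSE
    )
  })
}
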