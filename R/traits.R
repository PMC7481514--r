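phase_levels <- function(n_cuts) {
  if (n_cuts == 3L) c("AP", "EP-1", "EP-2") else
    c("AP", paste0("EP-", seq_len(n_cuts - 1L)))
}

#' Assign regrowth-phase labels to imaging timestamps
#'
#' The trial is divided by three defoliation cuts into an acclimation phase
#' (AP) and two experimental phases (EP-1, EP-2). Assignment uses half-open
#' intervals anchored at the cuts: AP = \[start, cut1), EP-1 = \[cut1, cut2),
#' EP-2 = \[cut2, cut3). A timestamp exactly at a cut therefore belongs to
#' the phase that starts at that cut (the plant has just been cut back).
#' Timestamps at or after the final cut are labelled `out-of-study` and a
#' warning is logged.
#'
#' @param timestamps numeric days since experiment start.
#' @param cut_dates exactly 3 strictly increasing cut days.
#' @param start experiment start day (default 0; must precede the first cut).
#' @return a factor with levels `AP`, `EP-1`, `EP-2`, `out-of-study`.
#' @examples
#' assign_phases(c(10, 30, 56, 90), c(28, 56, 84))
#' @export
assign_phases <- function(timestamps, cut_dates, start = 0) {
  if (length(cut_dates) < 2L || any(diff(cut_dates) <= 0)) {
    stop("`cut_dates` must be strictly increasing", call. = FALSE)
  }
  if (start >= cut_dates[1]) {
    stop("experiment start must precede the first cut", call. = FALSE)
  }
  levs <- c(phase_levels(length(cut_dates)), "out-of-study")
  idx <- findInterval(timestamps, c(start, cut_dates))
  idx[idx == 0L] <- length(levs)                 # before start: not in study
  if (any(idx == length(cut_dates) + 1L)) {
    ryenue_log(sprintf("%d timestamp(s) at/after the final cut labelled out-of-study",
                       sum(idx == length(cut_dates) + 1L)), "WARN")
  }
  idx[idx > length(cut_dates)] <- length(levs)
  factor(levs[idx], levels = levs)
}

#' Mean projected plant area from the two side views
#'
#' MPPA is the arithmetic mean of the segmented plant pixel areas of the two
#' orthogonal (0 and 90 degree) side-view images. It is the primary digital
#' biomass proxy of the pipeline. Missing (empty-flagged) views propagate
#' to a missing MPPA.
#'
#' @param area_side0,area_side90 projected areas in pixels (vectorized).
#' @return `(area_side0 + area_side90) / 2`, `NA` where either view is `NA`.
#' @export
mppa <- function(area_side0, area_side90) {
  if (any(area_side0 < 0, na.rm = TRUE) || any(area_side90 < 0, na.rm = TRUE)) {
    stop("view areas must be non-negative", call. = FALSE)
  }
  miss <- is.na(area_side0) | is.na(area_side90)
  if (any(miss)) ryenue_log(sprintf("MPPA missing for %d observation(s)", sum(miss)), "WARN")
  (area_side0 + area_side90) / 2
}

#' Digital volume proxies from the three view areas
#'
#' Three scalar combinations of the side- and top-view projected areas are
#' used as non-destructive biomass proxies:
#' \deqn{V = A_{s.0} + A_{s.90} + A_t}
#' \deqn{V_{lemnatec} = A_{s.0} \times A_{s.90} \times A_t}
#' \deqn{V_{keygene} = A_{s.0} + A_{s.90} + \ln(A_t^3)}
#' The logarithm in `V_keygene` is read as the natural log of the cubed top
#' area, i.e. `3 * log(A_t)`, matching the natural-log convention of the
#' relative growth rate; base-10 is selectable via `log_base`.
#'
#' @param area_side0,area_side90,area_top projected areas in pixels
#'   (vectorized). `area_top` must be strictly positive for `V_keygene`.
#' @param log_base base of the logarithm in `V_keygene`: `"e"` (default)
#'   or `"10"`.
#' @return a `data.frame` with columns `V`, `V_lemnatec`, `V_keygene`.
#' @examples
#' digital_volumes(1, 2, 3)$V             # 6
#' digital_volumes(100, 200, exp(3))$V_keygene  # 309
#' @export
digital_volumes <- function(area_side0, area_side90, area_top,
                            log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  if (any(area_top <= 0, na.rm = TRUE)) {
    stop("`area_top` must be strictly positive for V_keygene", call. = FALSE)
  }
  lg <- if (log_base == "e") log(area_top) else log10(area_top)
  data.frame(
    V = area_side0 + area_side90 + area_top,
    V_lemnatec = area_side0 * area_side90 * area_top,
    V_keygene = area_side0 + area_side90 + 3 * lg
  )
}

#' Nitrogen mass supplied per pot per phase
#'
#' The nutrient solution delivers elemental nitrogen at a molar
#' concentration; the mass supplied over a phase is
#' `concentration (mmol/L) x volume (L) x applications x 14.007 mg/mmol`,
#' reported in grams. The standard schedule — seven applications of 100 ml
#' at 0.5 mM or 5 mM — supplies 4.9 mg and 49 mg N per pot per phase.
#'
#' @param concentration_mM N concentration of the solution, mM (mmol/L).
#' @param volume_L volume per application, litres.
#' @param n_applications number of applications in the phase.
#' @param molar_mass_g_per_mmol molar mass of elemental N, g/mmol
#'   (default 0.014007).
#' @return supplied N in grams (vectorized over the first three arguments).
#' @examples
#' n_supplied(0.5, 0.1, 7)  # 0.0049 g = 4.9 mg
#' n_supplied(5, 0.1, 7)    # 0.049 g = 49 mg
#' @export
n_supplied <- function(concentration_mM, volume_L, n_applications,
                       molar_mass_g_per_mmol = 0.014007) {
  check_positive(concentration_mM, "concentration_mM")
  check_positive(volume_L, "volume_L")
  check_positive(n_applications, "n_applications")
  check_positive(molar_mass_g_per_mmol, "molar_mass_g_per_mmol")
  concentration_mM * volume_L * n_applications * molar_mass_g_per_mmol
}

#' Nitrogen use efficiency
#'
#' NUE is defined as units of dry matter produced per unit of nitrogen
#' supplied: `NUE = DM (g) / Ns (g)`, in g DM per g N.
#'
#' @param DM dry biomass, grams (non-negative; vectorized).
#' @param Ns supplied N, grams (strictly positive).
#' @return the exact quotient `DM / Ns`.
#' @examples
#' nue(1.29, n_supplied(0.5, 0.1, 7))  # about 263.3
#' @export
nue <- function(DM, Ns) {
  if (any(Ns <= 0, na.rm = TRUE)) stop("`Ns` must be strictly positive", call. = FALSE)
  if (any(DM < 0, na.rm = TRUE)) stop("`DM` must be non-negative", call. = FALSE)
  DM / Ns
}

#' Absolute and relative growth rates from an MPPA time series
#'
#' For each pot and phase, the phase-level absolute growth rate on area is
#' `AGR = (MPPA2 - MPPA1) / (t2 - t1)` and the relative growth rate is
#' `RGR = (ln MPPA2 - ln MPPA1) / (t2 - t1)`, where `t1` and `t2` are the
#' first and last imaging dates within the phase. Per-interval rates between
#' consecutive imaging dates are also returned, for temporal growth-rate
#' profiles. When harvest records are supplied, the phase-level table also
#' carries `AGR_dm` = dry matter at the phase-end harvest divided by the
#' phase duration in days.
#'
#' @param timeline `data.frame` with columns `pot_id`, `day`, `mppa`, and
#'   `phase` (or supply `cut_dates` to derive phases).
#' @param cut_dates optional cut schedule used to label phases when the
#'   timeline has no `phase` column.
#' @param harvests optional harvest records ([simulate_harvests()] shape)
#'   providing `DM` and `phase_duration` per pot and phase.
#' @return a list with `phase_rates` (per pot x phase: `t1`, `t2`, `MPPA1`,
#'   `MPPA2`, `AGR_area`, `RGR`, and `AGR_dm` when harvests are given) and
#'   `interval_rates` (per consecutive imaging interval). Phases with fewer
#'   than two imaging dates yield no row and are logged; a non-positive MPPA
#'   endpoint leaves `RGR` missing while `AGR_area` is still computed.
#' @export
growth_rates <- function(timeline, cut_dates = NULL, harvests = NULL) {
  stopifnot(all(c("pot_id", "day", "mppa") %in% names(timeline)))
  if (!"phase" %in% names(timeline)) {
    if (is.null(cut_dates)) stop("supply `cut_dates` or a `phase` column", call. = FALSE)
    timeline$phase <- assign_phases(timeline$day, cut_dates)
  }
  timeline <- timeline[!is.na(timeline$mppa) & timeline$phase != "out-of-study", ]
  timeline <- timeline[order(timeline$pot_id, timeline$day), ]

  grp <- split(timeline, list(timeline$pot_id, timeline$phase), drop = TRUE)
  phase_rows <- lapply(grp, function(d) {
    if (nrow(d) < 2L) {
      ryenue_log(sprintf("pot %s phase %s: <2 imaging dates, growth rates skipped",
                         d$pot_id[1], as.character(d$phase[1])), "WARN")
      return(NULL)
    }
    m1 <- d$mppa[1]; m2 <- d$mppa[nrow(d)]
    t1 <- d$day[1]; t2 <- d$day[nrow(d)]
    rgr <- if (m1 > 0 && m2 > 0) (log(m2) - log(m1)) / (t2 - t1) else NA_real_
    data.frame(pot_id = d$pot_id[1], phase = as.character(d$phase[1]),
               t1 = t1, t2 = t2, MPPA1 = m1, MPPA2 = m2,
               AGR_area = (m2 - m1) / (t2 - t1), RGR = rgr,
               stringsAsFactors = FALSE)
  })
  phase_rates <- do.call(rbind, phase_rows)

  interval_rows <- lapply(grp, function(d) {
    if (nrow(d) < 2L) return(NULL)
    i <- seq_len(nrow(d) - 1L)
    m1 <- d$mppa[i]; m2 <- d$mppa[i + 1L]
    dt <- d$day[i + 1L] - d$day[i]
    data.frame(pot_id = d$pot_id[1], phase = as.character(d$phase[1]),
               t1 = d$day[i], t2 = d$day[i + 1L],
               AGR_area = (m2 - m1) / dt,
               RGR = ifelse(m1 > 0 & m2 > 0, (log(m2) - log(m1)) / dt, NA_real_),
               stringsAsFactors = FALSE)
  })
  interval_rates <- do.call(rbind, interval_rows)
  if (is.null(phase_rates)) {
    return(list(phase_rates = NULL, interval_rates = interval_rates))
  }
  rownames(phase_rates) <- rownames(interval_rates) <- NULL

  if (!is.null(harvests)) {
    h <- harvests[, c("pot_id", "phase", "DM", "phase_duration")]
    phase_rates <- merge(phase_rates, h, by = c("pot_id", "phase"),
                         all.x = TRUE, sort = FALSE)
    phase_rates$AGR_dm <- phase_rates$DM / phase_rates$phase_duration
    phase_rates$DM <- NULL
  }
  ord <- order(phase_rates$pot_id, phase_rates$phase)
  list(phase_rates = phase_rates[ord, ], interval_rates = interval_rates)
}

#' Derive the per-pot per-phase trait table
#'
#' Joins the three views of the feature (or trajectory) table into wide form
#' per imaging date, computes MPPA and the digital volumes, takes the
#' end-of-phase values as the phase's digital traits, attaches growth rates,
#' harvest biomass, supplied N and NUE. NUE is only defined for the
#' experimental phases (the acclimation phase consumes residual nitrogen,
#' so its `Ns` and `NUE` are `NA`).
#'
#' @param features long feature table with columns `pot_id`, `day` (or
#'   `date`), `view` (`top`, `side-0`, `side-90`), `area`, plus optional
#'   `empty_flag`; alternatively a [simulate_growth()] trajectory table
#'   (columns `area_side0`, `area_side90`, `area_top`) is accepted directly.
#' @param harvests harvest records with `pot_id`, `phase`, `FM`, `DM`,
#'   `phase_duration`, `treatment`.
#' @param cut_dates defoliation schedule (3 cut days).
#' @param schedule named list per treatment level (character names) with
#'   elements `concentration_mM`, `volume_L`, `n_applications` — the
#'   nutrient schedule used for `Ns`.
#' @return a list with `traits` (one row per pot x phase: end-of-phase MPPA,
#'   `V`, `V_lemnatec`, `V_keygene`, `AGR_area`, `RGR`, `AGR_dm`, `FM`,
#'   `DM`, `Ns`, `NUE`) and `interval_rates`.
#' @export
derive_traits <- function(features, harvests, cut_dates, schedule) {
  wide <- features_to_wide(features)
  wide$phase <- assign_phases(wide$day, cut_dates)
  wide <- wide[wide$phase != "out-of-study", ]
  wide$mppa <- mppa(wide$area_side0, wide$area_side90)
  vol <- digital_volumes(pmax(wide$area_side0, 1e-9),
                         pmax(wide$area_side90, 1e-9),
                         pmax(wide$area_top, 1e-9))
  wide <- cbind(wide, vol)

  gr <- growth_rates(wide[, c("pot_id", "day", "mppa", "phase")],
                     harvests = harvests)

  # end-of-phase digital traits: last imaging date within the phase
  wide <- wide[order(wide$pot_id, wide$day), ]
  key <- interaction(wide$pot_id, wide$phase, drop = TRUE)
  last_idx <- tapply(seq_len(nrow(wide)), key, function(i) i[length(i)])
  eop <- wide[unlist(last_idx),
              c("pot_id", "phase", "day", "mppa", "V", "V_lemnatec", "V_keygene")]
  names(eop)[names(eop) == "day"] <- "eop_day"
  eop$phase <- as.character(eop$phase)

  traits <- merge(harvests, eop, by = c("pot_id", "phase"), all.x = TRUE)
  traits <- merge(traits,
                  gr$phase_rates[, c("pot_id", "phase", "AGR_area", "RGR",
                                     if ("AGR_dm" %in% names(gr$phase_rates)) "AGR_dm")],
                  by = c("pot_id", "phase"), all.x = TRUE)

  ns_by_trt <- vapply(as.character(traits$treatment), function(tr) {
    s <- schedule[[tr]]
    if (is.null(s)) return(NA_real_)
    n_supplied(s$concentration_mM, s$volume_L, s$n_applications)
  }, numeric(1))
  traits$Ns <- ifelse(traits$phase == "AP", NA_real_, ns_by_trt)
  traits$NUE <- ifelse(is.na(traits$Ns), NA_real_, traits$DM / traits$Ns)
  traits <- traits[order(traits$pot_id, traits$phase), ]
  rownames(traits) <- NULL
  list(traits = traits, interval_rates = gr$interval_rates)
}

# Accept either the long (pot_id, day, view, area) feature-table shape or a
# simulate_growth() trajectory and return one row per pot x day with
# area_side0 / area_side90 / area_top columns.
features_to_wide <- function(features) {
  if (all(c("area_side0", "area_side90", "area_top") %in% names(features))) {
    return(features[, c("pot_id", "day", "area_side0", "area_side90", "area_top")])
  }
  stopifnot(all(c("pot_id", "view", "area") %in% names(features)))
  if (!"day" %in% names(features)) {
    if ("date" %in% names(features)) features$day <- features$date else
      stop("feature table needs a `day` (or `date`) column", call. = FALSE)
  }
  if ("empty_flag" %in% names(features)) {
    features$area[features$empty_flag %in% TRUE] <- NA_real_
  }
  vmap <- c("side-0" = "area_side0", "side-90" = "area_side90", "top" = "area_top")
  bad <- setdiff(unique(features$view), names(vmap))
  if (length(bad)) stop("unknown view label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  wide <- stats::reshape(
    features[, c("pot_id", "day", "view", "area")],
    idvar = c("pot_id", "day"), timevar = "view", direction = "wide"
  )
  names(wide) <- sub("^area\\.(.*)$", "\\1", names(wide))
  names(wide)[match(names(vmap), names(wide))] <- vmap
  wide
}
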