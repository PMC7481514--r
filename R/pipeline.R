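#' Default pipeline configuration
#'
#' One nested list controls the whole pipeline: trial design dimensions,
#' defoliation and nutrient schedules, growth-truth parameters, rendering,
#' segmentation and statistics options, and the master seed. The defaults
#' describe the standard screening trial: 76 genotypes x 2 N levels
#' (0.5 / 5 mM) x 4 replicates in rows of 38 (608 pots), cuts at days
#' 28/56/84, imaging every 3.5 days, and 7 x 100 ml nutrient applications
#' per phase. Rendering is off by default (the simulated feature table is
#' written directly from the trajectory view areas); enable it to also
#' rasterize PNG imagery for a subset of pots.
#'
#' @return a nested named list; serialize with [yaml::write_yaml()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    design = list(n_genotypes = 76L, n_treatments = 2L, n_replicates = 4L,
                  row_capacity = 38L, treatments = c(0.5, 5)),
    schedule = list(
      cut_dates = c(28, 56, 84),
      imaging_interval = 3.5,
      nutrient = list(
        `0.5` = list(concentration_mM = 0.5, volume_L = 0.1, n_applications = 7L),
        `5` = list(concentration_mM = 5, volume_L = 0.1, n_applications = 7L)
      )
    ),
    growth = list(A0 = 8000, r = 0.22, K = c(80000, 160000),
                  sd_genotype = 0.30, sd_interaction = 0.08, sd_replicate = 3000,
                  sd_obs = 0.05, sd_fm = 0.13, sd_dm = 0.05,
                  fm_per_px = 9e-5, dm_fraction = c(0.20, 0.20), top_ratio = 0.8),
    render = list(enabled = FALSE, image_size = 192L, max_pots = 4L),
    segmentation = list(threshold = "otsu", min_exg = 20, open_radius = 0L,
                        close_radius = 0L, min_size = 15L),
    stats = list(responses = c("DM", "NUE"), per_treatment = FALSE)
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file path) against the documented
#' schema and returns *all* violations, each naming the offending key.
#'
#' @param config a configuration list, or path to a YAML file.
#' @return `data.frame` with columns `key` and `problem`; zero rows when
#'   the configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  v <- list()
  bad <- function(key, problem) v[[length(v) + 1L]] <<- data.frame(key = key, problem = problem)
  need <- function(key) {
    node <- config
    for (part in strsplit(key, ".", fixed = TRUE)[[1]]) {
      if (!is.list(node) || is.null(node[[part]])) { bad(key, "missing"); return(NULL) }
      node <- node[[part]]
    }
    node
  }
  pos_int <- function(key) {
    x <- need(key)
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)))
      bad(key, "must be a positive integer")
  }
  pos_num <- function(key) {
    x <- need(key)
    if (!is.null(x) && (!is.numeric(x) || any(is.na(x)) || any(x <= 0)))
      bad(key, "must be positive")
  }
  nonneg <- function(key) {
    x <- need(key)
    if (!is.null(x) && (!is.numeric(x) || any(is.na(x)) || any(x < 0)))
      bad(key, "must be non-negative")
  }

  for (k in c("design.n_genotypes", "design.n_treatments", "design.n_replicates",
              "design.row_capacity")) pos_int(k)
  pos_num("design.treatments")
  trts <- need("design.treatments"); nt <- need("design.n_treatments")
  if (!is.null(trts) && !is.null(nt) && length(trts) != nt)
    bad("design.treatments", "length must equal design.n_treatments")

  cuts <- need("schedule.cut_dates")
  if (!is.null(cuts) && (length(cuts) != 3L || any(diff(cuts) <= 0)))
    bad("schedule.cut_dates", "must be 3 strictly increasing cut days")
  pos_num("schedule.imaging_interval")
  nut <- need("schedule.nutrient")
  if (!is.null(nut) && !is.null(trts)) {
    for (tr in as.character(trts)) {
      s <- nut[[tr]]
      if (is.null(s)) { bad(paste0("schedule.nutrient.", tr), "missing"); next }
      for (f in c("concentration_mM", "volume_L", "n_applications")) {
        if (is.null(s[[f]]) || !is.numeric(s[[f]]) || s[[f]] <= 0)
          bad(paste0("schedule.nutrient.", tr, ".", f), "must be positive")
      }
    }
  }

  for (k in c("growth.A0", "growth.r", "growth.fm_per_px")) pos_num(k)
  for (k in c("growth.sd_genotype", "growth.sd_interaction", "growth.sd_replicate",
              "growth.sd_obs", "growth.sd_fm", "growth.sd_dm")) nonneg(k)
  Kv <- need("growth.K")
  if (!is.null(Kv) && !is.null(trts) && length(Kv) != length(trts))
    bad("growth.K", "needs one asymptote per treatment")
  A0v <- need("growth.A0")
  if (!is.null(Kv) && !is.null(A0v) && is.numeric(Kv) && is.numeric(A0v) &&
      any(Kv <= A0v))
    bad("growth.K", "every asymptote must exceed growth.A0")
  dmf <- need("growth.dm_fraction")
  if (!is.null(dmf) && (!is.numeric(dmf) || any(dmf <= 0) || any(dmf > 1)))
    bad("growth.dm_fraction", "must be in (0, 1]")

  pos_int("render.image_size")
  s <- need("seed")
  if (!is.null(s) && (!is.numeric(s) || length(s) != 1 || is.na(s)))
    bad("seed", "must be a single integer")

  if (length(v)) do.call(rbind, v) else data.frame(key = character(), problem = character())
}

#' Run the screening pipeline end to end
#'
#' Executes the requested stages in order — `simulate` (design, growth
#' trajectories, harvests, feature table, optional rendered imagery),
#' `extract` (segmentation + shape features over rendered imagery),
#' `derive` (per-pot per-phase traits: MPPA, digital volumes, growth rates,
#' Ns, NUE), `analyze` (summaries, feature-biomass correlations, BLUEs,
#' truth recovery) — writing every artifact under `out_dir` and a JSON run
#' manifest with an MD5 checksum per output file. Every stochastic stage
#' derives its seed from the master seed and the stage name, so an
#' identical config and seed reproduce identical manifests.
#'
#' @param config configuration list ([default_config()]) or YAML path.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "extract", "derive", "analyze")`.
#' @param seed optional master seed overriding `config$seed`.
#' @return the manifest, invisibly. On a mid-run stage failure the partial
#'   outputs and a manifest marking the failure point are preserved before
#'   the error propagates.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "extract", "derive", "analyze"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validate_config(config)
  if (nrow(viol)) {
    stop("invalid configuration:\n",
         paste(sprintf("  %s: %s", viol$key, viol$problem), collapse = "\n"),
         call. = FALSE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) config$seed <- seed
  master <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ryenue_log_file(file.path(out_dir, "run.log"))
  on.exit(ryenue_log_file(NULL), add = TRUE)

  manifest <- list(package = "ryeNUE",
                   version = as.character(utils::packageVersion("ryeNUE")),
                   seed = master, stages = stages, status = "running",
                   files = list())
  path <- function(...) file.path(out_dir, ...)
  register <- function(f) {
    manifest$files[[basename(f)]] <<- list(
      path = f, md5 = unname(tools::md5sum(f)), bytes = file.size(f))
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  run_stage <- function(name, fun) {
    ryenue_log(paste("stage:", name))
    tryCatch(fun(), error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      save_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    cfg <- config
    design <- generate_design(cfg$design$n_genotypes, cfg$design$n_treatments,
                              cfg$design$n_replicates, cfg$design$row_capacity,
                              seed = derive_seed(master, "design"),
                              treatments = cfg$design$treatments)
    g <- cfg$growth
    truth <- growth_truth(design, K = g$K, A0 = g$A0, r = g$r,
                          sd_genotype = g$sd_genotype, sd_interaction = g$sd_interaction,
                          sd_replicate = g$sd_replicate, sd_obs = g$sd_obs,
                          sd_fm = g$sd_fm, sd_dm = g$sd_dm, fm_per_px = g$fm_per_px,
                          dm_fraction = g$dm_fraction, top_ratio = g$top_ratio,
                          seed = derive_seed(master, "truth"))
    traj <- simulate_growth(design, truth, cut_dates = cfg$schedule$cut_dates,
                            imaging_interval = cfg$schedule$imaging_interval,
                            seed = derive_seed(master, "growth"))
    harv <- simulate_harvests(traj, truth, seed = derive_seed(master, "harvest"))

    utils::write.csv(design, path("design.csv"), row.names = FALSE)
    utils::write.csv(traj, path("trajectories.csv"), row.names = FALSE)
    utils::write.csv(harv, path("harvests.csv"), row.names = FALSE)
    feats <- traj[, c("pot_id", "day", "area_side0", "area_side90", "area_top")]
    utils::write.csv(feats, path("features.csv"), row.names = FALSE)
    truth_out <- unclass(truth)
    truth_out$gt_mult <- as.data.frame(truth_out$gt_mult)
    jsonlite::write_json(truth_out, path("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    for (f in c("design.csv", "trajectories.csv", "harvests.csv",
                "features.csv", "truth.json")) register(path(f))

    if (isTRUE(cfg$render$enabled)) {
      pots <- utils::head(design$pot_id, cfg$render$max_pots)
      sub <- traj[traj$pot_id %in% pots, ]
      for (i in seq_len(nrow(sub))) {
        sp <- plant_spec_for_area(sub$area_side0[i] / 25,
                                  image_size = cfg$render$image_size,
                                  seed = derive_seed(master, paste0("render", sub$pot_id[i], sub$day[i])))
        for (vw in c("top", "side-0", "side-90")) {
          rp <- render_plant(sp, vw, image_size = cfg$render$image_size,
                             seed = derive_seed(master, paste0("shade", vw, i)))
          d1 <- path("images", sub$pot_id[i], format(sub$day[i]))
          d2 <- path("masks", sub$pot_id[i], format(sub$day[i]))
          dir.create(d1, recursive = TRUE, showWarnings = FALSE)
          dir.create(d2, recursive = TRUE, showWarnings = FALSE)
          png::writePNG(rp$image, file.path(d1, paste0(vw, ".png")))
          png::writePNG(rp$mask * 1, file.path(d2, paste0(vw, ".png")))
        }
      }
      ryenue_log(sprintf("rendered imagery for %d pot(s)", length(pots)))
    }
    save_manifest()
  })

  if ("extract" %in% stages) run_stage("extract", function() {
    img_root <- path("images")
    if (!dir.exists(img_root)) {
      ryenue_log("no rendered imagery on disk; extract stage skipped", "WARN")
      return(invisible(NULL))
    }
    sp <- config$segmentation
    tab <- batch_extract(img_root,
                         segment_params(threshold = if (identical(sp$threshold, "otsu")) "otsu" else as.numeric(sp$threshold),
                                        min_exg = sp$min_exg, open_radius = sp$open_radius,
                                        close_radius = sp$close_radius, min_size = sp$min_size))
    utils::write.csv(tab, path("features_extracted.csv"), row.names = FALSE)
    register(path("features_extracted.csv"))
    save_manifest()
  })

  if ("derive" %in% stages) run_stage("derive", function() {
    feats <- utils::read.csv(path("features.csv"))
    harv <- utils::read.csv(path("harvests.csv"))
    dt <- derive_traits(feats, harv, cut_dates = config$schedule$cut_dates,
                        schedule = config$schedule$nutrient)
    utils::write.csv(dt$traits, path("traits.csv"), row.names = FALSE)
    utils::write.csv(dt$interval_rates, path("interval_rates.csv"), row.names = FALSE)
    register(path("traits.csv")); register(path("interval_rates.csv"))
    save_manifest()
  })

  if ("analyze" %in% stages) run_stage("analyze", function() {
    traits <- utils::read.csv(path("traits.csv"))
    design <- utils::read.csv(path("design.csv"))
    traits <- merge(traits, design[, c("pot_id", "replicate")],
                    by = "pot_id", suffixes = c("", ".design"))
    ep <- traits[traits$phase != "AP", ]

    summ <- rbind(
      cbind(trait = "DM", summarize_traits(ep, "DM", c("phase", "treatment"))),
      cbind(trait = "NUE", summarize_traits(ep, "NUE", c("phase", "treatment")))
    )
    utils::write.csv(summ, path("summary.csv"), row.names = FALSE)
    register(path("summary.csv"))

    cors <- correlate_traits(ep, c("mppa", "V", "V_lemnatec", "V_keygene", "FM", "DM"))
    utils::write.csv(as.data.frame(cors$r), path("correlations.csv"))
    register(path("correlations.csv"))

    truth_available <- file.exists(path("truth.json"))
    recovery <- list()
    for (resp in config$stats$responses) {
      for (ph in unique(ep$phase)) {
        fit <- fit_blues(ep[ep$phase == ph, ], resp,
                         per_treatment = isTRUE(config$stats$per_treatment))
        f <- sprintf("blues_%s_%s.csv", resp, ph)
        utils::write.csv(fit$blues, path(f), row.names = FALSE)
        register(path(f))
        if (truth_available && resp == "DM") {
          tj <- jsonlite::read_json(path("truth.json"), simplifyVector = TRUE)
          truth <- list(genotype_mult = stats::setNames(tj$genotype_mult,
                                                        names(tj$genotype_mult)))
          rec <- recover_parameters(fit, truth)
          recovery[[paste(resp, ph, sep = "_")]] <- rec
        }
      }
    }
    if (length(recovery)) {
      jsonlite::write_json(recovery, path("recovery.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      register(path("recovery.json"))
    }
    save_manifest()
  })

  manifest$status <- "success"
  save_manifest()
  ryenue_log("pipeline complete")
  invisible(manifest)
}
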