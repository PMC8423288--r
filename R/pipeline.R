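#' Run configuration for batched simulations
#'
#' The configuration mirrors a three-level hierarchy: one *sample*
#' (morphology), a list of *models* (cuff placement, materials, solver),
#' and a list of *sims* (fiberset, waveform, protocol). The pipeline
#' executes the full models x sims cross-product up to a breakpoint
#' stage.
#'
#' Accepted fields (as an R list or a JSON file):
#' * `sample`: [mock_params()] fields (plus `mode`), or
#'   `list(json = "path")` for a previously written sample
#' * `shrinkage`: optional shrinkage-correction fraction
#' * `models`: list of `list(cuff = list(...), add_ang =, solver =
#'   "analytic"|"fd", medium =, contact_weights =, deform = TRUE)`
#' * `sims`: list of `list(fiberset = list(mode, count, density, seed),
#'   fiber_model =, diameter =, fiber_length =, waveform = list(...),
#'   protocol = "activation"|"block"|"fixed", amplitudes =,
#'   search = list(...))`
#' * `breakpoint`: one of `"morphology"`, `"bases"`, `"fibersets"`,
#'   `"potentials"`, `"simulate"`, `"analyze"` (default)
#' * `out_dir`: output root; `seed`: global seed offset
#'
#' @param config list or path to a JSON file
#' @return an object of class `run_config`
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = FALSE)
  stopifnot(is.list(config))
  config$breakpoint <- config$breakpoint %||% "analyze"
  stages <- c("morphology", "bases", "fibersets", "potentials", "simulate",
              "analyze")
  if (!config$breakpoint %in% stages)
    stop("breakpoint must be one of: ", paste(stages, collapse = ", "))
  if (is.null(config$sample)) stop("config needs a 'sample' block")
  if (config$breakpoint != "morphology") {
    if (!length(config$models)) stop("config needs at least one model")
    if (!config$breakpoint %in% c("bases") && !length(config$sims))
      stop("config needs at least one sim")
  }
  config$out_dir <- config$out_dir %||% tempfile("nervestim_run_")
  config$seed <- config$seed %||% 1L
  structure(config, class = "run_config")
}

#' Execute the simulation pipeline
#'
#' Runs stages in order — morphology, bases, fibersets, potentials,
#' simulate, analyze — stopping at the configured breakpoint. Basis
#' solutions are cached under `out_dir/cache` keyed by a hash of geometry,
#' materials and grid, and reused on warm reruns (`force = TRUE`
#' recomputes). Failed (model, sim, fiber) jobs are logged and skipped,
#' not fatal. All randomness derives from the config seed, so two clean
#' runs produce identical outputs.
#'
#' @param run a [run_config()] (or list/path coercible to one)
#' @param force ignore cached bases
#' @param quiet suppress progress messages
#' @return list with the sample, per-model placements and bases, fibersets,
#'   a `thresholds` data frame (when simulated), skipped-job log, and
#'   output paths
#' @export
run_pipeline <- function(run, force = FALSE, quiet = FALSE) {
  run <- if (inherits(run, "run_config")) run else run_config(run)
  stages <- c("morphology", "bases", "fibersets", "potentials", "simulate",
              "analyze")
  upto <- match(run$breakpoint, stages)
  dir.create(run$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  # ---- morphology ----
  sample <- build_sample_from_config(run$sample, run$seed)
  if (!is.null(run$shrinkage) && run$shrinkage > 0) {
    sample <- apply_shrinkage_correction(sample, run$shrinkage)
    say("applied shrinkage correction %.3f", run$shrinkage)
  }
  write_sample_json(sample, file.path(run$out_dir, "sample.json"))
  say("morphology: %d fascicles", length(sample$fascicles))
  out <- list(sample = sample, out_dir = run$out_dir, log = log_lines)
  if (upto < 2L) { out$log <- log_lines; return(out) }

  # ---- bases (per model) ----
  cache_dir <- file.path(run$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  models <- lapply(seq_along(run$models), function(mi) {
    m <- run$models[[mi]]
    cuff <- build_cuff_from_config(m$cuff)
    samp_m <- sample
    if (isTRUE(m$deform %||% TRUE) && !is.null(sample$nerve))
      samp_m <- deform_to_cuff(samp_m, cuff$inner_diameter)
    pl <- place_cuff(cuff, samp_m, add_ang = m$add_ang %||% 0,
                     z_center = m$z_center %||% 0)
    solver <- m$solver %||% "analytic"
    medium <- get_material(m$medium %||% "endoneurium",
                           custom = m$materials)
    nb <- length(cuff$contacts)
    bases <- vector("list", nb)
    for (ci in seq_len(nb)) {
      if (solver == "analytic") {
        bases[[ci]] <- solve_basis_analytic(pl, ci, medium)
      } else {
        g <- do.call(grid_spec, m$grid)
        cm <- fd_map_from_sample(samp_m, medium, m)
        key <- object_hash(list(pl$source_points[ci, ], cm, g))
        cf <- file.path(cache_dir, paste0("basis_", key, ".rds"))
        if (!force && file.exists(cf)) {
          bases[[ci]] <- readRDS(cf)
          say("model %d contact %d: basis cache hit (%s)", mi, ci, key)
        } else {
          bases[[ci]] <- solve_basis_fd(pl, ci, cm, g)
          saveRDS(bases[[ci]], cf)
          say("model %d contact %d: basis solved (%d iters)", mi, ci,
              bases[[ci]]$iterations)
        }
      }
    }
    weights <- unlist(m$contact_weights %||% rep(-1, nb))  # cathodic default
    list(index = mi, cuff = cuff, sample = samp_m, placement = pl,
         bases = bases, field = superpose(bases, weights),
         add_ang = m$add_ang %||% 0)
  })
  out$models <- models
  if (upto < 3L) { out$log <- log_lines; return(out) }

  # ---- fibersets (per model x sim: deformation differs per model) ----
  sims <- run$sims
  fibersets <- lapply(models, function(md) lapply(seq_along(sims),
    function(si) {
      s <- sims[[si]]
      fsm <- s$fiberset %||% list(mode = "CENTROID")
      mode <- fiber_xy_mode(fsm$mode %||% "CENTROID",
                            count = fsm$count %||% 1L,
                            density = fsm$density,
                            seed = (fsm$seed %||% run$seed))
      build_fiberset(md$sample, mode, s$fiber_model %||% "MRG",
                     s$diameter %||% 10, s$fiber_length %||% 50000)
    }))
  out$fibersets <- fibersets
  if (upto < 4L) { out$log <- log_lines; return(out) }

  # ---- potentials ----
  potentials <- lapply(seq_along(models), function(mi)
    lapply(seq_along(sims), function(si) {
      fs <- fibersets[[mi]][[si]]
      lapply(fs$fibers, function(fb)
        sample_potentials(models[[mi]]$field,
                          cbind(fb$xy[1], fb$xy[2], fb$z)))
    }))
  out$potentials <- potentials
  if (upto < 5L) { out$log <- log_lines; return(out) }

  # ---- simulate ----
  skipped <- list()
  rows <- list()
  for (mi in seq_along(models)) for (si in seq_along(sims)) {
    s <- sims[[si]]
    fs <- fibersets[[mi]][[si]]
    wf <- build_waveform_from_config(s$waveform, s$protocol %||% "activation")
    search <- do.call(search_params, s$search %||% list())
    fib_cache <- new.env()
    for (fi in seq_along(fs$fibers)) {
      fb <- fs$fibers[[fi]]
      key <- sprintf("%s_%g", fb$model, fb$diameter)
      fiber <- get0(key, fib_cache)
      if (is.null(fiber)) {
        fiber <- build_fiber(fb$model, fb$diameter, fb$z, fb$compartment)
        assign(key, fiber, fib_cache)
      }
      up <- potentials[[mi]][[si]][[fi]]
      res <- tryCatch({
        proto <- s$protocol %||% "activation"
        if (proto == "activation") {
          tr <- find_activation_threshold(fiber, up, wf, search)
          c(threshold = tr$threshold, iterations = tr$iterations)
        } else if (proto == "block") {
          tr <- find_block_threshold(fiber, up, wf, search = search)
          c(threshold = tr$threshold, iterations = tr$iterations)
        } else {
          recs <- run_fixed_amplitudes(fiber, up, wf,
                                       unlist(s$amplitudes))
          c(threshold = NA_real_,
            iterations = sum(attr(recs, "spike_counts")))
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <-
          list(model = mi, sim = si, fiber = fi,
               message = conditionMessage(res))
        say("skipped model %d sim %d fiber %d: %s", mi, si, fi,
            conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          model = mi, sim = si, fiber = fi,
          x = fb$xy[1], y = fb$xy[2], fascicle = fb$fascicle,
          fiber_model = fb$model, diameter = fb$diameter,
          protocol = s$protocol %||% "activation",
          add_ang = models[[mi]]$add_ang,
          threshold = unname(res["threshold"]),
          iterations = unname(res["iterations"]))
      }
    }
  }
  thresholds <- if (length(rows)) do.call(rbind, rows) else NULL
  out$thresholds <- thresholds
  out$skipped <- skipped
  if (!is.null(thresholds))
    utils::write.csv(thresholds,
                     file.path(run$out_dir, "thresholds.csv"),
                     row.names = FALSE)
  if (upto < 6L) { out$log <- log_lines; return(out) }

  # ---- analyze ----
  if (!is.null(thresholds)) {
    heat <- lapply(seq_along(models), function(mi)
      lapply(seq_along(sims), function(si) {
        sub <- thresholds[thresholds$model == mi & thresholds$sim == si, ]
        if (!nrow(sub)) return(NULL)
        heatmap_table(fibersets[[mi]][[si]], sub$threshold)
      }))
    out$heatmaps <- heat
    say("analyze: %d threshold rows across %d models x %d sims",
        nrow(thresholds), length(models), length(sims))
  }
  writeLines(log_lines, file.path(run$out_dir, "run.log"))
  out$log <- log_lines
  out
}

build_sample_from_config <- function(sc, seed) {
  if (!is.null(sc$json)) return(read_sample_json(sc$json))
  mode <- sc$mode %||% "probabilistic"
  args <- sc
  args$mode <- mode
  args$json <- NULL
  args$seed <- sc$seed %||% seed
  # coerce nested JSON lists to the expected shapes
  if (!is.null(args$nerve)) args$nerve <- lapply(args$nerve, unlist)
  p <- do.call(mock_params, args)
  if (mode == "explicit") generate_mock_explicit(p)
  else generate_mock_probabilistic(p)
}

build_cuff_from_config <- function(cc) {
  if (!is.null(cc$preset))
    return(do.call(cuff_preset, cc[names(cc) %in%
      c("preset", "inner_diameter", "length", "theta_span", "z_span",
        "pitch")]))
  do.call(cuff_spec, cc)
}

build_waveform_from_config <- function(wc, protocol) {
  if (is.null(wc)) {
    wc <- if (protocol == "block")
      list(mode = "BIPHASIC_FULL_DUTY", frequency = 10, dt = 5, tstop = 46)
    else
      list(mode = "BIPHASIC_PULSE_TRAIN", pw = 100, period = 5000, dt = 5,
           tstop = 5, delay = 100)
  }
  make_waveform(do.call(waveform_spec, wc))
}

fd_map_from_sample <- function(sample, medium, m) {
  regions <- list()
  layers <- list()
  zext <- unlist(m$z_extent %||% c(-1e5, 1e5))
  for (fa in sample$fascicles) {
    if (length(fa$inners) > 1L && is.null(fa$outer))
      stop("peanut fascicles need an outer trace for FD conductivity maps")
    for (inn in fa$inners) {
      regions[[length(regions) + 1L]] <-
        list(trace = inn, z_extent = zext,
             material = get_material("endoneurium", custom = m$materials))
      layers[[length(layers) + 1L]] <-
        c(list(trace = inn, z_extent = zext),
          perineurium_layer(inn, thickness_um = m$perineurium_thickness))
    }
  }
  conductivity_map(medium, regions, layers)
}
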