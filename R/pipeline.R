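pipelineStages <- c("simulate", "peaks", "migration", "extrusion", "edu",
                    "shed")

#' Build and validate a pipeline configuration
#'
#' A pipeline configuration is a named list (typically loaded from YAML)
#' with experiment metadata (`seed`, `frame_interval_min`,
#' `induction_time_min`), a `stages` character vector, and one parameter
#' block per requested stage.  Validation is fail-fast: every requested
#' stage must have its block (analysis stages also require the `simulate`
#' sub-block that produces their input), and this is checked before any
#' computation.
#'
#' @param config named list, or path to a YAML file.
#' @return the validated config (class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$seed)) stop("config must set a master seed")
  if (is.null(config$stages))
    config$stages <- intersect(pipelineStages, names(config))
  bad <- setdiff(config$stages, pipelineStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needsSim <- c(peaks = "tracks", migration = "tracks", extrusion = "zstack",
                edu = "edu", shed = "shed")
  for (st in config$stages) {
    if (is.null(config[[st]]))
      stop("validation error: stage '", st,
           "' requested but its config block is missing")
    if (st %in% names(needsSim)) {
      sub <- needsSim[[st]]
      if (!"simulate" %in% config$stages ||
          is.null(config$simulate[[sub]]))
        stop("validation error: stage '", st, "' requires simulate block '",
             sub, "'")
    }
  }
  structure(config, class = c("PipelineConfig", "list"))
}

# Pull a stage block with defaults merged in.
blockWith <- function(config, name, defaults) {
  utils::modifyList(defaults, if (is.null(config[[name]])) list()
                              else config[[name]])
}

#' Run the synthetic-to-report pipeline
#'
#' Executes the requested stages in dependency order (simulate, then
#' peaks / migration / extrusion / edu / shed), writing every stage's
#' outputs as CSV/TIFF/JSON into `outDir` and returning a run manifest
#' (config hash, per-file checksums, row counts, wall time per stage).
#' Deterministic given the config's master seed.  A stage error aborts
#' downstream stages but leaves completed outputs intact.
#'
#' @param config a [pipelineConfig()] (or list / YAML path coercible to
#'   one).
#' @param outDir output directory, created if needed.
#' @return the manifest, invisibly (also written to
#'   `<outDir>/manifest.json`).
#' @export
runPipeline <- function(config, outDir) {
  config <- pipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgHash <- fnv1a32(yaml::as.yaml(unclass(config)))
  seeds <- childSeeds(config$seed, length(pipelineStages))
  names(seeds) <- pipelineStages
  manifest <- list(config_hash = cfgHash,
                   version = as.character(utils::packageVersion("mapkdyn")),
                   stages = list())
  record <- function(stage, files, rows, t0) {
    manifest$stages[[stage]] <<- list(
      outputs = lapply(files, function(f)
        list(file = basename(f),
             checksum = unname(tools::md5sum(f)))),
      rows = rows,
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
  }
  fim <- if (is.null(config$frame_interval_min)) 5
         else config$frame_interval_min

  paths <- list(tracks = file.path(outDir, "tracks.csv"),
                truth = file.path(outDir, "ground_truth.json"),
                edu = file.path(outDir, "edu_counts.csv"),
                shedTab = file.path(outDir, "shed_abundance.csv"))
  zstackTruth <- list()

  if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    files <- character(0); rows <- 0L; truthAll <- list()
    sim <- config$simulate
    if (!is.null(sim$tracks)) {
      b <- blockWith(list(x = sim$tracks), "x", list(
        n_cells = 60, n_frames = 73, bias_kappa = 1, inducible_fraction = 0.1,
        bias_onset_min = 120, field_size_um = 400, mean_rate = 2,
        noise_sd = 0.05, loc_fold = 1.8))
      tp <- pulseTrainParams(meanRate = b$mean_rate, noiseSd = b$noise_sd)
      mpar <- migrationSimParams(
        nCells = b$n_cells, nFrames = b$n_frames, biasKappa = b$bias_kappa,
        inducibleFraction = b$inducible_fraction,
        biasOnsetMin = b$bias_onset_min, fieldSizeUm = b$field_size_um,
        frameIntervalMin = fim, seed = seeds[["simulate"]])
      simT <- simulateTrackPopulation(tp, mpar,
                                      inducibleLocFold = b$loc_fold)
      writeTrackTable(simT$tracks, paths$tracks)
      truthAll$tracks <- simT$truth[c("biasKappa", "centerXy",
                                      "biasOnsetMin")]
      files <- c(files, paths$tracks); rows <- rows + nrow(simT$tracks)
    }
    if (!is.null(sim$zstack)) {
      b <- blockWith(list(x = sim$zstack), "x", list(
        n_positions = 2, n_baseline = 2, extrusion_offset_um = 6,
        nx = 120, ny = 120, n_nuclei = 60))
      zseeds <- childSeeds(seeds[["simulate"]] + 1L,
                           b$n_positions + b$n_baseline)
      k <- 0L
      for (grp in c("oncogenic", "parental")) {
        nPos <- if (grp == "oncogenic") b$n_positions else b$n_baseline
        off <- if (grp == "oncogenic") b$extrusion_offset_um else 0
        for (i in seq_len(nPos)) {
          k <- k + 1L
          zp <- zStackSimParams(nx = b$nx, ny = b$ny, nNuclei = b$n_nuclei,
                                extrusionOffsetUm = off, seed = zseeds[k])
          pid <- sprintf("%s_%02d", grp, i)
          simZ <- simulateZStack(zp, positionId = pid)
          f <- file.path(outDir, paste0("stack_", pid, ".tif"))
          writeStack(simZ$stack, f, simZ$zStepUm, simZ$zMinUm)
          zstackTruth[[pid]] <- list(group = grp, offset = off)
          files <- c(files, f)
        }
      }
      truthAll$zstack <- zstackTruth
    }
    if (!is.null(sim$edu)) {
      b <- blockWith(list(x = sim$edu), "x", list(n_positions = 8))
      simE <- simulateEduTable(b$n_positions, seed = seeds[["simulate"]] + 2L)
      utils::write.csv(simE$table, paths$edu, row.names = FALSE)
      truthAll$edu <- simE$truth$fractions
      files <- c(files, paths$edu); rows <- rows + nrow(simE$table)
    }
    if (!is.null(sim$shed)) {
      b <- blockWith(list(x = sim$shed), "x", list(
        n_proteins = 100, n_hits = 5, effect_lnfc = 1, replicate_cv = 0.2))
      simS <- simulateShedTable(b$n_proteins, b$n_hits, b$effect_lnfc,
                                b$replicate_cv,
                                seed = seeds[["simulate"]] + 3L)
      utils::write.csv(simS$table, paths$shedTab, row.names = FALSE)
      truthAll$shed <- list(hits = simS$truth$hits)
      files <- c(files, paths$shedTab); rows <- rows + nrow(simS$table)
    }
    writeGroundTruth(truthAll, paths$truth)
    files <- c(files, paths$truth)
    record("simulate", files, rows, t0)
  }

  if ("peaks" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    b <- blockWith(config, "peaks", list(
      min_amplitude = 0.15, min_slope = 0.005, fall_fraction = 0.5,
      smooth_window = 3, min_coverage = 2 / 3))
    tracks <- readTrackTable(paths$tracks)
    cleaned <- cleanTraces(tracksToTraces(tracks), b$min_coverage)
    cfgP <- peakConfig(smoothWindow = b$smooth_window,
                       minAmplitude = b$min_amplitude,
                       minSlope = b$min_slope,
                       fallFraction = b$fall_fraction)
    metrics <- lapply(cleaned$retained, function(tr) {
      pk <- countPeaks(tr, cfgP)
      rowsC <- tracks[tracks$cell_id == cellId(tr), , drop = FALSE]
      loc <- new("LocalizationTrace", cellId = cellId(tr),
                 timeMin = rowsC$time_min,
                 ncRatio = rowsC$nuc_loc / rowsC$cyt_loc)
      call <- classifyDynamics(pk, tr)
      data.frame(cell_id = cellId(tr), peak_count = peakCount(pk),
                 loc_fold = localizationFoldChange(loc),
                 mig_fold = migrationFoldChange(rowsC),
                 label = dynamicsLabel(call), stringsAsFactors = FALSE)
    })
    metrics <- do.call(rbind, c(metrics, list(stringsAsFactors = FALSE)))
    fM <- file.path(outDir, "cell_metrics.csv")
    utils::write.csv(cbind(metrics, config_hash = cfgHash), fM,
                     row.names = FALSE)
    fS <- file.path(outDir, "population_summary.csv")
    utils::write.csv(summarizePopulation(cleaned$retained), fS,
                     row.names = FALSE)
    fX <- file.path(outDir, "exclusion_log.csv")
    utils::write.csv(cleaned$log, fX, row.names = FALSE)
    record("peaks", c(fM, fS, fX), nrow(metrics), t0)
  }

  if ("migration" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    b <- blockWith(config, "migration", list(
      interval_min = 20, half_width_um = 100,
      epoch_before = c(0, 120), epoch_after = c(120, 360),
      n_iter = 200, n_sub = 500, n_bins = 12))
    tracks <- readTrackTable(paths$tracks)
    before <- collectAngles(tracks, b$epoch_before, "sim", "before",
                            b$interval_min, b$half_width_um)
    after <- collectAngles(tracks, b$epoch_after, "sim", "after",
                           b$interval_min, b$half_width_um)
    angTab <- rbind(
      data.frame(condition = "sim", epoch = "before",
                 angle_deg = angles(before)),
      data.frame(condition = "sim", epoch = "after",
                 angle_deg = angles(after)))
    fA <- file.path(outDir, "angles.csv")
    utils::write.csv(angTab, fA, row.names = FALSE)
    ks <- subsampledKsTest(before, after, b$n_iter, b$n_sub,
                           seed = seeds[["migration"]])
    fK <- file.path(outDir, "migration_ks.csv")
    utils::write.csv(data.frame(
      condition = "sim", pair = "before_vs_after", median_p = medianP(ks),
      stars = ks@stars, n_iter = b$n_iter,
      n_sub_a = ks@subsampleSize[1], n_sub_b = ks@subsampleSize[2],
      config_hash = cfgHash), fK, row.names = FALSE)
    record("migration", c(fA, fK), nrow(angTab), t0)
  }

  if ("extrusion" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    truth <- readGroundTruth(paths$truth)$zstack
    res <- lapply(names(truth), function(pid) {
      f <- file.path(outDir, paste0("stack_", pid, ".tif"))
      st <- readStack(f)
      cbind(quantifyExtrusion(st, attr(st, "zStepUm"), attr(st, "zMinUm"),
                              pid),
            group = truth[[pid]]$group, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    base <- res$delta_z_um[res$group == "parental" & res$converged]
    res$normalized_delta_z_um <- normalizeCondition(res$delta_z_um, base)
    res$outlier <- FALSE
    if (sum(res$converged) >= 4)
      res$outlier[res$converged] <-
        flagOutliers(res$normalized_delta_z_um[res$converged])
    fE <- file.path(outDir, "extrusion.csv")
    utils::write.csv(cbind(res, config_hash = cfgHash), fE,
                     row.names = FALSE)
    record("extrusion", fE, nrow(res), t0)
  }

  if ("edu" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    edu <- utils::read.csv(paths$edu, stringsAsFactors = FALSE)
    folds <- eduFoldTable(edu)
    fF <- file.path(outDir, "edu_folds.csv")
    utils::write.csv(cbind(folds, config_hash = cfgHash), fF,
                     row.names = FALSE)
    record("edu", fF, nrow(folds), t0)
  }

  if ("shed" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    b <- blockWith(config, "shed", list(p_max = 0.05, fc_min = 1.5))
    tab <- utils::read.csv(paths$shedTab, stringsAsFactors = FALSE)
    recs <- shedRecords(tab)
    filt <- filterShedProteins(recs, b$p_max, b$fc_min)
    fH <- file.path(outDir, "shed_filtered.csv")
    utils::write.csv(cbind(filt, config_hash = cfgHash), fH,
                     row.names = FALSE)
    record("shed", fH, nrow(filt), t0)
  }

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
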