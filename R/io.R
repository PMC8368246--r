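## NIfTI and tabular I/O, scheme serialization, and the top-level
## pipeline that chains simulate -> train -> segment -> quantify ->
## evaluate -> reliability -> characterize, writing a manifest per stage.

#' Read a 3D NIfTI volume
#'
#' Accepts plain and gzipped NIfTI-1. 4D or higher-dimensional inputs
#' are rejected with a clear error.
#'
#' @param path file path (.nii or .nii.gz).
#' @return list with `data` (3D array), `spacing` (mm) and `affine`
#'   (4 x 4 xform matrix).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D NIfTI volume, got %dD: %s", length(d),
                 path), call. = FALSE)
  list(data = array(as.numeric(img), d),
       spacing = RNifti::pixdim(img)[1:3],
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a 3D NIfTI volume
#'
#' @param grid 3D numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing in mm (ignored when `affine` is given).
#' @param affine optional 4 x 4 xform; defaults to a diagonal RAS affine
#'   built from the spacing.
#' @return the path, invisibly.
#' @export
writeVolume <- function(grid, path, spacing = c(1, 1, 1), affine = NULL) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L)
    stop("expected a 3D array", call. = FALSE)
  img <- RNifti::asNifti(grid)
  if (is.null(affine))
    affine <- diag(c(spacing, 1))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a segmentation mask from NIfTI
#'
#' @param path file path.
#' @return a [SegmentationMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  if (any(abs(v$data - round(v$data)) > 1e-6))
    warning("mask values are not integral; rounding", call. = FALSE)
  SegmentationMask(array(as.integer(round(v$data)), dim(v$data)),
                   v$spacing)
}

#' Write a segmentation mask to NIfTI
#'
#' @param mask a [SegmentationMask-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  writeVolume(mask@labels, path, spacing = mask@spacing)
}

#' Serialize a label scheme to YAML
#'
#' @param scheme a [MuscleLabelScheme-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScheme <- function(scheme, path) {
  g <- schemeGroups(scheme)
  obj <- list(background = scheme@background,
              groups = lapply(seq_len(nrow(g)), function(i)
                list(group = g$group[i], left = g$left[i],
                     right = if (is.na(g$right[i])) NULL else g$right[i],
                     levels = g$levels[i])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a label scheme from YAML
#'
#' @param path path written by [writeScheme()].
#' @return a [MuscleLabelScheme-class].
#' @export
readScheme <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- do.call(rbind, lapply(obj$groups, function(x)
    data.frame(group = x$group, left = x$left,
               right = if (is.null(x$right)) NA_integer_ else x$right,
               levels = if (is.null(x$levels)) NA_character_ else x$levels,
               stringsAsFactors = FALSE)))
  MuscleLabelScheme(g, background = obj$background)
}

#' Write / read measure tables as CSV
#'
#' @param measures a `MuscleMeasures` data.frame.
#' @param path CSV path.
#' @return the path ([writeMeasures()]) or the data.frame
#'   ([readMeasures()]).
#' @export
writeMeasures <- function(measures, path) {
  write.csv(measures, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasures
#' @export
readMeasures <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' @param out_dir run directory (created if absent).
#' @param seed master seed; recorded in every manifest and used to derive
#'   all stage seeds.
#' @param n_train,n_test numbers of simulated training/testing phantoms.
#' @param phantom base [phantomSpec()] for the simulated scans (default
#'   the desk-scale 4-class phantom).
#' @param net a [denseVNetConfig()] sized to the phantom.
#' @param train a [trainingConfig()].
#' @param perturb a [raterPerturbSpec()] for the simulated second rater.
#' @param cohort a [cohortSpec()] for the characterization stage.
#' @param stages character vector of stages to run, in order.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(out_dir, seed = 1L, n_train = 6L, n_test = 3L,
                      phantom = deskPhantomSpec(),
                      net = denseVNetConfig(n_classes = 4L,
                                            init_features = 6L,
                                            growth = c(4L, 6L),
                                            bottleneck = c(6L, 12L),
                                            head_features = 6L,
                                            dropout = 0),
                      train = trainingConfig(window = c(24L, 24L, 8L),
                                             max_iterations = 150L,
                                             eval_every = 25L),
                      perturb = raterPerturbSpec(boundary_shift = 1L,
                                                 morph_prob = 0.5),
                      cohort = cohortSpec(),
                      stages = c("simulate", "train", "segment",
                                 "evaluate", "reliability",
                                 "characterize"),
                      log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(n_train >= 1, n_test >= 1, seed == round(seed))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 phantom = phantom, net = net, train = train,
                 perturb = perturb, cohort = cohort, stages = stages,
                 log_level = log_level), class = "RunConfig")
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

.writeManifest <- function(dir, stage, inputs, outputs, seed, hash) {
  man <- list(stage = stage, inputs = as.list(basename(inputs)),
              outputs = as.list(basename(outputs)), seed = seed,
              config_hash = hash)
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage,
                                                  ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the end-to-end pipeline on simulated data
#'
#' Chains the requested stages: `simulate` (phantom quartets + masks +
#' truth tables), `train` (dense V-Net on the training phantoms,
#' validation on the same non-augmented volumes), `segment` (predictions
#' + per-muscle measures for the test phantoms), `evaluate` (overlap
#' metrics GT vs prediction), `reliability` (agreement battery GT vs a
#' simulated second rater), `characterize` (synthetic cohort analyses).
#' Every stage writes its outputs plus a JSON manifest (inputs, outputs,
#' seed, config hash) under `out_dir`; re-running with the same
#' configuration reproduces identical outputs. A failing stage leaves a
#' `FAILED` marker file and propagates the error.
#'
#' @param config a [runConfig()].
#' @return the run directory, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  info <- function(...) if (config$log_level == "info") message(...)
  scheme <- config$phantom$scheme
  paths <- new.env(parent = emptyenv())
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    sdir <- file.path(config$out_dir, name)
    dir.create(sdir, showWarnings = FALSE)
    info("stage: ", name)
    tryCatch(fun(sdir), error = function(e) {
      writeLines(conditionMessage(e), file.path(sdir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  simPhantom <- function(i) {
    sp <- config$phantom
    sp$seed <- config$seed * 1000L + i
    generatePhantom(sp)
  }

  stage("simulate", function(sdir) {
    outs <- character()
    for (i in seq_len(config$n_train + config$n_test)) {
      ph <- simPhantom(i)
      tag <- sprintf("%s%02d", if (i <= config$n_train) "train" else
        "test", i)
      sp <- voxelSpacing(ph$volume)
      f <- file.path(sdir, paste0(tag, c("_fat.nii", "_water.nii",
                                         "_ip.nii", "_oop.nii",
                                         "_mask.nii", "_truth.csv")))
      writeVolume(fatSignal(ph$volume), f[1], sp)
      writeVolume(waterSignal(ph$volume), f[2], sp)
      writeVolume(inPhase(ph$volume), f[3], sp)
      writeVolume(outOfPhase(ph$volume), f[4], sp)
      writeMask(ph$mask, f[5])
      write.csv(ph$truth, f[6], row.names = FALSE)
      outs <- c(outs, f)
    }
    writeScheme(scheme, file.path(sdir, "scheme.yaml"))
    .writeManifest(config$out_dir, "simulate", character(),
                   c(outs, file.path(sdir, "scheme.yaml")),
                   config$seed, hash)
  })

  getPhantoms <- function(idx) lapply(idx, simPhantom)
  train_idx <- seq_len(config$n_train)
  test_idx <- config$n_train + seq_len(config$n_test)

  model <- NULL
  stage("train", function(sdir) {
    phs <- getPhantoms(train_idx)
    samples <- lapply(phs, function(ph)
      makeTrainingSample(ph$volume, ph$mask, scheme))
    net <- buildDenseVNet(config$net, seed = config$seed)
    tc <- config$train
    tc$seed <- config$seed
    model <<- trainDenseVNet(net, samples, config = tc,
                             verbose = config$log_level == "info")
    write.csv(model$history, file.path(sdir, "history.csv"),
              row.names = FALSE)
    saveRDS(model, file.path(sdir, "model.rds"))
    .writeManifest(config$out_dir, "train", character(),
                   file.path(sdir, c("history.csv", "model.rds")),
                   config$seed, hash)
  })

  stage("segment", function(sdir) {
    if (is.null(model))
      model <<- readRDS(file.path(config$out_dir, "train", "model.rds"))
    outs <- character()
    meas <- list()
    for (i in test_idx) {
      ph <- simPhantom(i)
      seg <- segmentDixon(model, inPhase(ph$volume),
                          outOfPhase(ph$volume),
                          spacing = voxelSpacing(ph$volume))
      f <- file.path(sdir, sprintf("test%02d_pred.nii", i))
      writeMask(seg$mask, f)
      outs <- c(outs, f)
      meas[[length(meas) + 1L]] <-
        measureAll(ph$volume, seg$mask, scheme,
                   scan_id = sprintf("test%02d", i))
    }
    mf <- file.path(sdir, "measures_pred.csv")
    writeMeasures(do.call(rbind, meas), mf)
    .writeManifest(config$out_dir, "segment", character(),
                   c(outs, mf), config$seed, hash)
  })

  stage("evaluate", function(sdir) {
    if (is.null(model))
      model <<- readRDS(file.path(config$out_dir, "train", "model.rds"))
    reports <- list()
    for (i in test_idx) {
      ph <- simPhantom(i)
      seg <- segmentDixon(model, inPhase(ph$volume),
                          outOfPhase(ph$volume),
                          spacing = voxelSpacing(ph$volume))
      rep1 <- metricsReport(ph$mask, seg$mask, scheme)
      rep1$scan_id <- sprintf("test%02d", i)
      reports[[length(reports) + 1L]] <- rep1
    }
    f <- file.path(sdir, "overlap_metrics.csv")
    write.csv(do.call(rbind, reports), f, row.names = FALSE)
    .writeManifest(config$out_dir, "evaluate", character(), f,
                   config$seed, hash)
  })

  stage("reliability", function(sdir) {
    meas_gt <- list(); meas_r2 <- list()
    for (i in test_idx) {
      ph <- simPhantom(i)
      pspec <- config$perturb
      pspec$seed <- config$seed * 1000L + 500L + i
      m2 <- perturbMask(ph$mask, pspec)
      id <- sprintf("test%02d", i)
      meas_gt[[length(meas_gt) + 1L]] <-
        measureAll(ph$volume, ph$mask, scheme, scan_id = id)
      meas_r2[[length(meas_r2) + 1L]] <-
        measureAll(ph$volume, m2, scheme, scan_id = id)
    }
    rel <- reliabilityReport(do.call(rbind, meas_gt),
                             do.call(rbind, meas_r2))
    f <- file.path(sdir, "reliability.csv")
    write.csv(rel, f, row.names = FALSE)
    .writeManifest(config$out_dir, "reliability", character(), f,
                   config$seed, hash)
  })

  stage("characterize", function(sdir) {
    cs <- config$cohort
    cs$seed <- config$seed
    tab <- generateCohort(cs)
    f_tab <- file.path(sdir, "cohort.csv")
    write.csv(tab, f_tab, row.names = FALSE)
    sx <- sexAncova(tab)
    pt <- pairedGroupTests(tab)
    rm <- rmAncova(tab)
    groups <- names(cs$baseline)
    pc <- do.call(rbind, lapply(groups, function(g) {
      r_age <- partialCorr(tab[[g]], tab$age,
                           data.frame(female = tab$sex == "F",
                                      bmi = tab$bmi))
      r_bmi <- partialCorr(tab[[g]], tab$bmi,
                           data.frame(female = tab$sex == "F",
                                      age = tab$age))
      data.frame(group = g, r_age = r_age$r, p_age = r_age$p,
                 r_bmi = r_bmi$r, p_bmi = r_bmi$p,
                 stringsAsFactors = FALSE)
    }))
    f_pt <- file.path(sdir, "paired_tests.csv")
    f_pc <- file.path(sdir, "partial_correlations.csv")
    write.csv(pt, f_pt, row.names = FALSE)
    write.csv(pc, f_pc, row.names = FALSE)
    f_js <- file.path(sdir, "characterization.json")
    jsonlite::write_json(list(
      sex_ancova = list(estimate = sx$estimate, se = sx$se,
                        ci = sx$ci, F = sx$F, p = sx$p),
      rm_ancova_within = rm$within, rm_ancova_between = rm$between),
      f_js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .writeManifest(config$out_dir, "characterize", f_tab,
                   c(f_pt, f_pc, f_js), config$seed, hash)
  })

  invisible(config$out_dir)
}
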