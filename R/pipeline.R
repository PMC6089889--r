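#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed. Defaults are
#' the full-resolution protocol (3100-px spots, 750/375/250 patch geometry,
#' alpha 0.5, 224-px inputs, 50000 iterations, c = 0.25); the `"half"`
#' profile is the desk-scale variant used throughout the tests (1550-px
#' spots, halved patch geometry, alpha 0.25, 96-px inputs, resize 107).
#'
#' @param profile `"full"` or `"half"`.
#' @param n_train_spots,n_test_spots Synthetic cohort sizes.
#' @param iterations Training iterations.
#' @param alpha,input_size Network width multiplier and input size.
#' @param threshold Scoring threshold `c`.
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param ... Overrides stored verbatim in the config.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("full", "half"),
                            n_train_spots = 40L, n_test_spots = 20L,
                            iterations = NULL, alpha = NULL,
                            input_size = NULL, threshold = 0.25,
                            seed = 1L, ...) {
  profile <- match.arg(profile)
  full <- profile == "full"
  geometry <- if (full) patch_geometry("full")
              else patch_geometry("half", resize_to = 107L, crop_size = 96L)
  cfg <- list(
    profile = profile,
    spot_size = if (full) 3100L else 1550L,
    geometry = geometry,
    network = network_config(alpha = alpha %||% if (full) 0.5 else 0.25,
                             input_size = input_size %||%
                               if (full) 224L else 96L),
    iterations = as.integer(iterations %||% if (full) 50000L else 2000L),
    n_train_spots = as.integer(n_train_spots),
    n_test_spots = as.integer(n_test_spots),
    threshold = threshold,
    seed = as.integer(seed),
    extra = list(...))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  flat <- list(profile = config$profile,
               n_train_spots = config$n_train_spots,
               n_test_spots = config$n_test_spots,
               iterations = config$iterations,
               alpha = config$network$alpha,
               input_size = config$network$input_size,
               threshold = config$threshold,
               seed = config$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

PIPELINE_STAGES <- c("simulate", "mask", "patch", "train", "infer",
                     "score", "evaluate", "cam", "survival")

write_manifest <- function(run_dir, stage, config, inputs, outputs) {
  jsonlite::write_json(
    list(stage = stage, config_hash = rlang::hash(unclass(config)),
         seed = config$seed, inputs = inputs, outputs = outputs),
    file.path(run_dir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA)
}

#' Run the grading pipeline end to end on a synthetic cohort
#'
#' Stages (in dependency order): `simulate` (synthetic cohorts + clinical
#' table), `mask` (tissue detection), `patch` (labelled patch extraction),
#' `train` (patch classifier), `infer` (whole-spot probability maps),
#' `score` (composite Gleason scores), `evaluate` (agreement statistics
#' against ground truth), `cam` (class activation maps of confident
#' patches), `survival` (risk-group stratification). Each stage writes its
#' outputs plus a `manifest_<stage>.json` (inputs, config hash, seed) into
#' `run_dir`; re-running with identical config and seed reproduces
#' identical outputs. A stage whose inputs are missing fails with an error
#' naming the absent artifact.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of the stage names above.
#' @param run_dir Output directory.
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES,
                         run_dir = tempfile("gleason_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0)
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())

  need <- function(name, loader, artifact) {
    if (!is.null(env[[name]])) return(env[[name]])
    value <- tryCatch(loader(), error = function(e) NULL)
    if (is.null(value))
      abort(sprintf("stage input missing: %s (run the producing stage first)",
                    artifact))
    env[[name]] <- value
    value
  }
  geometry <- config$geometry
  texture <- texture_params(config$spot_size / 3100)

  for (stage in stages) {
    switch(stage,
      simulate = {
        # training uses region-pure spots (patches from within delineated
        # regions); the held-out test cohort carries mixed-score spots
        env$train_cohort <- generate_pattern_cohort(
          config$n_train_spots, spot_size_px = config$spot_size,
          texture = texture, seed = derive_seed(config$seed, 1))
        env$test_cohort <- generate_cohort(
          config$n_test_spots, spot_size_px = config$spot_size,
          texture = texture, seed = derive_seed(config$seed, 2))
        write_cohort(env$train_cohort, file.path(run_dir, "cohort_train"))
        write_cohort(env$test_cohort, file.path(run_dir, "cohort_test"))
        write_manifest(run_dir, stage, config, list(),
                       c("cohort_train", "cohort_test"))
      },
      mask = {
        test <- need("test_cohort",
                     function() read_cohort(file.path(run_dir, "cohort_test")),
                     "cohort_test")
        dir.create(file.path(run_dir, "tissue_masks"), showWarnings = FALSE)
        env$tissue_masks <- lapply(test$spots, function(sp) {
          m <- detect_tissue(sp$image,
                             tissue_mask_params(morph_radius = max(
                               2L, as.integer(10 * config$spot_size / 3100))))
          write_tissue_mask(m, file.path(run_dir, "tissue_masks",
                                         paste0(sp$spot_id, ".png")))
          m
        })
        write_manifest(run_dir, stage, config, "cohort_test", "tissue_masks")
      },
      patch = {
        train <- need("train_cohort",
                      function() read_cohort(file.path(run_dir,
                                                       "cohort_train")),
                      "cohort_train")
        env$patches <- extract_cohort_patches(train, geometry,
                                              pixels = "uint8")
        write_patch_manifest(env$patches, file.path(run_dir, "patches.csv"))
        write_manifest(run_dir, stage, config, "cohort_train", "patches.csv")
      },
      train = {
        patches <- env$patches %||%
          abort("stage input missing: patches (run 'patch' first)")
        model <- build_network(config$network,
                               seed = derive_seed(config$seed, 3))
        tc <- train_config("scratch", iterations = config$iterations,
                           seed = derive_seed(config$seed, 4))
        env$model <- train_classifier(model, patches, tc, geometry)
        save_model(env$model, file.path(run_dir, "model"))
        write_manifest(run_dir, stage, config, "patches.csv", "model")
      },
      infer = {
        model <- need("model",
                      function() load_model(file.path(run_dir, "model")),
                      "model")
        test <- need("test_cohort",
                     function() read_cohort(file.path(run_dir, "cohort_test")),
                     "cohort_test")
        masks <- env$tissue_masks %||%
          abort("stage input missing: tissue_masks (run 'mask' first)")
        ann <- convert_to_fcn(model)
        dir.create(file.path(run_dir, "maps"), showWarnings = FALSE)
        env$maps <- lapply(test$spots, function(sp) {
          pm <- probability_map(ann, sp$image, masks[[sp$spot_id]],
                                scale = training_scale(geometry),
                                spot_id = sp$spot_id)
          saveRDS(pm, file.path(run_dir, "maps",
                                paste0(sp$spot_id, ".rds")))
          jsonlite::write_json(
            list(spot_id = sp$spot_id, model_id = pm$model_id,
                 channels = GLEASON_CLASSES,
                 border_px = attr(pm, "border_px")),
            file.path(run_dir, "maps", paste0(sp$spot_id, ".json")),
            auto_unbox = TRUE, digits = NA)
          pm
        })
        write_manifest(run_dir, stage, config,
                       c("model", "cohort_test", "tissue_masks"), "maps")
      },
      score = {
        maps <- env$maps %||% abort("stage input missing: maps (run 'infer' first)")
        env$scores <- score_cohort(maps, scoring_config(config$threshold))
        write.csv(env$scores, file.path(run_dir, "scores.csv"),
                  row.names = FALSE)
        write_manifest(run_dir, stage, config, "maps", "scores.csv")
      },
      evaluate = {
        scores <- need("scores", function() {
          tibble::as_tibble(read.csv(file.path(run_dir, "scores.csv")))
        }, "scores.csv")
        test <- need("test_cohort",
                     function() read_cohort(file.path(run_dir, "cohort_test")),
                     "cohort_test")
        joined <- dplyr::inner_join(scores, test$clinical, by = "spot_id")
        lev <- c("Benign", "6", "7", "8", "9", "10")
        to_lab <- function(s) ifelse(s == 0, "Benign", as.character(s))
        cm <- confusion_matrix(to_lab(joined$true_score),
                               to_lab(joined$score), lev)
        # kappa is undefined when all spots fall in one category
        kap <- tryCatch(quadratic_kappa(cm$counts),
                        error = function(e) NA_real_)
        env$evaluation <- list(counts = cm$counts, kappa = kap)
        jsonlite::write_json(
          list(level = "spot", classes = lev,
               benign_rank_adjacent_to_6 = TRUE,
               counts = as.vector(t(cm$counts)),
               kappa = kap, macro_recall = macro_recall(cm$counts),
               exact_agreement = mean(joined$true_score == joined$score)),
          file.path(run_dir, "evaluation.json"), auto_unbox = TRUE,
          digits = NA)
        write_manifest(run_dir, stage, config,
                       c("scores.csv", "cohort_test"), "evaluation.json")
      },
      cam = {
        model <- need("model",
                      function() load_model(file.path(run_dir, "model")),
                      "model")
        patches <- env$patches %||%
          abort("stage input missing: patches (run 'patch' first)")
        conf <- select_confident(head(patches, 200), model, geometry)
        dir.create(file.path(run_dir, "cam"), showWarnings = FALSE)
        n_out <- min(4L, nrow(conf))
        for (i in seq_len(n_out)) {
          px <- augment_patch(conf$pixels[[i]], geometry, random = FALSE)
          am <- class_activation_map(model, px,
                                     as.character(conf$label[i]))
          png::writePNG(am$heatmap,
                        file.path(run_dir, "cam",
                                  sprintf("cam_%02d_%s.png", i,
                                          conf$label[i])))
        }
        write_manifest(run_dir, stage, config, c("model", "patches.csv"),
                       "cam")
      },
      survival = {
        scores <- need("scores", function() {
          tibble::as_tibble(read.csv(file.path(run_dir, "scores.csv")))
        }, "scores.csv")
        test <- need("test_cohort",
                     function() read_cohort(file.path(run_dir, "cohort_test")),
                     "cohort_test")
        rep <- stratification_report(scores, test$clinical)
        env$survival <- rep
        jsonlite::write_json(
          list(groups = as.list(setNames(as.integer(rep$group_counts),
                                         names(rep$group_counts))),
               tests = rep$tests),
          file.path(run_dir, "survival.json"), auto_unbox = TRUE,
          digits = NA)
        write_manifest(run_dir, stage, config,
                       c("scores.csv", "cohort_test"), "survival.json")
      })
  }
  invisible(run_dir)
}
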