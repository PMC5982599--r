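## Pipeline orchestration: simulate -> calibrate -> segment -> describe ->
## select -> classify, streaming one lesion at a time so cohorts never
## need to be held in memory at once. Each stage writes its artifacts
## under the run directory and an entry in manifest.json.

PIPELINE_STAGES <- c("simulate", "calibrate", "segment", "describe",
                     "select", "classify")

#' Pipeline run configuration
#'
#' All knobs of [run_pipeline()] in one validated object. Unknown
#' arguments are rejected (R signature matching), so a configuration
#' list can be applied safely with `do.call(run_config, cfg)`.
#'
#' @param out_dir run directory (created).
#' @param n_nevi,n_melanomas cohort composition (default 39 + 14).
#' @param resolution_scale camera-grid scale for the simulation, see
#'   [default_band_sets()].
#' @param phantom base [phantom_config()] template (`NULL`: defaults at
#'   `resolution_scale`).
#' @param jitter,class_profiles,class_texture cohort heterogeneity, see
#'   [cohort_configs()].
#' @param histogram_bins histogram size N for the descriptors.
#' @param entropy_mode,mu3_mode descriptor modes, see [entropy()] and
#'   [third_central_moment()].
#' @param absorbance_order see [make_variants()].
#' @param skin_margin_px guard band around the lesion excluded from the
#'   healthy-skin average, see [skin_region()].
#' @param use_truth_masks use the phantoms' ground-truth masks instead of
#'   Otsu segmentation (diagnostic mode).
#' @param rules rule set for the selection stage: a list of
#'   [threshold_rule()]s, `"default"` for [default_rules()], or `"fitted"`
#'   to calibrate intervals on the cohort with [fit_rules()].
#' @param pc_pairs candidate PC pairs for [select_pc_pair()].
#' @param svm_cost,svm_kernel see [train_svm()].
#' @param seed run seed; drives every random draw.
#' @param stages contiguous subset of
#'   `simulate, calibrate, segment, describe, select, classify`.
#' @param write_images also write per-lesion phantom TIFF stacks and
#'   reflectance variants (large; off by default).
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir,
                       n_nevi = 39, n_melanomas = 14,
                       resolution_scale = 1 / 8,
                       phantom = NULL,
                       jitter = cohort_jitter(),
                       class_profiles = NULL,
                       class_texture = NULL,
                       histogram_bins = 256,
                       entropy_mode = "as_printed",
                       mu3_mode = "as_printed",
                       absorbance_order = "log_first",
                       skin_margin_px = 5,
                       use_truth_masks = FALSE,
                       rules = "default",
                       pc_pairs = list(c(1, 2), c(1, 3), c(2, 3)),
                       svm_cost = 1,
                       svm_kernel = "linear",
                       seed = 1L,
                       stages = PIPELINE_STAGES,
                       write_images = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  pos <- sort(match(stages, PIPELINE_STAGES))
  if (!identical(pos, seq(min(pos), max(pos))))
    stop("stages must be a contiguous run of: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  if (is.null(phantom))
    phantom <- phantom_config(resolution_scale = resolution_scale)
  structure(list(out_dir = out_dir, n_nevi = n_nevi,
                 n_melanomas = n_melanomas,
                 resolution_scale = resolution_scale, phantom = phantom,
                 jitter = jitter, class_profiles = class_profiles,
                 class_texture = class_texture,
                 histogram_bins = histogram_bins,
                 entropy_mode = entropy_mode, mu3_mode = mu3_mode,
                 absorbance_order = absorbance_order,
                 skin_margin_px = skin_margin_px,
                 use_truth_masks = use_truth_masks, rules = rules,
                 pc_pairs = pc_pairs, svm_cost = svm_cost,
                 svm_kernel = svm_kernel, seed = as.integer(seed),
                 stages = PIPELINE_STAGES[min(pos):max(pos)],
                 write_images = write_images),
            class = "run_config")
}

resolve_rules <- function(cfg, table = NULL) {
  if (is.list(cfg$rules)) return(cfg$rules)
  if (identical(cfg$rules, "default")) return(default_rules())
  if (identical(cfg$rules, "fitted")) {
    if (is.null(table)) stop("fitted rules need a descriptor table")
    return(fit_rules(table, vapply(default_rules(), `[[`, "", "descriptor")))
  }
  stop("rules must be a list of threshold_rule, \"default\" or \"fitted\"")
}

## calibrate + segment + describe for one phantom; returns the pieces the
## per-stage reports need
process_lesion <- function(phantom, cfg) {
  stacks <- list(); masks <- list(); variants <- list()
  expo <- list(); dice_truth <- c()
  for (sid in names(phantom$captures))
    stacks[[sid]] <- compute_reflectance(phantom$captures[[sid]],
                                         phantom$calibrations[[sid]])
  seg_in_stages <- "segment" %in% cfg$stages
  if (seg_in_stages || "describe" %in% cfg$stages) {
    if (cfg$use_truth_masks) {
      masks <- phantom$truth_mask
    } else {
      vis_mask <- segment_quadrants(stacks$VISNIR$images[["414"]])
      masks$VISNIR <- vis_mask
      if (!is.null(phantom$truth_transform))
        masks$EXNIR <- transfer_mask(vis_mask, phantom$truth_transform)
    }
    for (sid in names(masks))
      if (!is.null(phantom$truth_mask[[sid]]))
        dice_truth[sid] <- dice(masks[[sid]], phantom$truth_mask[[sid]])
  }
  row <- NULL
  if ("describe" %in% cfg$stages) {
    scale_ratio <- if (!is.null(phantom$truth_transform))
      phantom$truth_transform$scale else 1
    for (sid in names(stacks)) {
      margin <- if (sid == "EXNIR")
        max(1, round(cfg$skin_margin_px * scale_ratio))
      else cfg$skin_margin_px
      variants[[sid]] <- make_variants(stacks[[sid]], masks[[sid]],
                                       skin_region(masks[[sid]], margin),
                                       cfg$absorbance_order)
    }
    row <- lesion_descriptors(variants, masks, cfg$histogram_bins,
                              cfg$entropy_mode, cfg$mu3_mode)
  }
  for (sid in names(phantom$captures))
    expo[[sid]] <- as.list(phantom$captures[[sid]]$exposure_index)
  list(row = row, masks = masks, stacks = stacks, variants = variants,
       dice = dice_truth, exposure_index = expo)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order over a synthetic cohort,
#' streaming one lesion at a time. Artifacts per stage:
#' `cohort_manifest.csv` and (with `write_images`) phantom TIFF stacks
#' (simulate); `calibration_report.json` (calibrate);
#' `segmentation_report.json` plus mask PNGs (segment);
#' `descriptors.csv` (describe); `selection.json` (select);
#' `classification_report.json`, `pc_scores.csv` and a PC scatter PNG
#' (classify). A `manifest.json` lists every file written with its MD5.
#' Runs whose first enabled stage is `select` or `classify` read
#' `descriptors.csv` from an earlier run in the same directory.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the run directory, the descriptor
#'   table (if computed), the selection result and the classification
#'   outcome.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  t_all <- proc.time()[3]
  note <- function(stage, files, t0) {
    files <- files[file.exists(files)]
    manifest[[length(manifest) + 1]] <<- list(
      stage = stage,
      files = as.list(basename(files)),
      md5 = as.list(unname(tools::md5sum(files))),
      seed = cfg$seed,
      elapsed_s = round(proc.time()[3] - t0, 2))
  }

  table <- NULL; selection <- NULL; classification <- NULL
  front <- intersect(cfg$stages, c("simulate", "calibrate", "segment",
                                   "describe"))
  if (length(front) > 0) {
    if (front[1] != "simulate")
      stop("missing upstream artifact: run the simulate stage first ",
           "(in-memory streaming starts there)")
    t0 <- proc.time()[3]
    configs <- cohort_configs(cfg$n_nevi, cfg$n_melanomas,
                              base_config = cfg$phantom, seed = cfg$seed,
                              jitter = cfg$jitter,
                              class_profiles = cfg$class_profiles,
                              class_texture = cfg$class_texture)
    classes <- vapply(configs, `[[`, "", "lesion_class")
    man <- data.frame(id = names(configs), class = classes,
                      seed = vapply(configs, `[[`, 0L, "seed"),
                      row.names = NULL)
    utils::write.csv(man, file.path(cfg$out_dir, "cohort_manifest.csv"),
                     row.names = FALSE)

    rows <- list(); cal_report <- list(); seg_report <- list()
    for (id in names(configs)) {
      ph <- generate_phantom(configs[[id]])
      if (cfg$write_images)
        write_phantom(ph, file.path(cfg$out_dir, "phantoms", id))
      if (length(front) == 1) next  # simulate only
      res <- process_lesion(ph, cfg)
      cal_report[[id]] <- res$exposure_index
      if (length(res$dice) > 0)
        seg_report[[id]] <- as.list(round(res$dice, 4))
      if (cfg$write_images && "segment" %in% cfg$stages)
        for (sid in names(res$masks))
          write_mask_png(res$masks[[sid]],
                         file.path(cfg$out_dir, "phantoms", id,
                                   paste0("mask_", sid, ".png")))
      if (!is.null(res$row)) rows[[id]] <- res$row
    }
    note("simulate", file.path(cfg$out_dir, "cohort_manifest.csv"), t0)
    if ("calibrate" %in% cfg$stages) {
      t0 <- proc.time()[3]
      jsonlite::write_json(cal_report,
                           file.path(cfg$out_dir, "calibration_report.json"),
                           auto_unbox = TRUE, digits = NA)
      note("calibrate", file.path(cfg$out_dir, "calibration_report.json"), t0)
    }
    if ("segment" %in% cfg$stages) {
      t0 <- proc.time()[3]
      jsonlite::write_json(seg_report,
                           file.path(cfg$out_dir, "segmentation_report.json"),
                           auto_unbox = TRUE, digits = NA)
      note("segment", file.path(cfg$out_dir, "segmentation_report.json"), t0)
    }
    if ("describe" %in% cfg$stages) {
      t0 <- proc.time()[3]
      lesions <- lapply(names(rows), function(id)
        list(class = classes[[id]]))
      names(lesions) <- names(rows)
      mat <- do.call(rbind, rows)
      table <- data.frame(id = names(rows),
                          class = unname(classes[names(rows)]), mat,
                          check.names = FALSE, row.names = NULL)
      write_descriptor_table(table, file.path(cfg$out_dir, "descriptors.csv"))
      note("describe", file.path(cfg$out_dir, "descriptors.csv"), t0)
    }
  }

  if (any(c("select", "classify") %in% cfg$stages) && is.null(table)) {
    path <- file.path(cfg$out_dir, "descriptors.csv")
    if (!file.exists(path))
      stop("missing upstream artifact descriptors.csv: ",
           "run the describe stage first")
    table <- read_descriptor_table(path)
  }

  rules <- NULL
  if ("select" %in% cfg$stages) {
    t0 <- proc.time()[3]
    rules <- resolve_rules(cfg, table)
    ranked <- rank_rules(table, rules)
    selection <- greedy_select(table, ranked)
    rule_calls <- classify_by_rules(table, selection$selected)
    sel_json <- list(
      rules = lapply(ranked, function(r)
        list(descriptor = r$descriptor, upper = r$upper, lower = r$lower)),
      melanomas_caught = as.list(attr(ranked, "melanomas_caught")),
      selected = vapply(selection$selected, `[[`, "", "descriptor"),
      cumulative_sensitivity = selection$cumulative_sensitivity,
      rule_sensitivity =
        mean(rule_calls[table$class == "melanoma"] == "malignant"),
      rule_specificity =
        mean(rule_calls[table$class == "nevus"] == "benign"))
    jsonlite::write_json(sel_json, file.path(cfg$out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
    note("select", file.path(cfg$out_dir, "selection.json"), t0)
  }

  if ("classify" %in% cfg$stages) {
    t0 <- proc.time()[3]
    if (is.null(rules)) rules <- resolve_rules(cfg, table)
    descriptors <- vapply(rules, `[[`, "", "descriptor")
    std <- standardize(table, descriptors)
    model <- pca_svd(std)
    best <- select_pc_pair(model, pairs = cfg$pc_pairs, cost = cfg$svm_cost,
                           kernel = cfg$svm_kernel)
    sc <- data.frame(id = table$id, class = table$class,
                     sapply(seq_len(min(3, length(model$d))),
                            function(k) pc_scores(model, k)))
    names(sc)[-(1:2)] <- paste0("PC", seq_len(ncol(sc) - 2))
    utils::write.csv(sc, file.path(cfg$out_dir, "pc_scores.csv"),
                     row.names = FALSE)
    rep_json <- list(
      pc_pair = best$pair,
      confusion = best$report[c("TP", "FN", "TN", "FP")],
      sensitivity_pct = best$report$sensitivity_pct,
      specificity_pct = best$report$specificity_pct,
      explained_variance = model$explained_variance,
      all_pairs = lapply(best$all_reports, function(r)
        list(sensitivity_pct = r$sensitivity_pct,
             specificity_pct = r$specificity_pct)))
    jsonlite::write_json(rep_json,
                         file.path(cfg$out_dir, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA)
    plot_path <- file.path(cfg$out_dir, "pc_scatter.png")
    plot_pc_boundary(best, table$class, plot_path)
    classification <- list(pair = best$pair, report = best$report,
                           model = model, boundary = best$boundary,
                           scores = best$scores)
    note("classify", c(file.path(cfg$out_dir, "pc_scores.csv"),
                       file.path(cfg$out_dir, "classification_report.json"),
                       plot_path), t0)
  }

  manifest[[length(manifest) + 1]] <- list(
    stage = "run", files = list(), md5 = list(), seed = cfg$seed,
    elapsed_s = round(proc.time()[3] - t_all, 2))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = cfg$out_dir, table = table,
                 selection = selection, classification = classification))
}

## PC-pair scatter with the SVM decision boundary as a contour at 0
plot_pc_boundary <- function(best, classes, path) {
  grDevices::png(path, width = 900, height = 750, res = 120)
  on.exit(grDevices::dev.off())
  sc <- best$scores
  cols <- ifelse(classes == "melanoma", "darkorange2", "forestgreen")
  graphics::plot(sc[, 1], sc[, 2], col = cols, pch = 19,
                 xlab = colnames(sc)[1], ylab = colnames(sc)[2],
                 main = "PC scores with SVM decision boundary")
  gx <- seq(min(sc[, 1]), max(sc[, 1]), length.out = 120)
  gy <- seq(min(sc[, 2]), max(sc[, 2]), length.out = 120)
  grid <- as.matrix(expand.grid(gx, gy))
  colnames(grid) <- colnames(sc)
  dv <- matrix(decision_values(best$boundary, grid), length(gx))
  graphics::contour(gx, gy, dv, levels = 0, add = TRUE, lwd = 2,
                    drawlabels = FALSE)
  graphics::legend("topright", legend = c("melanoma", "nevus"),
                   col = c("darkorange2", "forestgreen"), pch = 19)
}
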