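#' Preprocess one ROI: resample, re-rasterize, mask
#'
#' Resamples the image to the target spacing, maps the polygon onto the
#' resampled grid (polygons are re-rasterized, never interpolated as
#' masks), and rasterizes it. Raw intensities are resampled first;
#' normalization and quantization happen inside feature extraction on
#' the resampled grid, so the +/-3 sigma window is always consistent
#' with the analyzed pixels.
#'
#' @param img a [gray_image()].
#' @param poly a [roi_polygon()] drawn on `img`'s native grid.
#' @param target target spacing in mm (default 0.390625).
#' @return List with `img` (resampled) and `mask`.
#' @export
preprocess_roi <- function(img, poly, target = 0.390625) {
  out <- resample_to_spacing(img, target)
  poly2 <- rescale_polygon(poly, img$spacing_row, img$spacing_col, target)
  list(img = out, mask = rasterize_roi(poly2, dim(out$pixels)))
}

#' Feature table of a cohort for one reading
#'
#' Runs preprocessing and panel extraction for every subject with the
#' chosen segmentation reading, over one or both sequences.
#'
#' @param cohort a rendered `synthetic_cohort`.
#' @param reading `"r1r1"`, `"r1r2"` or `"r2r1"`.
#' @param registry feature registry.
#' @param target target spacing (mm).
#' @param sequences subset of `c("T2w", "LGE")`.
#' @return Numeric matrix `subjects x features`, rownames = subject ids,
#'   colnames = `<sequence>.<canonical name>`.
#' @export
cohort_features <- function(cohort, reading = "r1r1",
                            registry = default_registry(),
                            target = 0.390625,
                            sequences = c("T2w", "LGE")) {
  stopifnot(!is.null(cohort$imaging), reading %in% c("r1r1", "r1r2", "r2r1"))
  rows <- lapply(cohort$subjects$id, function(id) {
    sub <- cohort$imaging[[id]]
    out <- numeric(0)
    if ("T2w" %in% sequences) {
      pp <- preprocess_roi(sub$t2w, sub$rois$T2w[[reading]], target)
      f <- extract_features(pp$img, pp$mask, registry)
      names(f) <- paste0("T2w.", names(f))
      out <- c(out, f)
    }
    if ("LGE" %in% sequences) {
      pp <- preprocess_roi(sub$lge, sub$rois$LGE[[reading]], target)
      f <- extract_features(pp$img, pp$mask, registry)
      names(f) <- paste0("LGE.", names(f))
      out <- c(out, f)
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- cohort$subjects$id
  tab
}

#' Pipeline run configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param cohort a [cohort_spec()] for the simulate stage.
#' @param target_spacing resampling target in mm.
#' @param icc_threshold reliability exclusion threshold (`ICC <=`
#'   drops).
#' @param r_threshold redundancy threshold (`|r| >` drops).
#' @param classifiers classifier names to evaluate.
#' @param k cross-validation folds.
#' @param n_replicates seed replicates behind the confidence intervals.
#' @param include_clinical append age, sex and BMI to the feature table
#'   before selection.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, cohort = cohort_spec(),
                       target_spacing = 0.390625,
                       icc_threshold = 0.6, r_threshold = 0.8,
                       classifiers = c("ANN-MLP", "J48", "NaiveBayes",
                                       "RandomForest", "SMO"),
                       k = 10, n_replicates = 10,
                       include_clinical = TRUE) {
  cfg <- as.list(environment())
  stopifnot(icc_threshold >= 0, icc_threshold <= 1,
            r_threshold >= 0, r_threshold <= 1, target_spacing > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' simulate -> preprocess/extract (three readings, two sequences) ->
#' reliability + redundancy selection -> replicated cross-validated
#' evaluation of every configured classifier (both metric orientations)
#' with Hanley-McNeil comparisons of each classifier against the
#' top-AUC one. All tabular outputs are written to `out_dir` as CSV,
#' the manifest as JSON; a rerun with the same config reproduces them
#' byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @param cohort optionally, a pre-generated rendered cohort (the
#'   simulate stage is then skipped).
#' @return A `pipeline_run` list: `config`, `features` (list of the
#'   three reading tables), `report` (reliability report), `kept`,
#'   `metrics`, `comparisons`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort,
                              seed = derive_seed(config$seed, "simulate"))
  }
  registry <- default_registry()
  feats <- lapply(c(r1r1 = "r1r1", r1r2 = "r1r2", r2r1 = "r2r1"),
                  function(rd) {
                    cohort_features(cohort, rd, registry,
                                    target = config$target_spacing)
                  })
  if (config$include_clinical) {
    clin <- as.matrix(cohort$subjects[, c("age", "sex", "bmi")])
    colnames(clin) <- c("Clin.Age", "Clin.Sex", "Clin.BMI")
    feats <- lapply(feats, cbind, clin)
  }
  # features with any missing value (unrealizable descriptors) are
  # dropped before selection
  ok <- Reduce(`&`, lapply(feats, function(m) colSums(is.na(m)) == 0))
  feats <- lapply(feats, function(m) m[, ok, drop = FALSE])
  report <- reliability_filter(feats$r1r1, feats$r1r2, feats$r2r1,
                               threshold = config$icc_threshold)
  report <- redundancy_prune(feats$r1r1, report,
                             r_threshold = config$r_threshold)
  kept <- kept_features(report)
  metrics <- NULL
  comparisons <- NULL
  if (length(kept) == 0) {
    message("no features survive selection; evaluation skipped")
  } else {
    x <- feats$r1r1[, kept, drop = FALSE]
    y <- cohort$subjects$macce
    metrics <- do.call(rbind, lapply(config$classifiers, function(cl) {
      m <- cv_replicates(x, y, classifier_spec(cl), k = config$k,
                         seed = derive_seed(config$seed, "evaluate", cl),
                         seeds = vapply(seq_len(config$n_replicates),
                                        function(i) derive_seed(config$seed,
                                                                "evaluate",
                                                                cl, i),
                                        integer(1)))
      cbind(classifier = cl, m)
    }))
    comparisons <- auc_comparisons(metrics, x, y, config)
  }
  run <- structure(list(config = config, cohort_subjects = cohort$subjects,
                        features = feats, report = report, kept = kept,
                        metrics = metrics, comparisons = comparisons,
                        out_dir = out_dir),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Hanley-McNeil comparison of each classifier against the top pooled
# AUC classifier (positive class 1), with the correlation term
# estimated from paired pooled scores of one shared seed.
auc_comparisons <- function(metrics, x, y, config) {
  auc1 <- metrics[metrics$metric == "auc" & metrics$positive_class == 1, ]
  if (nrow(auc1) < 2) return(NULL)
  best <- auc1$classifier[which.max(auc1$mean)]
  shared_seed <- derive_seed(config$seed, "compare")
  score_of <- function(cl) {
    run_crossval(x, y, classifier_spec(cl), k = config$k,
                 seed = shared_seed)$scores
  }
  s_best <- score_of(best)
  others <- setdiff(auc1$classifier, best)
  rows <- lapply(others, function(cl) {
    s <- score_of(cl)
    r <- estimate_r_hm(s_best, s, y)
    hm <- hanley_mcneil(auc1$mean[auc1$classifier == best],
                        n_pos = sum(y == 1), n_neg = sum(y == 0),
                        a2 = auc1$mean[auc1$classifier == cl], r_hm = r)
    data.frame(best = best, other = cl, auc_best = hm$a1, auc_other = hm$a2,
               r_hm = r, z = hm$z, p = hm$p)
  })
  do.call(rbind, rows)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (rd in names(run$features)) {
    utils::write.csv(run$features[[rd]],
                     file.path(out_dir, paste0("features_", rd, ".csv")))
  }
  write_reliability_report(run$report,
                           file.path(out_dir, "reliability_report.csv"))
  writeLines(run$kept, file.path(out_dir, "kept_features.txt"))
  if (!is.null(run$metrics)) {
    utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$comparisons)) {
    utils::write.csv(run$comparisons,
                     file.path(out_dir, "auc_comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(config = serialize_config(run$config)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Serialize / parse a run configuration
#'
#' Round-trips losslessly through JSON so a manifest replays the run.
#'
#' @param config a [run_config()].
#' @return For `serialize_config`, a plain list; for `parse_config`, a
#'   `run_config`.
#' @export
serialize_config <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out
}

#' @rdname serialize_config
#' @param lst a list as produced by `serialize_config` (e.g. parsed from
#'   a manifest).
#' @export
parse_config <- function(lst) {
  cohort <- do.call(cohort_spec, lst$cohort)
  lst$cohort <- cohort
  do.call(run_config, lst)
}

#' Human-readable run summary
#'
#' Summarizes a completed [run_pipeline()] result: selection outcome
#' with ICC bands, per-classifier metrics in both orientations, and the
#' Hanley-McNeil comparisons; flags a null-compatible AUC when the best
#' classifier's interval covers 0.5.
#'
#' @param run a `pipeline_run`.
#' @param file optional path; default prints to the console.
#' @return The summary lines, invisibly.
#' @export
write_report <- function(run, file = "") {
  stopifnot(inherits(run, "pipeline_run"))
  rep <- run$report
  lines <- c(
    "== Texture pipeline run ==",
    sprintf("subjects: %d (%d events)", nrow(run$cohort_subjects),
            sum(run$cohort_subjects$macce)),
    sprintf("features entering selection: %d", nrow(rep)),
    sprintf("dropped by reliability (ICC <= %.2f): %d",
            run$config$icc_threshold, sum(rep$verdict == "drop_icc")),
    sprintf("dropped as redundant (|r| > %.2f): %d",
            run$config$r_threshold, sum(rep$verdict == "drop_redundant")),
    sprintf("kept: %d", length(run$kept)),
    "")
  if (length(run$kept)) {
    kr <- rep[rep$verdict == "keep", ]
    lines <- c(lines, "kept features (inter/intra ICC, band):",
               sprintf("  %-28s %.3f / %.3f  %s", kr$feature, kr$icc_inter,
                       kr$icc_intra, kr$band), "")
  }
  if (!is.null(run$metrics)) {
    for (cl in unique(run$metrics$classifier)) {
      for (pc in c(1, 0)) {
        m <- run$metrics[run$metrics$classifier == cl &
                           run$metrics$positive_class == pc, ]
        lines <- c(lines, sprintf("%s (positive class = %d):", cl, pc),
                   sprintf("  %-12s %.3f [%.3f-%.3f]", m$metric, m$mean,
                           m$lo, m$hi))
      }
      lines <- c(lines, "")
    }
    auc1 <- run$metrics[run$metrics$metric == "auc" &
                          run$metrics$positive_class == 1, ]
    best <- auc1[which.max(auc1$mean), ]
    if (best$lo <= 0.5 && best$hi >= 0.5) {
      lines <- c(lines,
                 "NOTE: best AUC interval covers 0.5 (null-compatible).", "")
    }
  } else {
    lines <- c(lines, "no features survive selection; no evaluation run.", "")
  }
  if (!is.null(run$comparisons)) {
    lines <- c(lines, "AUC comparisons (Hanley-McNeil) vs best classifier:",
               sprintf("  %s vs %s: AUC %.3f vs %.3f, z = %.2f, p = %.4f",
                       run$comparisons$best, run$comparisons$other,
                       run$comparisons$auc_best, run$comparisons$auc_other,
                       run$comparisons$z, run$comparisons$p))
  }
  writeLines(lines, file)
  invisible(lines)
}
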