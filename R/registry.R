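#' The default texture feature registry
#'
#' Enumerates the shipped per-ROI feature panel: 4 histogram features;
#' 11 co-occurrence features for each of 4 directions (0, 45, 90, 135
#' degrees) x 5 inter-pixel distances (220); 5 run-length features for
#' each of 4 angles (20); 5 absolute-gradient features; 5 autoregressive
#' features; and 4 Haar sub-band energies at each of 7 scales (28) --
#' 282 descriptors in total. The registry is data-driven: alternative
#' panels can be loaded with [read_registry()] and the panel size is a
#' property of the registry, not of the engine.
#'
#' @param glcm_distances inter-pixel distances for the co-occurrence
#'   family.
#' @param angles directions/angles (degrees) for the co-occurrence and
#'   run-length families.
#' @param wavelet_scales scales for the Haar energies.
#' @return A data frame with columns `family`, `distance`, `angle`,
#'   `scale`, `feature`, `name` (canonical, unique).
#' @export
default_registry <- function(glcm_distances = 1:5,
                             angles = c(0, 45, 90, 135),
                             wavelet_scales = 1:7) {
  rows <- list()
  hist_f <- c("Mean", "Variance", "Skewness", "Kurtosis")
  rows$hist <- data.frame(family = "histogram", distance = NA, angle = NA,
                          scale = NA, feature = hist_f,
                          name = paste0("Hist.", hist_f))
  glcm_f <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
              "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
              "DifEntrp")
  g <- expand.grid(feature = glcm_f, angle = angles,
                   distance = glcm_distances, stringsAsFactors = FALSE)
  rows$glcm <- data.frame(family = "glcm", distance = g$distance,
                          angle = g$angle, scale = NA, feature = g$feature,
                          name = sprintf("GLCM.d%d.a%d.%s", g$distance,
                                         g$angle, g$feature))
  rlm_f <- c("RLNonUni", "GLevNonU", "LngREmph", "ShrtREmp", "Fraction")
  r <- expand.grid(feature = rlm_f, angle = angles, stringsAsFactors = FALSE)
  rows$rlm <- data.frame(family = "rlm", distance = NA, angle = r$angle,
                         scale = NA, feature = r$feature,
                         name = sprintf("RLM.a%d.%s", r$angle, r$feature))
  grad_f <- c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")
  rows$grad <- data.frame(family = "gradient", distance = NA, angle = NA,
                          scale = NA, feature = grad_f,
                          name = paste0("Grad.", grad_f))
  ar_f <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  rows$ar <- data.frame(family = "ar", distance = NA, angle = NA, scale = NA,
                        feature = ar_f, name = paste0("AR.", ar_f))
  wv <- expand.grid(feature = c("LL", "LH", "HL", "HH"),
                    scale = wavelet_scales, stringsAsFactors = FALSE)
  rows$wav <- data.frame(family = "wavelet", distance = NA, angle = NA,
                         scale = wv$scale, feature = wv$feature,
                         name = sprintf("WavEn%s.s%d", wv$feature, wv$scale))
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  validate_registry(reg)
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$name)) {
    stop("duplicate canonical feature names in registry: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  }
  reg
}

#' Read / write a feature registry file
#'
#' One descriptor per line: `family;param=value;...;name`, e.g.
#' `glcm;distance=4;angle=135;feature=DifVarnc;GLCM.d4.a135.DifVarnc`.
#'
#' @param path registry file path.
#' @return A registry data frame (see [default_registry()]).
#' @export
read_registry <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ";", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed registry line: ", ln)
    fam <- parts[1]
    nm <- parts[length(parts)]
    kv <- parts[-c(1, length(parts))]
    out <- list(family = fam, distance = NA_real_, angle = NA_real_,
                scale = NA_real_, feature = NA_character_, name = nm)
    for (p in kv) {
      eq <- strsplit(p, "=", fixed = TRUE)[[1]]
      if (length(eq) != 2) stop("malformed registry parameter: ", p)
      key <- eq[1]
      out[[key]] <- if (key == "feature") eq[2] else as.numeric(eq[2])
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  validate_registry(do.call(rbind, rows))
}

#' @rdname read_registry
#' @param reg a registry data frame.
#' @export
write_registry <- function(reg, path) {
  fmt <- function(row) {
    kv <- character(0)
    for (key in c("distance", "angle", "scale")) {
      if (!is.na(row[[key]])) kv <- c(kv, sprintf("%s=%g", key, row[[key]]))
    }
    if (!is.na(row$feature)) kv <- c(kv, paste0("feature=", row$feature))
    paste(c(row$family, kv, row$name), collapse = ";")
  }
  writeLines(vapply(seq_len(nrow(reg)), function(i) fmt(reg[i, ]),
                    character(1)), path)
  invisible(path)
}

#' Extract the full texture panel for one ROI
#'
#' Preprocesses the masked image (6-bit and 4-bit +/-3 sigma
#' quantization) and evaluates every descriptor of the registry in
#' registry order. Families are computed in blocks (one co-occurrence
#' matrix per distance x direction, one run table per angle) and the
#' registry indexes into the block results, so the cost is independent
#' of how many descriptors reference a block. Unrealizable descriptors
#' (wavelet scales beyond the window; too-small ROI for the
#' autoregressive fit) are `NA`, never imputed.
#'
#' @param img a preprocessed [gray_image()] (already resampled).
#' @param mask logical ROI mask congruent with `img`.
#' @param registry a registry data frame (default [default_registry()]).
#' @return Named numeric vector, one value per registry row, in registry
#'   order.
#' @export
extract_features <- function(img, mask, registry = default_registry()) {
  validate_registry(registry)
  out <- rep(NA_real_, nrow(registry))
  names(out) <- registry$name
  cr <- crop_to_mask(img, mask)
  img <- cr$img; mask <- cr$mask
  fams <- unique(registry$family)
  q6 <- if (any(fams %in% c("glcm", "rlm", "ar"))) {
    normalize_and_quantize(img, mask, bits = 6)
  }
  if ("histogram" %in% fams) {
    hv <- histogram_features(img, mask)
    sel <- registry$family == "histogram"
    out[sel] <- hv[registry$feature[sel]]
  }
  if ("glcm" %in% fams) {
    sel <- which(registry$family == "glcm")
    combos <- unique(registry[sel, c("distance", "angle")])
    for (i in seq_len(nrow(combos))) {
      d <- combos$distance[i]; a <- combos$angle[i]
      fv <- glcm_features(build_cooccurrence(
        q6, d, angle_offsets()[[as.character(a)]]))
      rows <- sel[registry$distance[sel] == d & registry$angle[sel] == a]
      out[rows] <- fv[registry$feature[rows]]
    }
  }
  if ("rlm" %in% fams) {
    sel <- which(registry$family == "rlm")
    for (a in unique(registry$angle[sel])) {
      fv <- rlm_features(build_run_table(q6, a))
      rows <- sel[registry$angle[sel] == a]
      out[rows] <- fv[registry$feature[rows]]
    }
  }
  if ("gradient" %in% fams) {
    q4 <- normalize_and_quantize(img, mask, bits = 4)
    fv <- gradient_features(q4)
    sel <- registry$family == "gradient"
    out[sel] <- fv[registry$feature[sel]]
  }
  if ("ar" %in% fams) {
    fv <- tryCatch(ar_features(q6), error = function(e) {
      warning("autoregressive features unavailable: ", conditionMessage(e))
      c(Teta1 = NA_real_, Teta2 = NA_real_, Teta3 = NA_real_,
        Teta4 = NA_real_, Sigma = NA_real_)
    })
    sel <- registry$family == "ar"
    out[sel] <- fv[registry$feature[sel]]
  }
  if ("wavelet" %in% fams) {
    sel <- which(registry$family == "wavelet")
    fv <- wavelet_features(img, mask, scales = seq_len(max(registry$scale[sel])))
    nm <- sprintf("WavEn%s.s%d", registry$feature[sel], registry$scale[sel])
    out[sel] <- fv[nm]
  }
  out
}

# Crop an image/mask pair to the mask bounding box. All panel families
# only consume in-mask pixels (or, for the wavelet window, pixels inside
# the bounding box), so cropping changes no feature value; box sides are
# rounded up to multiples of 16 to bound the number of distinct grid
# shapes the scan-line cache sees.
crop_to_mask <- function(img, mask) {
  w <- which(mask, arr.ind = TRUE)
  r0 <- min(w[, 1]); r1 <- max(w[, 1])
  c0 <- min(w[, 2]); c1 <- max(w[, 2])
  r1 <- min(r0 + ceiling((r1 - r0 + 1) / 16) * 16 - 1, nrow(mask))
  c1 <- min(c0 + ceiling((c1 - c0 + 1) / 16) * 16 - 1, ncol(mask))
  list(img = gray_image(img$pixels[r0:r1, c0:c1],
                        img$spacing_row, img$spacing_col),
       mask = mask[r0:r1, c0:c1, drop = FALSE])
}

#' Extract the panel for a paired T2w/LGE ROI
#'
#' Runs [extract_features()] on each sequence and prefixes the canonical
#' names with the sequence tag, mirroring the two-sequence per-subject
#' design.
#'
#' @param img_t2w,mask_t2w,img_lge,mask_lge preprocessed image/mask pairs.
#' @param registry a registry data frame.
#' @return Named numeric vector of length `2 * nrow(registry)` with
#'   names `T2w.<name>` then `LGE.<name>`.
#' @export
extract_panel <- function(img_t2w, mask_t2w, img_lge, mask_lge,
                          registry = default_registry()) {
  t2 <- extract_features(img_t2w, mask_t2w, registry)
  lg <- extract_features(img_lge, mask_lge, registry)
  names(t2) <- paste0("T2w.", names(t2))
  names(lg) <- paste0("LGE.", names(lg))
  c(t2, lg)
}
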