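#' Synthetic cohort specification
#'
#' Parameters of the fully synthetic imaging cohort emulating a
#' 58-subject takotsubo study population: paired T2w-like and LGE-like
#' short-axis images with an elliptical myocardial ring, three reader
#' segmentations per subject, demographics, and a fixed number of MACCE
#' events. The outcome-linked texture effect (a shift in random-field
#' correlation length and variance) is injected only into the T2w-like
#' images of event subjects; re-segmentation instability is induced on
#' the LGE-like images through a high-frequency granular field whose
#' statistics are hypersensitive to region-boundary perturbation.
#'
#' @param n_subjects cohort size (58).
#' @param n_events number of MACCE = 1 subjects, fixed per cohort (6,
#'   i.e. a 10.3\% event rate).
#' @param n_female number of female subjects (56, 96.6\%).
#' @param age_mean,age_sd age distribution in years (68.4, 11.8),
#'   clipped to `[30, 95]`.
#' @param bmi_mean,bmi_sd BMI distribution in kg/m^2 (24.4, 4.3),
#'   clipped to `[14, 45]`.
#' @param image_size image side in pixels (256).
#' @param spacing pixel spacing in mm (0.390625).
#' @param outer_radius,ring_thickness ranges (pixels) for the elliptical
#'   myocardial ring.
#' @param t2w_ell correlation length (pixels) of the T2w-like in-ring
#'   Gaussian random field.
#' @param t2w_field_sd standard deviation of that field.
#' @param t2w_noise_sd white-noise SD added to T2w-like in-ring pixels.
#' @param effect_dell,effect_dsd texture effect for event subjects:
#'   added to `t2w_ell` and `t2w_field_sd` respectively. Zero for a null
#'   cohort.
#' @param lge_ell correlation length of the LGE-like granular field
#'   (small: high-frequency).
#' @param lge_granularity amplitude (SD) of the LGE-like granular field;
#'   drives re-segmentation instability of LGE features.
#' @param roi_jitter radial vertex perturbation SD (pixels) applied to
#'   the repeat and second-reader segmentations of the T2w-like image.
#' @param lge_roi_jitter perturbation SD (pixels) for re-segmentations
#'   of the LGE-like image; larger, because the granular low-contrast
#'   LGE appearance gives readers a far less reproducible boundary.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 58, n_events = 6, n_female = 56,
                        age_mean = 68.4, age_sd = 11.8,
                        bmi_mean = 24.4, bmi_sd = 4.3,
                        image_size = 256, spacing = 0.390625,
                        outer_radius = c(55, 70),
                        ring_thickness = c(18, 26),
                        t2w_ell = 3, t2w_field_sd = 60, t2w_noise_sd = 10,
                        effect_dell = 4, effect_dsd = 50,
                        lge_ell = 0.8, lge_granularity = 120,
                        roi_jitter = 1.5, lge_roi_jitter = 5) {
  spec <- as.list(environment())
  stopifnot(n_events >= 0, n_events <= n_subjects,
            n_female >= 0, n_female <= n_subjects,
            age_sd >= 0, bmi_sd >= 0, t2w_ell > 0, lge_ell > 0,
            t2w_noise_sd >= 0, lge_granularity >= 0, roi_jitter >= 0,
            lge_roi_jitter >= 0,
            image_size >= 32, spacing > 0)
  if (outer_radius[2] + 8 > image_size / 2) stop("ring does not fit image")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic cohort
#'
#' Draws covariates and labels (event and female counts are exact by
#' construction; ages and BMIs are clipped normal draws) and renders the
#' per-subject images and segmentations. Identical `(spec, seed)` yield
#' a bit-identical cohort; covariates do not depend on whether images
#' are rendered.
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed for the cohort.
#' @param render if `FALSE`, skip image rendering (covariates and labels
#'   only), e.g. for demographic calibration.
#' @return A `synthetic_cohort`: list with `spec`, `seed`, `subjects` (a
#'   data frame: `id`, `age`, `sex` (1 = female), `bmi`, `macce`), and
#'   unless `render = FALSE` a list `imaging` of per-subject lists
#'   holding `t2w`, `lge` ([gray_image()]s) and `rois`: per sequence
#'   (`T2w`, `LGE`), the three [roi_polygon()]s `r1r1`, `r1r2`, `r2r1`
#'   (reader 1 read 1, reader 1 read 2, reader 2) -- segmentations are
#'   drawn per image, so each sequence has its own reading set.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  subjects <- with_seed(derive_seed(seed, "covariates"), {
    age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd), 30), 95)
    bmi <- pmin(pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), 14), 45)
    sex <- integer(n); sex[sample.int(n, spec$n_female)] <- 1L
    macce <- integer(n); macce[sample.int(n, spec$n_events)] <- 1L
    data.frame(id = sprintf("S%03d", seq_len(n)), age = age, sex = sex,
               bmi = bmi, macce = macce, stringsAsFactors = FALSE)
  })
  imaging <- NULL
  if (render) {
    imaging <- lapply(seq_len(n), function(i) {
      render_subject(spec, event = subjects$macce[i] == 1,
                     seed = derive_seed(seed, "subject", i))
    })
    names(imaging) <- subjects$id
  }
  structure(list(spec = spec, seed = seed, subjects = subjects,
                 imaging = imaging),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d events, %s\n",
              nrow(x$subjects), sum(x$subjects$macce),
              if (is.null(x$imaging)) "not rendered" else "rendered"))
  invisible(x)
}

#' Render one synthetic subject
#'
#' The myocardium is an elliptical annulus with randomized center, radii
#' and orientation. In-ring T2w-like intensities are a smooth Gaussian
#' random field (correlation length extended by the class effect for
#' event subjects) plus white noise; LGE-like intensities are a
#' high-frequency granular field scaled by `lge_granularity`. The
#' background is dark tissue and the blood pool a bright disc, so
#' boundary perturbations exchange pixels across strong intensity
#' steps. The base segmentation is a 24-vertex polygon tracing the outer
#' ring boundary; per sequence, reader 1 read 1 uses it directly, while
#' reader 1 read 2 and reader 2 are radial perturbations of magnitude
#' `roi_jitter` (T2w) or `lge_roi_jitter` (LGE).
#'
#' @param spec a [cohort_spec()].
#' @param event logical: does this subject carry the outcome-linked
#'   texture effect?
#' @param seed subject-level seed.
#' @return List with `t2w`, `lge`, `rois` (list of three
#'   [roi_polygon()]s), and `base_poly`.
#' @export
render_subject <- function(spec, event, seed) {
  sz <- spec$image_size
  geom <- with_seed(derive_seed(seed, "geometry"), {
    list(cx = (sz - 1) / 2 + stats::runif(1, -6, 6),
         cy = (sz - 1) / 2 + stats::runif(1, -6, 6),
         r_out = stats::runif(1, spec$outer_radius[1], spec$outer_radius[2]),
         thick = stats::runif(1, spec$ring_thickness[1],
                              spec$ring_thickness[2]),
         ecc = stats::runif(1, 0, 0.12),
         phi = stats::runif(1, 0, pi))
  })
  if (geom$r_out - geom$thick <= 4) stop("degenerate ring radii")
  x <- matrix(0:(sz - 1), sz, sz, byrow = TRUE)
  y <- matrix(0:(sz - 1), sz, sz)
  u <- ((x - geom$cx) * cos(geom$phi) + (y - geom$cy) * sin(geom$phi)) /
    (1 + geom$ecc)
  v <- (-(x - geom$cx) * sin(geom$phi) + (y - geom$cy) * cos(geom$phi)) /
    (1 - geom$ecc)
  rad <- sqrt(u^2 + v^2)
  ring <- rad <= geom$r_out & rad >= geom$r_out - geom$thick
  pool <- rad < geom$r_out - geom$thick
  ell <- spec$t2w_ell + if (event) spec$effect_dell else 0
  fsd <- spec$t2w_field_sd + if (event) spec$effect_dsd else 0
  t2w <- with_seed(derive_seed(seed, "t2w"), {
    img <- 80 + stats::rnorm(sz * sz, 0, 6)
    dim(img) <- c(sz, sz)
    img[pool] <- 450 + stats::rnorm(sum(pool), 0, 10)
    img[ring] <- 300 + fsd * gaussian_field(sz, ell)[ring] +
      stats::rnorm(sum(ring), 0, spec$t2w_noise_sd)
    gray_image(img, spec$spacing)
  })
  lge <- with_seed(derive_seed(seed, "lge"), {
    img <- 80 + stats::rnorm(sz * sz, 0, 6)
    dim(img) <- c(sz, sz)
    img[pool] <- 500 + stats::rnorm(sum(pool), 0, 10)
    img[ring] <- 250 + spec$lge_granularity * gaussian_field(sz, spec$lge_ell)[ring] +
      stats::rnorm(sum(ring), 0, 10)
    # bright epicardial collar just outside the true boundary (fat is not
    # suppressed on LGE): re-segmentation jitter exchanges pixels across
    # this intensity step, which is what makes LGE features unstable
    collar <- rad > geom$r_out & rad <= geom$r_out + 4
    img[collar] <- 250 + 5 * spec$lge_granularity +
      stats::rnorm(sum(collar), 0, 30)
    gray_image(img, spec$spacing)
  })
  theta <- seq(0, 2 * pi, length.out = 25)[-25]
  pu <- geom$r_out * cos(theta); pv <- geom$r_out * sin(theta)
  base_poly <- roi_polygon(cbind(
    x = geom$cx + pu * (1 + geom$ecc) * cos(geom$phi) -
      pv * (1 - geom$ecc) * sin(geom$phi),
    y = geom$cy + pu * (1 + geom$ecc) * sin(geom$phi) +
      pv * (1 - geom$ecc) * cos(geom$phi)), reader = 1L, read = 1L)
  reading_set <- function(seq_tag, jitter) {
    rois <- list(
      r1r1 = base_poly,
      r1r2 = perturb_polygon(base_poly, jitter,
                             derive_seed(seed, "read", seq_tag, "r1r2")),
      r2r1 = perturb_polygon(base_poly, jitter,
                             derive_seed(seed, "read", seq_tag, "r2r1")))
    rois$r1r2$read <- 2L
    rois$r2r1$reader <- 2L
    rois
  }
  list(t2w = t2w, lge = lge,
       rois = list(T2w = reading_set("T2w", spec$roi_jitter),
                   LGE = reading_set("LGE", spec$lge_roi_jitter)),
       base_poly = base_poly)
}

# Zero-mean, unit-variance Gaussian random field: white noise smoothed by
# an isotropic Gaussian kernel of width `ell` (pixels) via FFT (circular
# convolution), then standardized. Consumes the current RNG stream.
gaussian_field <- function(sz, ell) {
  wn <- matrix(stats::rnorm(sz * sz), sz, sz)
  fr <- c(0:(sz %/% 2), -((sz - sz %/% 2 - 1):1)) / sz
  k <- exp(-2 * pi^2 * ell^2 * outer(fr^2, fr^2, "+"))
  f <- Re(stats::fft(stats::fft(wn) * k, inverse = TRUE)) / (sz * sz)
  (f - mean(f)) / stats::sd(f)
}

#' Perturb a polygon radially
#'
#' Each vertex is displaced along its ray from the polygon centroid by
#' an independent `N(0, magnitude^2)` draw. If the perturbed polygon is
#' self-intersecting or encloses fewer than 16 pixels, a fresh draw is
#' attempted (up to 10 times); the last simple attempt is returned with
#' a warning if none succeeds. Magnitude 0 returns the polygon
#' unchanged.
#'
#' @param poly a [roi_polygon()].
#' @param magnitude radial displacement SD in pixels (>= 0).
#' @param seed integer seed.
#' @return A perturbed [roi_polygon()].
#' @export
perturb_polygon <- function(poly, magnitude, seed) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(poly)
  v <- poly$vertices
  ctr <- colMeans(v)
  rad <- sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2)
  dir <- cbind((v[, 1] - ctr[1]) / rad, (v[, 2] - ctr[2]) / rad)
  with_seed(seed, {
    for (attempt in 1:10) {
      d <- stats::rnorm(nrow(v), 0, magnitude)
      w <- v + dir * d
      ok <- polygon_is_simple(w) && abs(polygon_area(w)) >= 16
      if (ok) {
        return(roi_polygon(w, reader = poly$reader, read = poly$read))
      }
    }
    warning("polygon perturbation kept breaking simplicity; ",
            "returning the unperturbed polygon")
    poly
  })
}

# Shoelace area (signed).
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Write a cohort to disk as portable text files
#'
#' Per subject: two PGM images with spacing sidecars
#' (`<id>_T2w.pgm`, `<id>_LGE.pgm`) and three ROI JSON files; plus
#' `cohort.csv` (id, age, sex, bmi, macce) and `manifest.json` recording
#' the spec and seed for exact replay.
#'
#' @param cohort a rendered `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(!is.null(cohort$imaging))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$subjects$id) {
    sub <- cohort$imaging[[id]]
    write_pgm(sub$t2w, file.path(dir, paste0(id, "_T2w.pgm")))
    write_pgm(sub$lge, file.path(dir, paste0(id, "_LGE.pgm")))
    for (sq in names(sub$rois)) {
      for (tag in names(sub$rois[[sq]])) {
        write_roi_json(sub$rois[[sq]][[tag]],
                       file.path(dir, paste0(id, "_", sq, "_roi_", tag,
                                             ".json")))
      }
    }
  }
  utils::write.csv(cohort$subjects, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(cohort$spec), seed = cohort$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
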