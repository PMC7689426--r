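test_that("cohort composition counts are exact by construction", {
  for (seed in c(1, 7, 99)) {
    co <- generate_cohort(cohort_spec(), seed = seed, render = FALSE)
    expect_equal(nrow(co$subjects), 58)
    expect_equal(sum(co$subjects$macce), 6)
    expect_equal(sum(co$subjects$sex), 56)
    expect_true(all(co$subjects$age >= 30 & co$subjects$age <= 95))
    expect_true(all(co$subjects$bmi >= 14 & co$subjects$bmi <= 45))
  }
})

test_that("identical spec and seed give a bit-identical cohort", {
  small <- cohort_spec(n_subjects = 4, n_events = 1, n_female = 3)
  a <- generate_cohort(small, seed = 5)
  b <- generate_cohort(small, seed = 5)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$imaging[[1]]$t2w$pixels, b$imaging[[1]]$t2w$pixels)
  expect_identical(a$imaging[[2]]$lge$pixels, b$imaging[[2]]$lge$pixels)
  expect_identical(a$imaging[[3]]$rois, b$imaging[[3]]$rois)
  # covariates do not depend on whether images were rendered
  c0 <- generate_cohort(small, seed = 5, render = FALSE)
  expect_identical(c0$subjects, a$subjects)
})

test_that("the outcome effect is confined to T2w images of event subjects", {
  spec_null <- cohort_spec(effect_dell = 0, effect_dsd = 0)
  a <- render_subject(spec_null, event = TRUE, seed = 42)
  b <- render_subject(spec_null, event = FALSE, seed = 42)
  # with a null effect, event status changes nothing
  expect_identical(a$t2w$pixels, b$t2w$pixels)
  expect_identical(a$lge$pixels, b$lge$pixels)
  spec_eff <- cohort_spec()
  c1 <- render_subject(spec_eff, event = TRUE, seed = 42)
  c2 <- render_subject(spec_eff, event = FALSE, seed = 42)
  expect_false(identical(c1$t2w$pixels, c2$t2w$pixels))
  expect_identical(c1$lge$pixels, c2$lge$pixels)  # LGE carries no effect
})

test_that("polygon perturbation: identity at zero, simple and bounded otherwise", {
  base <- render_subject(cohort_spec(), event = FALSE, seed = 3)$base_poly
  expect_identical(perturb_polygon(base, 0, 1), base)
  dices <- vapply(1:100, function(s) {
    p <- perturb_polygon(base, 1.5, s)
    expect_true(nrow(p$vertices) == nrow(base$vertices))
    mask_dice(rasterize_roi(p, c(256, 256)), rasterize_roi(base, c(256, 256)))
  }, numeric(1))
  expect_true(all(dices >= 0.85 & dices < 1))
  expect_gt(median(dices), 0.95)
  expect_lt(median(dices), 0.99)
})

test_that("written cohorts round-trip through the text formats", {
  small <- cohort_spec(n_subjects = 3, n_events = 1, n_female = 2,
                       image_size = 160)
  co <- generate_cohort(small, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(tab$macce, co$subjects$macce)
  img <- read_image(file.path(dir, "S001_T2w.pgm"))
  expect_equal(img$spacing_row, 0.390625)
  expect_equal(dim(img$pixels), c(160L, 160L))
  # PGM stores rounded integers
  expect_lt(max(abs(img$pixels - round(co$imaging[[1]]$t2w$pixels))), 1e-9)
  roi <- read_roi_json(file.path(dir, "S001_T2w_roi_r2r1.json"))
  expect_equal(roi$vertices, co$imaging[[1]]$rois$T2w$r2r1$vertices)
  expect_equal(roi$reader, 2L)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 9)
  expect_equal(man$spec$n_subjects, 3)
})

test_that("grand mean age and BMI match the configured distribution", {
  ages <- unlist(lapply(1:50, function(s) {
    generate_cohort(cohort_spec(), seed = s, render = FALSE)$subjects$age
  }))
  expect_lt(abs(mean(ages) - 68.4), 0.5)
  bmis <- unlist(lapply(1:50, function(s) {
    generate_cohort(cohort_spec(), seed = s, render = FALSE)$subjects$bmi
  }))
  expect_lt(abs(mean(bmis) - 24.4), 0.3)
})

test_that("LGE re-segmentations are less reproducible than T2w ones", {
  co <- generate_cohort(cohort_spec(n_subjects = 6, n_events = 1,
                                    n_female = 5), seed = 31)
  d <- function(sq) {
    vapply(co$imaging, function(sub) {
      mask_dice(rasterize_roi(sub$rois[[sq]]$r1r1, c(256, 256)),
                rasterize_roi(sub$rois[[sq]]$r2r1, c(256, 256)))
    }, numeric(1))
  }
  expect_gt(mean(d("T2w")), mean(d("LGE")))
})
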