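# Shared sphere-pair phantoms (0.5 mm isotropic unless stated).
pair_05 <- function(rt, ra, offset = c(0, 0, 0)) {
  sp <- phantom_spec(c(0, 0, 0), rt, offset, ra, spacing = c(0.5, 0.5, 0.5))
  make_phantom(sp)
}

test_that("residual_tumor measures the uncovered tumor volume", {
  ph <- pair_05(10, 15)
  expect_equal(residual_tumor(ph$tumor, ph$ablation), 0)

  shell <- pair_05(10, 8)                       # tumor protrudes 2 mm
  got <- residual_tumor(shell$tumor, shell$ablation)
  want <- 4 / 3 * pi * (10^3 - 8^3)
  expect_lt(abs(got - want) / want, 0.10)

  apart <- phantom_spec(c(0, 0, 0), 5, c(30, 0, 0), 5, spacing = c(1, 1, 1))
  ph2 <- make_phantom(apart)
  expect_equal(residual_tumor(ph2$tumor, ph2$ablation),
               volume_mm3(ph2$tumor))

  other <- annotated_volume(array(FALSE, c(3, 3, 3)))
  expect_error(residual_tumor(ph$tumor, other), "same grid")
})

test_that("coverage MAM reproduces closed-form sphere margins", {
  ph <- pair_05(10, 15)
  cov <- mam_coverage(ph$tumor, ph$ablation)
  expect_equal(cov$mam, 5L)
  expect_equal(cov$sentinel, 5L)
  # unablated volume profile is zero up to the margin, positive after,
  # and non-decreasing in r
  u <- cov$unablated_volume_by_margin
  expect_equal(u$unablated_mm3[u$r_mm <= 5], rep(0, 5))
  expect_true(all(u$unablated_mm3[u$r_mm > 5] > 0))
  expect_true(all(diff(u$unablated_mm3) >= 0))

  off <- pair_05(8, 14, offset = c(2, 0, 0))    # R_a - d - R_t = 4
  expect_equal(mam_coverage(off$tumor, off$ablation)$mam, 4L)

  res <- pair_05(10, 8)
  cov_res <- mam_coverage(res$tumor, res$ablation)
  expect_equal(cov_res$mam, "residual")
  expect_equal(cov_res$sentinel, -1L)

  empty <- annotated_volume(array(FALSE, dim(ph$tumor$grid)),
                            spacing = ph$tumor$spacing,
                            origin = ph$tumor$origin)
  expect_error(mam_coverage(empty, ph$ablation), "empty")
})

test_that("surface MAM matches closed forms with sign", {
  ph <- pair_05(10, 15)
  expect_equal(mam_surface(ph$tumor, ph$ablation), 5L)
  res <- pair_05(10, 8)
  expect_equal(mam_surface(res$tumor, res$ablation), -2L)
  empty <- annotated_volume(array(FALSE, dim(ph$tumor$grid)),
                            spacing = ph$tumor$spacing,
                            origin = ph$tumor$origin)
  expect_error(mam_surface(ph$tumor, empty), "empty")
})

test_that("surface MAM equals the brute-force signed oracle on random masks", {
  set.seed(2024)
  n_checked <- 0
  for (i in 1:15) {
    dm <- sample(8:16, 3, replace = TRUE)
    spacing <- round(runif(3, 0.5, 2), 2)
    ablation <- rand_mask(dm, runif(1, 0.2, 0.5))
    tumor <- rand_mask(dm, 0.1)
    if (!any(tumor) || !any(ablation)) next
    tv <- annotated_volume(tumor, spacing)
    av <- annotated_volume(ablation, spacing)
    want <- brute_signed_mam(tumor, ablation, spacing)
    expect_equal(mam_surface(tv, av, rounded = FALSE), want,
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("octant margins localize one-sided insufficiency", {
  ph <- pair_05(10, 15)
  oct <- octant_margins(ph$tumor, ph$ablation)
  # symmetry: all octants carry (about) the global margin
  glob <- mam_surface(ph$tumor, ph$ablation, rounded = FALSE)
  expect_true(all(abs(oct$table$min_margin_mm - glob) <= 1))

  # ablation shifted +3 mm along left-right: the thin side is the left pole
  # (16 - 3 - 10 = 3 mm); octants on the right still contain near-equator
  # voxels, where the closed-form margin is R_a - sqrt(R_t^2 + d^2) = 5.56 mm
  shifted <- pair_05(10, 16, offset = c(3, 0, 0))
  oct2 <- octant_margins(shifted$tumor, shifted$ablation)
  left <- grepl("^L", oct2$table$octant)
  expect_true(all(abs(oct2$table$min_margin_mm[left] - 3) <= 1))
  expect_true(all(abs(oct2$table$min_margin_mm[!left] -
                        (16 - sqrt(100 + 9))) <= 1))
  expect_setequal(oct2$insufficient_octants, oct2$table$octant[left])
})

test_that("minimum over octants equals the global surface MAM", {
  set.seed(99)
  for (i in 1:8) {
    dm <- sample(10:16, 3, replace = TRUE)
    spacing <- round(runif(3, 0.5, 1.5), 2)
    tumor <- rand_mask(dm, 0.12)
    ablation <- rand_mask(dm, 0.4)
    if (!any(tumor) || !any(ablation)) next
    tv <- annotated_volume(tumor, spacing)
    av <- annotated_volume(ablation, spacing)
    oct <- octant_margins(tv, av)
    expect_equal(min(oct$table$min_margin_mm, na.rm = TRUE),
                 mam_surface(tv, av, rounded = FALSE), tolerance = 1e-12)
  }
})

test_that("sphere margins converge to the closed form as spacing shrinks", {
  errs <- vapply(c(2, 1, 0.5), function(h) {
    sp <- phantom_spec(c(0, 0, 0), 10, c(0, 0, 0), 15,
                       spacing = c(h, h, h))
    ph <- make_phantom(sp)
    diag_mm <- sqrt(3) * h
    err_surf <- abs(mam_surface(ph$tumor, ph$ablation, rounded = FALSE) - 5)
    expect_lte(err_surf, diag_mm)
    cov <- mam_coverage(ph$tumor, ph$ablation)$mam
    expect_lte(abs(cov - 5), max(1, diag_mm))
    err_surf
  }, numeric(1))
  expect_lt(errs[3], errs[1])           # finer grids measure closer to truth
})

test_that("both MAM definitions agree on fully covered convex phantoms", {
  set.seed(5)
  for (i in 1:6) {
    rt <- runif(1, 4, 9)
    gap <- runif(1, 1, 8)
    off <- runif(3, -1, 1)
    ph <- make_phantom(phantom_spec(c(0, 0, 0), rt, off, rt + gap +
                                      sqrt(sum(off^2)),
                                    spacing = c(0.8, 0.8, 0.8)))
    surf_raw <- mam_surface(ph$tumor, ph$ablation, rounded = FALSE)
    cov <- mam_coverage(ph$tumor, ph$ablation)$mam
    expect_true(is.numeric(cov))
    expect_lte(abs(cov - min(max(floor(surf_raw), 0), 10)), 1)
  }
})

test_that("growing the ablation zone never decreases either MAM", {
  set.seed(31)
  for (i in 1:5) {
    ph <- pair_05(6, runif(1, 5, 9), offset = runif(3, -2, 2))
    bigger <- dilate_mm(ph$ablation, 1.5)
    expect_gte(mam_surface(ph$tumor, bigger, rounded = FALSE),
               mam_surface(ph$tumor, ph$ablation, rounded = FALSE))
    s1 <- mam_coverage(ph$tumor, ph$ablation)$sentinel
    s2 <- mam_coverage(ph$tumor, bigger)$sentinel
    expect_gte(s2, s1)
  }
})

test_that("quantify composes registration, margins, and octants", {
  sp <- phantom_spec(c(0, 0, 0), 10, c(0, 0, 0), 15,
                     spacing = c(0.5, 0.5, 0.5),
                     misalignment = rigid_transform(diag(3), c(4, 0, 0)),
                     n_landmarks = 4, seed = 9)
  ph <- make_phantom(sp)
  res <- quantify(ph$tumor, ph$ablation, landmarks = ph$landmarks)
  expect_s3_class(res, "margin_result")
  expect_equal(res$mam_coverage, 5L)
  expect_equal(res$mam_surface, 5L)
  expect_equal(res$sentinel_coverage, 5L)
  expect_equal(res$residual_volume_mm3, 0)
  expect_length(res$insufficient_octants, 0)
  expect_true(res$registration$audit$sufficient)

  # residual phantom: sentinel convention
  res_ph <- pair_05(10, 8)
  r2 <- quantify(res_ph$tumor, res_ph$ablation)
  expect_equal(r2$mam_coverage, "residual")
  expect_equal(r2$sentinel_coverage, -1L)
  expect_lt(r2$mam_surface, 0)
})

test_that("quantify refuses tumors with failed co-registration", {
  ph <- pair_05(10, 15)
  pre <- matrix(runif(15, -10, 10), ncol = 3)
  post <- pre
  post[4, 1] <- post[4, 1] + 9          # two opposing gross mismatches:
  post[5, 1] <- post[5, 1] - 9          # no rigid fit can absorb both
  bad <- landmark_set(pre, post)
  expect_error(quantify(ph$tumor, ph$ablation, landmarks = bad),
               "excluded: failed co-registration")
})
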