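peaks_toy <- function() {
  tibble::tibble(
    individual_id = rep(c("Pbm_01", "Fg_01"), each = 3),
    phase = rep(c("Pbm", "Fg"), each = 3),
    compound_id = rep(c("C23", "C27:1", "11-MeC27"), 2),
    class = rep(c("n_alkane", "unsaturated", "branched"), 2),
    carbon_n = rep(c(23, 27, 28), 2),
    area = c(200, 300, 500, 100, 100, 200),
    is_area = 1000)
}

test_that("percent normalization matches hand arithmetic and its invariances", {
  rel <- normalize_relative(peaks_toy(), scope = "all")
  p1 <- rel[rel$individual_id == "Pbm_01", ]
  expect_equal(p1$pct, c(20, 30, 50))
  sums <- tapply(rel$pct, rel$individual_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # single compound -> 100%
  one <- normalize_relative(peaks_toy()[1, ], scope = "all")
  expect_equal(one$pct, 100)

  # invariance under rescaling all areas of an individual
  scaled <- peaks_toy()
  scaled$area[scaled$individual_id == "Pbm_01"] <-
    scaled$area[scaled$individual_id == "Pbm_01"] * 37
  expect_equal(normalize_relative(scaled, "all")$pct, rel$pct)

  # per-class normalization equals all-scope restricted and renormalized
  pc <- normalize_relative(peaks_toy(), scope = "per_class")
  alk <- rel[rel$class == "n_alkane", ]
  renorm <- 100 * alk$pct / tapply(alk$pct, alk$individual_id,
                                   sum)[alk$individual_id]
  expect_equal(pc$pct[pc$class == "n_alkane"], as.numeric(renorm))
  expect_error(normalize_relative(dplyr::mutate(peaks_toy(), area = -1)),
               ">= 0")
})

test_that("calibration fitting recovers a noise-free line exactly", {
  standards <- make_standards(slope = 0.5, intercept = 0)
  curves <- fit_calibration(standards)
  ct <- tibble::as_tibble(curves)
  expect_equal(ct$slope, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(ct$intercept, rep(0, 3), tolerance = 1e-9)
  expect_equal(ct$r_value, rep(1, 3), tolerance = 1e-12)
  expect_true(glance(curves)$all_acceptable)

  # a nonzero intercept is recovered too
  ci <- tibble::as_tibble(fit_calibration(make_standards(0.8, 0.4)))
  expect_equal(ci$slope, rep(0.8, 3), tolerance = 1e-9)
  expect_equal(ci$intercept, rep(0.4, 3), tolerance = 1e-9)

  flat <- make_standards(); flat$area <- 5
  expect_error(fit_calibration(flat), "zero-variance")
  expect_error(fit_calibration(make_standards()[c(1, 7, 13), ]), ">= 3")
})

test_that("with 2% multiplicative noise the calibration R clears 0.99", {
  cfg <- chc_sim_config(noise_cv = 0.02, seed = 21)
  curves <- fit_calibration(generate_chc(cfg)$standards)
  expect_true(all(tibble::as_tibble(curves)$r_value >= 0.99))
})

test_that("the curve-assignment rule is exact on every carbon number", {
  expect_identical(assign_curve(20:35),
                   c(rep("C23", 5),   # C20-C24
                     rep("C25", 5),   # C25-C29
                     rep("C32", 6)))  # C30-C35
  expect_error(assign_curve(19), "\\[20, 35\\]")
  expect_error(assign_curve(36), "\\[20, 35\\]")
})

test_that("absolute quantification inverts the calibration and corrects pools", {
  standards <- make_standards(slope = 0.5, intercept = 0)
  curves <- fit_calibration(standards)
  peaks <- peaks_toy()
  amounts <- absolute_quantify(peaks, curves, pool_size = 1,
                               extract_volume_ml = 0.160)
  # hand inversion: conc = 0.5 * area/IS; amount = conc * 0.160
  expect_equal(amounts$amount_ug,
               0.5 * peaks$area / peaks$is_area * 0.160,
               tolerance = 1e-12)
  pooled <- absolute_quantify(peaks, curves, pool_size = 3,
                              extract_volume_ml = 0.160)
  expect_equal(pooled$amount_ug, amounts$amount_ug / 3, tolerance = 1e-12)

  # negative prediction clamps to zero with a warning and a flag
  neg_curves <- fit_calibration(make_standards(slope = 0.5, intercept = -3))
  low <- peaks; low$area <- 1
  expect_warning(res <- absolute_quantify(low, neg_curves), "clamped")
  expect_true(all(res$amount_ug == 0))
  expect_true(all(res$below_quantification))
})

test_that("class totals sum per-bee compound amounts within class", {
  standards <- make_standards(slope = 1, intercept = 0)
  curves <- fit_calibration(standards)
  amounts <- absolute_quantify(peaks_toy(), curves, 1, 1)
  tot <- chc_class_totals(amounts)
  expect_setequal_chr(unique(tot$class), c("n_alkane", "unsaturated"))
  a1 <- amounts[amounts$individual_id == "Pbm_01", ]
  expect_equal(tot$total_ug[tot$individual_id == "Pbm_01" &
                              tot$class == "n_alkane"],
               sum(a1$amount_ug[a1$class == "n_alkane"]))
})

test_that("phase tests letter each compound and honor the CLD contract", {
  cfg <- chc_sim_config(noise_cv = 0.05, seed = 31)
  sim <- generate_chc(cfg)
  rel <- normalize_relative(sim$peaks)
  lt <- per_peak_phase_test(rel)
  expect_setequal_chr(unique(lt$compound_id), cfg$roster$compound_id)
  tests <- attr(lt, "tests")
  for (cmp in names(tests)) {
    pl <- tests[[cmp]]
    share <- function(a, b) any(strsplit(pl$letters$letter[a], "")[[1]] %in%
                                  strsplit(pl$letters$letter[b], "")[[1]])
    for (i in 1:2) for (j in (i + 1):3) {
      expect_identical(share(i, j),
                       pl$p_pairwise[pl$letters$group[i],
                                     pl$letters$group[j]] >= pl$alpha)
    }
  }
  # planted forager shift in class totals: Fg distinct for n-alkanes
  curves <- fit_calibration(sim$standards)
  totals <- chc_class_totals(absolute_quantify(sim$peaks, curves,
                                               cfg$pool_size,
                                               cfg$extract_volume_ml))
  cl <- per_class_phase_test(totals)
  alk <- cl[cl$class == "n_alkane", ]
  expect_false(alk$letter[alk$phase == "Fg"] %in%
                 alk$letter[alk$phase != "Fg"])
})

test_that("identical phase distributions share one letter", {
  set.seed(41)
  flat <- tibble::tibble(
    individual_id = paste0("i", 1:30),
    phase = rep(c("Pbm", "Ne", "Fg"), each = 10),
    class = "n_alkane",
    total_ug = rnorm(30, 10, 1))
  cl <- per_class_phase_test(flat)
  expect_length(unique(cl$letter), 1L)
})

test_that("PCA concentrates loadings on the driving compound", {
  set.seed(51)
  n <- 20
  driver <- c(rnorm(10, 20, 4), rnorm(10, 60, 4))
  rest <- 100 - driver
  rel <- tibble::tibble(
    individual_id = rep(paste0("i", 1:n), times = 2),
    phase = rep(rep(c("Ne", "Fg"), each = 10), 2),
    compound_id = rep(c("C23", "C25"), each = n),
    pct = c(driver, rest))
  pca <- pca_loadings(rel)
  expect_gte(pca$var_explained[1], 0.99)
  expect_true(all(diff(pca$var_explained) <= 1e-9))
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-12)
  # 2-variable toy: loadings equal the covariance eigenvectors
  wide <- cbind(driver, rest)
  ev <- eigen(cov(wide))$vectors[, 1]
  l1 <- pca$loadings[pca$loadings$component == "PC1", ]
  got <- l1$loading[match(c("C23", "C25"), l1$compound_id)]
  expect_equal(abs(got), abs(ev), tolerance = 1e-9)
  # loadings ranked by absolute value within component
  expect_true(all(tapply(abs(l1$loading), rep(1, nrow(l1)),
                         function(v) all(diff(v) <= 1e-12))))
})
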