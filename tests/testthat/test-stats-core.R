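test_that("pearson matches the product-moment formula computed by hand", {
  x <- 1:9
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 9)
  # closed-form oracle, spelled out term by term
  n <- 9
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * (1 - pt(abs(t_hand), df = n - 2))
  res <- pearson_test(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$n, 9L)
  # independent route: stats::cor.test
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("pearson handles exact and degenerate cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  expect_equal(pearson_test(x, x)$p, 0)
  expect_error(pearson_test(rep(1, 5), x), "zero variance")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
})

test_that("pearson is symmetric and invariant under positive affine maps", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    a <- pearson_test(x, y); b <- pearson_test(y, x)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    z <- pearson_test(2.5 * x + 7, y)
    expect_equal(a$r, z$r, tolerance = 1e-12)
  }
})

test_that("two-proportion z matches the pooled formula and its edge cases", {
  # hand-computed pooled oracle for (30/100 vs 50/100)
  pool <- (30 + 50) / 200
  se <- sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  z_hand <- (0.3 - 0.5) / se
  res <- two_proportion_z(30, 100, 50, 100)
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)

  eq <- two_proportion_z(20, 50, 40, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(two_proportion_z(0, 10, 0, 20), "degenerate")
  expect_error(two_proportion_z(10, 10, 20, 20), "degenerate")
})

test_that("two-proportion z p-value agrees with a simulated binomial null at small counts", {
  obs <- two_proportion_z(3, 12, 8, 10)
  set.seed(7)
  nrep <- 50000
  pool <- (3 + 8) / 22
  k1 <- rbinom(nrep, 12, pool); k2 <- rbinom(nrep, 10, pool)
  zs <- vapply(seq_len(nrep), function(i) {
    p <- (k1[i] + k2[i]) / 22
    if (p == 0 || p == 1) return(0)
    (k1[i] / 12 - k2[i] / 10) / sqrt(p * (1 - p) * (1 / 12 + 1 / 10))
  }, numeric(1))
  p_mc <- mean(abs(zs) >= abs(obs$z) - 1e-12)
  mc_se <- sqrt(p_mc * (1 - p_mc) / nrep)
  # normal approximation vs exact null: allow MC error plus discreteness
  expect_lt(abs(obs$p - p_mc), 4 * mc_se + 0.02)
})

test_that("two-proportion z holds its type-I error under an equal-proportion null", {
  set.seed(11)
  nrep <- 10000
  k1 <- rbinom(nrep, 200, 0.3); k2 <- rbinom(nrep, 200, 0.3)
  pool <- (k1 + k2) / 400
  se <- sqrt(pool * (1 - pool) * (2 / 200))
  z <- (k1 / 200 - k2 / 200) / se
  # the vectorized formula must agree with the function itself
  spot <- vapply(1:200, function(i) two_proportion_z(k1[i], 200, k2[i], 200)$z,
                 numeric(1))
  expect_equal(spot, z[1:200], tolerance = 1e-12)
  rej <- mean(2 * pnorm(-abs(z)) < 0.05)
  ci <- 4 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rej - 0.05), ci)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  # independent step-up oracle
  ord <- order(p)
  q_hand <- numeric(50)
  running <- 1
  for (i in 50:1) {
    running <- min(running, p[ord[i]] * 50 / i)
    q_hand[ord[i]] <- running
  }
  expect_equal(q, q_hand, tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
})

test_that("Student's t on identical samples gives t = 0, p = 1", {
  res <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("Shapiro-Wilk gate matches stats::shapiro.test and rejects constants", {
  set.seed(5)
  x <- rlnorm(30)
  expect_equal(shapiro_wilk(x)$p, shapiro.test(x)$p.value)
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
})

test_that("ANOVA/Tukey letters separate a strongly shifted group and merge identical ones", {
  set.seed(21)
  d_same <- data.frame(y = rnorm(90, 10, 1), g = rep(c("a", "b", "c"), 30))
  expect_length(unique(anova_tukey(d_same, y, g)$letters$letter), 1L)

  d_shift <- data.frame(y = c(rnorm(20, 0, 1), rnorm(20, 0, 1),
                              rnorm(20, 10, 1)),
                        g = rep(c("a", "b", "c"), each = 20))
  lt <- anova_tukey(d_shift, y, g)$letters
  expect_false(lt$letter[lt$group == "c"] %in%
                 lt$letter[lt$group != "c"])
  expect_error(anova_tukey(data.frame(y = 1:3, g = c("a", "a", "b")), y, g),
               "at least 2")
})

test_that("Tukey pairwise p matches a Monte-Carlo studentized-range oracle", {
  d <- data.frame(y = c(5.1, 4.8, 5.4, 5.0, 6.2, 6.0, 6.5, 5.9,
                        5.3, 5.6, 5.2, 5.5),
                  g = rep(c("a", "b", "c"), each = 4))
  res <- anova_tukey(d, y, g)
  # MC oracle: null distribution of the studentized range for k = 3,
  # df = 9, via direct simulation
  k <- 3; df <- 9; nmc <- 100000
  ms_within <- sum(unlist(tapply(d$y, d$g, function(v) (v - mean(v))^2))) / df
  means <- tapply(d$y, d$g, mean)
  q_obs <- abs(outer(means, means, "-")) / sqrt(ms_within / 4)
  set.seed(13)
  zs <- matrix(rnorm(nmc * k), ncol = k)
  ss <- sqrt(rchisq(nmc, df) / df)
  q_null <- (apply(zs, 1, max) - apply(zs, 1, min)) / ss
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    p_mc <- mean(q_null >= q_obs[pr[1], pr[2]])
    p_pkg <- res$p_pairwise[pr[1], pr[2]]
    mc_se <- sqrt(max(p_mc * (1 - p_mc), 1e-6) / nmc)
    expect_lt(abs(p_pkg - p_mc), 5 * mc_se + 0.005)
  }
})

test_that("Conover-Iman t equals hand rank arithmetic on a 3x4 table", {
  vals <- c(12, 15, 11, 14,   22, 25, 21, 24,   32, 35, 31, 34)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  # hand computation: no ties, ranks are a permutation of 1..12
  rk <- rank(vals)
  N <- 12; k <- 3
  rbar <- tapply(rk, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(4 * (rbar - (N + 1) / 2)^2)
  S2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  pooled <- S2 * (N - 1 - H) / (N - k)
  t_hand <- (rbar[["g1"]] - rbar[["g2"]]) / sqrt(pooled * (1 / 4 + 1 / 4))
  res <- conover_iman_t(vals, grp, "g1", "g2")
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 9)
})

test_that("Kruskal/Conover letters: identical groups share, monotone shifts separate", {
  set.seed(31)
  d_same <- data.frame(y = sample(1:300), g = rep(c("a", "b", "c"), 100))
  expect_length(unique(kruskal_conover(d_same, y, g)$letters$letter), 1L)

  d_shift <- data.frame(y = c(rnorm(15, 0), rnorm(15, 6), rnorm(15, 12)),
                        g = rep(c("a", "b", "c"), each = 15))
  expect_length(unique(kruskal_conover(d_shift, y, g)$letters$letter), 3L)
  expect_error(kruskal_conover(data.frame(y = rep(1, 9),
                                          g = rep(c("a", "b", "c"), 3)),
                               y, g), "tied")
})

test_that("compact letters reproduce exactly the significance matrix they came from", {
  set.seed(17)
  for (rep_i in 1:25) {
    k <- sample(3:6, 1)
    groups <- paste0("G", seq_len(k))
    pm <- matrix(1, k, k, dimnames = list(groups, groups))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pm[i, j] <- pm[j, i] <- sample(c(0.001, 0.2, 0.8), 1)
    }
    lt <- cld_letters(pm, alpha = 0.05)
    share <- function(a, b) {
      any(strsplit(lt$letter[a], "")[[1]] %in% strsplit(lt$letter[b], "")[[1]])
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      expect_identical(share(i, j), pm[i, j] >= 0.05,
                       label = sprintf("rep %d pair %d-%d", rep_i, i, j))
    }
  }
})
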