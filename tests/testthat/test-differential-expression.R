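test_that("CPM normalization matches hand arithmetic and is scale-invariant", {
  m <- matrix(c(10, 90, 20, 180), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpm_normalize(m)
  expect_equal(cpm["g1", "s1"], 10 / 100 * 1e6)
  expect_equal(cpm["g2", "s2"], 180 / 200 * 1e6)
  # doubling one library's depth leaves its normalized values unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(cpm_normalize(m2), cpm)
  # equal library sizes: identity up to one global constant
  meq <- matrix(c(10, 90, 30, 70), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(cpm_normalize(meq), meq * 1e4)
  # gene-length correction gives FPKM-like values
  fl <- cpm_normalize(m, lengths = c(500, 2000))
  expect_equal(fl["g1", "s1"], (10 / 0.5) / (10 / 0.5 + 90 / 2) * 1e6)
})

test_that("nb_wald p matches the delta-method hand calculation on a toy", {
  set.seed(19)
  na <- 30
  cnt <- cbind(matrix(rnbinom(na, mu = 500, size = 10), 1),
               matrix(rnbinom(na, mu = 2000, size = 10), 1))
  cnt <- rbind(cnt, 1000)  # second gene stabilizes library sizes
  colnames(cnt) <- paste0("s", 1:60)
  rownames(cnt) <- c("g1", "g2")
  meta <- tibble::tibble(sample_id = colnames(cnt),
                         phase = rep(c("A", "B"), each = 30),
                         replicate = rep(1:30, 2))
  st <- expression_study(cnt, meta, "toy")
  res <- test_de(st, "A", "B", method = "nb_wald")
  # hand calculation from the documented model, done independently here
  xa <- st$normalized["g1", 1:30]; xb <- st$normalized["g1", 31:60]
  ma <- mean(xa); mb <- mean(xb)
  aa <- max(0, (var(xa) - ma) / ma^2); ab <- max(0, (var(xb) - mb) / mb^2)
  alpha <- (aa * 29 + ab * 29) / 58
  zz <- (log(mb + 1) - log(ma + 1)) /
    sqrt((1 / (ma + 1) + alpha) / 30 + (1 / (mb + 1) + alpha) / 30)
  expect_equal(res$p[res$gene == "g1"], 2 * pnorm(-abs(zz)),
               tolerance = 1e-10)
  expect_lt(res$p[res$gene == "g1"], 1e-6)
})

test_that("all-zero genes are reported untestable with p = 1", {
  st <- tiny_study()
  res <- test_de(st, "Pbm", "Ne")
  g3 <- res[res$gene == "g3", ]
  expect_true(g3$untestable)
  expect_equal(g3$p, 1)
  expect_equal(g3$direction, "none")
})

test_that("a no-effect deterministic simulation yields no significant genes", {
  cfg <- expression_sim_config(
    n_genes = 200, dispersion = 0, seed = 2,
    class_fractions = c(eusocial_heterochronic = 0, all_shared = 0,
                        solitary_shifted = 0, species_specific = 0,
                        flat = 1))
  sim <- generate_expression(cfg)
  res <- test_de(sim$studies$Am, "Pbm", "Ne")
  expect_equal(nrow(filter_degs(res)), 0L)
  expect_true(all(res$q > 0.9))
})

test_that("test_de is antisymmetric in its phase arguments", {
  sim <- generate_expression(expression_sim_config(n_genes = 80, seed = 4))
  ab <- test_de(sim$studies$Fv, "Pbm", "Ne")
  ba <- test_de(sim$studies$Fv, "Ne", "Pbm")
  expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("the two-method intersection is never more permissive than either method", {
  sim <- generate_expression(expression_sim_config(n_genes = 120, seed = 6))
  st <- sim$studies$Am
  w <- filter_degs(test_de(st, "Pbm", "Fg", method = "nb_wald"))
  p <- filter_degs(test_de(st, "Pbm", "Fg", method = "rank_perm"))
  b <- filter_degs(test_de(st, "Pbm", "Fg", method = "both"))
  expect_true(all(b$gene %in% w$gene))
  expect_true(all(b$gene %in% p$gene))
})

test_that("rank permutation p has the exact floor of the 3v3 design", {
  sim <- generate_expression(expression_sim_config(n_genes = 50, seed = 7))
  res <- test_de(sim$studies$Am, "Pbm", "Fg", method = "rank_perm")
  expect_gte(min(res$p), 2 / 20)
})

test_that("the DEG filter applies the study thresholds with the stated bounds", {
  base <- tibble::tibble(gene = "g", comparison = "Pbm_vs_Ne",
                         direction = "Ne", untestable = FALSE)
  rec <- dplyr::bind_rows(
    dplyr::mutate(base, gene = "low_abund", log2FC = 3, p = 0.001, q = 0.01,
                  mean_a = 1, mean_b = 2),
    dplyr::mutate(base, gene = "small_fc", log2FC = 0.8, p = 0.001, q = 0.01,
                  mean_a = 100, mean_b = 100 * 2^0.8),
    dplyr::mutate(base, gene = "boundary", log2FC = -1.0, p = 0.01, q = 0.04,
                  mean_a = 10, mean_b = 4.5, direction = "Pbm"),
    dplyr::mutate(base, gene = "q_fail", log2FC = 2, p = 0.04, q = 0.05,
                  mean_a = 10, mean_b = 40))
  kept <- filter_degs(rec)
  expect_identical(kept$gene, "boundary")  # |lfc| >= 1 inclusive, q < 0.05 strict
})

test_that("upregulation summary partitions a toy universe exactly as set arithmetic", {
  mk <- function(gene, comparison, direction) {
    tibble::tibble(gene = gene, comparison = comparison,
                   direction = direction, log2FC = 2, p = 0.001, q = 0.001,
                   mean_a = 10, mean_b = 40, untestable = FALSE)
  }
  degs <- dplyr::bind_rows(
    mk(paste0("g", 1:4), "Pbm_vs_Ne", "Ne"),
    mk(paste0("g", 3:7), "Pbm_vs_Fg", "Pbm"),
    mk(paste0("g", c(3, 8, 9, 10)), "Ne_vs_Fg", "Fg"))
  s <- upregulation_summary(degs)
  expect_equal(s$universe_size, 10L)
  venn <- setNames(s$venn$count, s$venn$region)
  # brute-force enumeration of the three-set partition
  inA <- paste0("g", 1:4); inB <- paste0("g", 3:7)
  inC <- paste0("g", c(3, 8, 9, 10))
  u <- paste0("g", 1:10)
  regions <- sapply(u, function(g) paste(sort(c(
    if (g %in% inA) "Pbm_vs_Ne", if (g %in% inB) "Pbm_vs_Fg",
    if (g %in% inC) "Ne_vs_Fg")), collapse = "&"))
  expect_equal(venn[names(table(regions))], table(regions) |> as.vector() |>
                 setNames(names(table(regions))))
  expect_equal(sum(s$venn$count), 10L)
  expect_lte(sum(s$venn$pct), 100 + 1e-9)
  # empty set
  s0 <- upregulation_summary(degs[0, ])
  expect_equal(s0$universe_size, 0L)
  expect_equal(nrow(s0$venn), 0L)
})

test_that("identical summaries compare with p = 1", {
  degs <- tibble::tibble(gene = paste0("g", 1:6), comparison = "Pbm_vs_Fg",
                         direction = rep(c("Pbm", "Fg"), 3), log2FC = 2,
                         p = 0.001, q = 0.001, mean_a = 10, mean_b = 40,
                         untestable = FALSE)
  s <- upregulation_summary(degs)
  res <- compare_proportions(s, s, "Pbm_vs_Fg:Pbm")
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("nb_wald agrees with DESeq2 on which planted genes are real", {
  sim <- generate_expression(expression_sim_config(n_genes = 300, seed = 10))
  st <- sim$studies$Am
  mine <- test_de(st, "Pbm", "Ne", method = "nb_wald")
  keep <- st$meta$phase %in% c("Pbm", "Ne")
  cts <- st$counts[, st$meta$sample_id[keep]]
  cd <- data.frame(phase = factor(st$meta$phase[keep],
                                  levels = c("Pbm", "Ne")))
  dds <- suppressMessages(DESeq2::DESeq(
    DESeq2::DESeqDataSetFromMatrix(cts, cd, ~phase), quiet = TRUE))
  ds <- as.data.frame(DESeq2::results(dds))
  both <- merge(mine, data.frame(gene = rownames(ds), p_ds = ds$pvalue),
                by = "gene")
  called_mine <- both$gene[both$q < 0.05 & abs(both$log2FC) >= 1]
  called_ds <- both$gene[p.adjust(both$p_ds, "BH") < 0.05 &
                           abs(both$log2FC) >= 1]
  jac <- length(intersect(called_mine, called_ds)) /
    length(union(called_mine, called_ds))
  expect_gt(jac, 0.8)
})
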