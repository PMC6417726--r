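# Small fixtures built in code; no data files.

# deterministic toy study: 4 genes x (2 phases x 3 reps), hand-set counts
tiny_study <- function() {
  counts <- rbind(
    g1 = c(10, 12, 11, 40, 44, 42),
    g2 = c(100, 90, 110, 100, 95, 105),
    g3 = c(0, 0, 0, 0, 0, 0),
    g4 = c(50, 55, 45, 12, 10, 14))
  colnames(counts) <- c("Pbm_1", "Pbm_2", "Pbm_3", "Ne_1", "Ne_2", "Ne_3")
  meta <- tibble::tibble(
    sample_id = colnames(counts),
    phase = rep(c("Pbm", "Ne"), each = 3),
    replicate = rep(1:3, 2))
  expression_study(counts, meta, species = "toy")
}

# study built from an explicit gene x sample matrix (3 phases x 3 reps)
study_from_matrix <- function(m, species = "syn") {
  colnames(m) <- paste0(rep(c("Pbm", "Ne", "Fg"), each = 3), "_", rep(1:3, 3))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  meta <- tibble::tibble(sample_id = colnames(m),
                         phase = rep(c("Pbm", "Ne", "Fg"), each = 3),
                         replicate = rep(1:3, 3))
  expression_study(round(m), meta, species = species)
}

# noise-free standard series on the line amount = slope * ratio + intercept
make_standards <- function(slope = 0.5, intercept = 0, is_area = 1e6,
                           levels = c(1.25, 2.5, 5, 10, 15, 20),
                           ids = c("C23", "C25", "C32")) {
  tidyr::expand_grid(standard_id = ids, level_ug_ml = levels) |>
    dplyr::mutate(area = (level_ug_ml - intercept) / slope * is_area,
                  is_area = is_area)
}

# brute-force complete-linkage clustering over a distance matrix, used as an
# independent oracle for merge structure (small n only)
brute_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h; best <- c(i, j)
        }
      }
    }
    merges <- c(merges, list(sort(unlist(clusters[best]))))
    heights <- c(heights, best_h)
    clusters <- c(clusters[-best],
                  list(sort(unlist(clusters[best]))))
  }
  list(leafsets = merges, heights = heights)
}

expect_setequal_chr <- function(a, b) expect_true(setequal(a, b))
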