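# Differential expression between developmental phases.
#
# The calling scheme follows the comparative design: a per-gene negative-
# binomial Wald test (method-of-moments dispersion, floored at 0) and/or an
# exact replicate-label permutation test, with "both" requiring a gene to be
# significant under each test — the intersection semantics used when two
# independent DE tools must agree.

#' Test genes for differential expression between two phases
#'
#' @param study An [expression_study()].
#' @param phase_a,phase_b Phase labels to compare; fold changes are reported
#'   as `phase_b` relative to `phase_a`.
#' @param method `"nb_wald"` (default), `"rank_perm"`, or `"both"`.
#'   \describe{
#'     \item{nb_wald}{per-gene NB model on normalized counts: group means
#'       \eqn{m_A, m_B}; pooled method-of-moments dispersion
#'       \eqn{\alpha = \max(0, (s^2 - m)/m^2)}; Wald statistic on
#'       \eqn{\log((m_B+1)/(m_A+1))} with delta-method variance
#'       \eqn{1/(n m) + \alpha/n} per group.}
#'     \item{rank_perm}{exact permutation of replicate labels (all
#'       \eqn{\binom{n_A+n_B}{n_A}} splits; at 3 + 3 replicates the smallest
#'       attainable two-sided p is 0.1), statistic = difference of group
#'       means.}
#'     \item{both}{runs both; a gene's p and q are the larger of the two, so
#'       the intersection is never more permissive than either test alone.}
#'   }
#' @return Tibble with one row per gene: `gene`, `comparison`, `mean_a`,
#'   `mean_b` (normalized phase means), `log2FC` (pseudo-count 1), `p`, `q`
#'   (BH across genes), `direction` (phase with the higher mean, `"none"` for
#'   ties) and `untestable` (all-zero rows, reported with p = 1).
#' @export
test_de <- function(study, phase_a, phase_b,
                    method = c("nb_wald", "rank_perm", "both")) {
  method <- match.arg(method)
  stop_if_not(inherits(study, "expression_study"), "`study` must be an expression_study")
  stop_if_not(all(c(phase_a, phase_b) %in% study$phases),
              "phases must exist in the study")
  a_ids <- phase_samples(study, phase_a)
  b_ids <- phase_samples(study, phase_b)
  stop_if_not(length(a_ids) >= 2 && length(b_ids) >= 2,
              "both phases need >= 2 replicates")
  xa <- study$normalized[, a_ids, drop = FALSE]
  xb <- study$normalized[, b_ids, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  untestable <- ma == 0 & mb == 0
  p_wald <- p_perm <- NULL
  if (method %in% c("nb_wald", "both")) p_wald <- nb_wald_p(xa, xb)
  if (method %in% c("rank_perm", "both")) p_perm <- perm_p(xa, xb)
  res <- switch(method,
    nb_wald = list(p = p_wald, q = bh_adjust(p_wald)),
    rank_perm = list(p = p_perm, q = bh_adjust(p_perm)),
    both = list(p = pmax(p_wald, p_perm),
                q = pmax(bh_adjust(p_wald), bh_adjust(p_perm))))
  p <- ifelse(untestable, 1, res$p)
  q <- ifelse(untestable, 1, pmax(res$q, res$p))
  log2fc <- log2((mb + 1) / (ma + 1))
  tibble::tibble(
    gene = rownames(study$normalized),
    comparison = paste0(phase_a, "_vs_", phase_b),
    mean_a = unname(ma), mean_b = unname(mb), log2FC = unname(log2fc),
    p = unname(p), q = unname(q),
    direction = dplyr::case_when(log2fc > 0 ~ phase_b,
                                 log2fc < 0 ~ phase_a,
                                 TRUE ~ "none"),
    untestable = untestable)
}

# NB Wald two-tailed p per gene (rows), delta-method variance on log means.
nb_wald_p <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  # pooled method-of-moments dispersion, floored at 0
  disp_of <- function(m, v) ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  alpha <- (disp_of(ma, va) * (na - 1) + disp_of(mb, vb) * (nb - 1)) /
    (na + nb - 2)
  lfc <- log(mb + 1) - log(ma + 1)
  se2 <- (1 / (ma + 1) + alpha) / na + (1 / (mb + 1) + alpha) / nb
  z <- lfc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  ifelse(is.finite(p), p, 1)
}

# exact two-sided permutation p on the difference of group means
perm_p <- function(xa, xb) {
  x <- cbind(xa, xb)
  na <- ncol(xa); ntot <- ncol(x)
  splits <- combn(ntot, na)
  obs <- abs(rowMeans(xb) - rowMeans(xa))
  stat <- apply(splits, 2, function(idx) {
    abs(rowMeans(x[, -idx, drop = FALSE]) - rowMeans(x[, idx, drop = FALSE]))
  })
  if (is.null(dim(stat))) stat <- matrix(stat, nrow = 1)
  rowMeans(stat >= obs - 1e-12)
}

#' Filter DE records with the study thresholds
#'
#' A record is kept iff `q < q_max`, `|log2FC| >= min_abs_log2fc` and the
#' larger of the two normalized phase means is at least `min_abundance`
#' (the FPKM-like abundance floor). Fold-change and abundance bounds are
#' inclusive; the q bound is strict, matching the stated thresholds
#' (q-value < 0.05, |log2FC| >= 1, abundance >= 5).
#'
#' @param records Output of [test_de()] (rows from several comparisons may be
#'   bound together).
#' @param q_max,min_abs_log2fc,min_abundance Thresholds.
#' @return The retained rows.
#' @export
filter_degs <- function(records, q_max = 0.05, min_abs_log2fc = 1,
                        min_abundance = 5) {
  dplyr::filter(records,
                .data$q < q_max,
                abs(.data$log2FC) >= min_abs_log2fc,
                pmax(.data$mean_a, .data$mean_b) >= min_abundance,
                !.data$untestable)
}

#' Summarize DEG membership and upregulation across the three comparisons
#'
#' Builds the Venn partition of the species' DEG universe over the pairwise
#' phase comparisons, and the per-comparison upregulation counts (which phase
#' had the higher mean). Percentages are taken over the DEG universe (all
#' distinct genes significant in at least one comparison).
#'
#' @param degs Filtered DE records ([filter_degs()]) for all pairwise
#'   comparisons of one species, bound by row.
#' @return An `upregulation_summary`: `$universe_size`, `$venn` (tibble
#'   region/count/pct; regions are `&`-joined comparison sets, exhaustive and
#'   disjoint) and `$upregulated` (tibble comparison/up_phase/count/pct).
#' @export
upregulation_summary <- function(degs) {
  comparisons <- sort(unique(degs$comparison))
  universe <- unique(degs$gene)
  n_u <- length(universe)
  venn <- if (n_u == 0) {
    tibble::tibble(region = character(), count = integer(), pct = numeric())
  } else {
    degs |>
      dplyr::distinct(.data$gene, .data$comparison) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(region = paste(sort(unique(.data$comparison)),
                                      collapse = "&"), .groups = "drop") |>
      dplyr::count(.data$region, name = "count") |>
      dplyr::mutate(pct = 100 * .data$count / n_u)
  }
  up <- degs |>
    dplyr::filter(.data$direction != "none") |>
    dplyr::count(.data$comparison, up_phase = .data$direction,
                 name = "count") |>
    dplyr::mutate(pct = if (n_u == 0) 0 else 100 * .data$count / n_u)
  structure(list(universe_size = n_u, venn = venn, upregulated = up),
            class = "upregulation_summary")
}

#' @export
print.upregulation_summary <- function(x, ...) {
  cat(sprintf("<upregulation_summary> DEG universe: %d genes\n",
              x$universe_size))
  print(x$upregulated)
  invisible(x)
}

#' Compare an upregulation category between two species
#'
#' Two-proportion z-test on the count of genes in `category` over each
#' species' DEG universe (the test used to contrast, e.g., the percentage of
#' genes upregulated in pharate adults relative to foragers between species).
#'
#' @param summary_a,summary_b [upregulation_summary()] objects.
#' @param category Either a Venn region (e.g. `"Pbm_vs_Ne"`) or an
#'   upregulation category written `"comparison:up_phase"`
#'   (e.g. `"Pbm_vs_Fg:Pbm"`).
#' @return A one-row tibble with `z` and `p`.
#' @export
compare_proportions <- function(summary_a, summary_b, category) {
  k <- function(s) {
    if (grepl(":", category, fixed = TRUE)) {
      parts <- strsplit(category, ":", fixed = TRUE)[[1]]
      row <- dplyr::filter(s$upregulated, .data$comparison == parts[1],
                           .data$up_phase == parts[2])
    } else {
      row <- dplyr::filter(s$venn, .data$region == category)
    }
    if (nrow(row) == 0) 0L else row$count[[1]]
  }
  two_proportion_z(k(summary_a), summary_a$universe_size,
                   k(summary_b), summary_b$universe_size)
}
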