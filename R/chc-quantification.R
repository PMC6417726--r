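# Cuticular hydrocarbon quantification: relative (percent-area) profiles,
# internal-standard calibration, absolute ug/bee amounts, phase tests and
# PCA of the percent profiles.

check_peak_table <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  need <- c("individual_id", "phase", "compound_id", "class", "carbon_n",
            "area", "is_area")
  stop_if_not(all(need %in% names(peaks)),
              "peak table needs columns: %s", paste(need, collapse = ", "))
  stop_if_not(all(peaks$area >= 0), "peak areas must be >= 0")
  stop_if_not(all(peaks$is_area > 0), "internal-standard areas must be > 0")
  dup <- peaks |>
    dplyr::count(.data$individual_id, .data$compound_id) |>
    dplyr::filter(.data$n > 1)
  stop_if_not(nrow(dup) == 0, "duplicate (individual, compound) rows")
  peaks
}

#' Percent-area normalization of CHC peaks
#'
#' Converts each individual's peak areas to percentages of its total signal.
#' `scope = "all"` normalizes over all compounds of the individual;
#' `scope = "per_class"` repeats the normalization within each compound
#' class (n-alkanes, unsaturated, branched), so percentages sum to 100
#' within every class.
#'
#' @param peaks Peak table (see [generate_chc()] for the column contract).
#' @param scope `"all"` or `"per_class"`.
#' @return The peak table with a `pct` column added.
#' @export
normalize_relative <- function(peaks, scope = c("all", "per_class")) {
  scope <- match.arg(scope)
  peaks <- check_peak_table(peaks)
  grp <- if (scope == "all") "individual_id" else c("individual_id", "class")
  peaks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(pct = 100 * .data$area / sum(.data$area)) |>
    dplyr::ungroup()
}

#' Fit internal-standard calibration curves
#'
#' For each external standard (C23, C25, C32), ordinary least squares of the
#' known amount on the analyte/internal-standard area ratio:
#' `amount = a * ratio + b`. The fit's Pearson correlation R is the
#' curve-quality figure (values of at least 0.99 are the conventional
#' acceptance bar).
#'
#' @param standards Tibble with columns `standard_id`, `level_ug_ml`,
#'   `area`, `is_area`; at least 3 levels per standard.
#' @return A `calibration_curves` tibble: `standard_id`, `slope`,
#'   `intercept`, `r_value`, `n`, `level_min`, `level_max`.
#' @export
fit_calibration <- function(standards) {
  standards <- tibble::as_tibble(standards)
  need <- c("standard_id", "level_ug_ml", "area", "is_area")
  stop_if_not(all(need %in% names(standards)),
              "standards need columns: %s", paste(need, collapse = ", "))
  out <- standards |>
    dplyr::group_by(.data$standard_id) |>
    dplyr::group_modify(function(d, key) {
      stop_if_not(nrow(d) >= 3L, "need >= 3 levels per standard")
      ratio <- d$area / d$is_area
      stop_if_not(sd(ratio) > 0, "zero-variance area ratios")
      fit <- lm(d$level_ug_ml ~ ratio)
      tibble::tibble(slope = unname(coef(fit)[2]),
                     intercept = unname(coef(fit)[1]),
                     r_value = cor(ratio, d$level_ug_ml),
                     n = nrow(d),
                     level_min = min(d$level_ug_ml),
                     level_max = max(d$level_ug_ml))
    }) |>
    dplyr::ungroup()
  class(out) <- c("calibration_curves", class(out))
  out
}

#' @method glance calibration_curves
#' @export
glance.calibration_curves <- function(x, ...) {
  tibble::tibble(n_curves = nrow(x), min_r = min(x$r_value),
                 all_acceptable = all(x$r_value >= 0.99))
}

#' Assign the calibration curve for a chain length
#'
#' Compounds up to C24 use the C23 curve; C25 through C29 the C25 curve;
#' above C29 up to C35 the C32 curve.
#'
#' @param carbon_n Integer vector of carbon numbers, each within \[20, 35\].
#' @return Character vector of standard ids (`"C23"`, `"C25"`, `"C32"`).
#' @examples
#' assign_curve(c(24, 25, 29, 30))
#' @export
assign_curve <- function(carbon_n) {
  stop_if_not(all(is.finite(carbon_n)), "carbon numbers must be numeric")
  stop_if_not(all(carbon_n >= 20 & carbon_n <= 35),
              "carbon number outside [20, 35]: no assignable curve")
  ifelse(carbon_n <= 24, "C23", ifelse(carbon_n <= 29, "C25", "C32"))
}

#' Absolute CHC quantification in ug per bee
#'
#' Inverse prediction through the assigned calibration curve:
#' `conc = a * (area / is_area) + b` (ug/ml), scaled by the extract volume
#' and divided by the pool size to give ug per bee. Negative predictions
#' (area below the calibration background) are clamped to 0 with a warning
#' and flagged `below_quantification`.
#'
#' @param peaks Peak table.
#' @param curves A [fit_calibration()] result.
#' @param pool_size Bees per extract (1, or 3 for pooled extracts; per-bee
#'   values are the pooled amounts divided by this).
#' @param extract_volume_ml Extract resuspension volume in ml.
#' @return Tibble: individual_id, phase, compound_id, class, carbon_n,
#'   standard_id, `amount_ug` (per bee) and `below_quantification`.
#' @export
absolute_quantify <- function(peaks, curves, pool_size = 1,
                              extract_volume_ml = 0.160) {
  peaks <- check_peak_table(peaks)
  pool_size <- check_count(pool_size, "pool_size", min = 1L)
  check_number(extract_volume_ml, "extract_volume_ml", min = 1e-6)
  stop_if_not(inherits(curves, "calibration_curves"),
              "`curves` must come from fit_calibration()")
  out <- peaks |>
    dplyr::mutate(standard_id = assign_curve(.data$carbon_n)) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(curves), "standard_id", "slope",
                    "intercept"),
      by = "standard_id") |>
    dplyr::mutate(
      conc = .data$slope * (.data$area / .data$is_area) + .data$intercept,
      amount_raw = .data$conc * extract_volume_ml / pool_size,
      below_quantification = .data$amount_raw < 0,
      amount_ug = pmax(.data$amount_raw, 0)) |>
    dplyr::select("individual_id", "phase", "compound_id", "class",
                  "carbon_n", "standard_id", "amount_ug",
                  "below_quantification")
  if (any(out$below_quantification)) {
    warn(sprintf("%d peak(s) predicted below the calibration background; clamped to 0",
                 sum(out$below_quantification)))
  }
  out
}

#' Per-class absolute totals
#'
#' Sums the per-bee compound amounts within the n-alkane and unsaturated
#' classes for every individual (the class-level quantities compared across
#' phases).
#'
#' @param amounts An [absolute_quantify()] result.
#' @param classes Classes to total (default n_alkane and unsaturated).
#' @return Tibble individual_id/phase/class/total_ug.
#' @export
chc_class_totals <- function(amounts,
                             classes = c("n_alkane", "unsaturated")) {
  amounts |>
    dplyr::filter(.data$class %in% classes) |>
    dplyr::group_by(.data$individual_id, .data$phase, .data$class) |>
    dplyr::summarise(total_ug = sum(.data$amount_ug), .groups = "drop")
}

#' Phase comparison of each CHC peak's relative abundance
#'
#' ANOVA + Tukey HSD ([anova_tukey()]) of the percent area across
#' developmental phases, one test per compound.
#'
#' @param rel_table A [normalize_relative()] result.
#' @param alpha Significance level for the letters.
#' @return Tibble compound_id/phase/letter; the full `pairwise_letters`
#'   objects are attached as the `tests` attribute (named by compound).
#' @export
per_peak_phase_test <- function(rel_table, alpha = 0.05) {
  split_tests(rel_table, "compound_id", "pct", alpha)
}

#' Phase comparison of per-class absolute quantities
#'
#' @param class_totals A [chc_class_totals()] result.
#' @param alpha Significance level.
#' @return Tibble class/phase/letter with the `tests` attribute as in
#'   [per_peak_phase_test()].
#' @export
per_class_phase_test <- function(class_totals, alpha = 0.05) {
  split_tests(class_totals, "class", "total_ug", alpha)
}

split_tests <- function(data, by, value_col, alpha) {
  keys <- unique(data[[by]])
  tests <- list()
  rows <- lapply(keys, function(k) {
    d <- data[data[[by]] == k, ]
    pl <- anova_tukey_vec(d[[value_col]], as.character(d$phase), alpha = alpha)
    tests[[k]] <<- pl
    tibble::tibble(!!by := k, phase = pl$letters$group,
                   letter = pl$letters$letter)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tests") <- tests
  out
}

#' PCA of percent CHC profiles
#'
#' Column-centered principal component analysis of the individuals-by-
#' compounds percent matrix: which compounds drive the separation between
#' phases.
#'
#' @param rel_table A [normalize_relative()] result (scope `"all"`).
#' @return A `chc_pca` object: `$scores` (tibble individual_id/phase/PCs),
#'   `$loadings` (tibble compound_id/component/loading, ranked by absolute
#'   loading within each component), `$var_explained` (fractions summing
#'   to 1) and the underlying `prcomp` fit.
#' @export
pca_loadings <- function(rel_table) {
  wide <- rel_table |>
    dplyr::select("individual_id", "phase", "compound_id", "pct") |>
    tidyr::pivot_wider(names_from = "compound_id", values_from = "pct")
  m <- as.matrix(wide[, -(1:2)])
  rownames(m) <- wide$individual_id
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  loadings <- tibble::as_tibble(fit$rotation, rownames = "compound_id") |>
    tidyr::pivot_longer(-"compound_id", names_to = "component",
                        values_to = "loading") |>
    dplyr::arrange(.data$component, dplyr::desc(abs(.data$loading)))
  scores <- dplyr::bind_cols(wide[, 1:2], tibble::as_tibble(fit$x))
  structure(list(scores = scores, loadings = loadings, var_explained = ve,
                 prcomp = fit),
            class = "chc_pca")
}

#' @export
print.chc_pca <- function(x, ...) {
  cat(sprintf("<chc_pca> %d individuals, %d components; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), length(x$var_explained),
              100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], 0)))
  invisible(x)
}

#' @method tidy chc_pca
#' @export
tidy.chc_pca <- function(x, ...) x$loadings

#' @method glance chc_pca
#' @export
glance.chc_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$var_explained)),
                 var_explained = x$var_explained)
}
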