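# Cuticle-thickness comparison across developmental phases.
#
# Decision tree: exactly two phases -> Student's t-test; three or more ->
# Shapiro-Wilk on the pooled per-phase-demeaned residuals decides between
# parametric (ANOVA + Tukey HSD) and rank-based (Kruskal-Wallis +
# Conover-Iman + Bonferroni) branches.

check_thickness <- function(data) {
  data <- tibble::as_tibble(data)
  stop_if_not(all(c("phase", "thickness_um") %in% names(data)),
              "thickness data needs columns `phase` and `thickness_um`")
  stop_if_not(all(data$thickness_um > 0), "measurements must be positive")
  ns <- table(data$phase)
  stop_if_not(length(ns) >= 2L, "need at least 2 phases")
  stop_if_not(all(ns >= 2L), "need at least 2 measurements per phase")
  data
}

#' Choose the thickness-comparison branch
#'
#' @param data Tibble with columns `phase` and `thickness_um`.
#' @param alpha Normality-gate level for the Shapiro-Wilk test.
#' @return `"students_t"` (two phases), `"anova_tukey"` (residuals pass the
#'   normality gate) or `"kruskal_conover"`.
#' @export
choose_test <- function(data, alpha = 0.05) {
  data <- check_thickness(data)
  if (length(unique(data$phase)) == 2L) return("students_t")
  resid <- data |>
    dplyr::group_by(.data$phase) |>
    dplyr::mutate(r = .data$thickness_um - mean(.data$thickness_um)) |>
    dplyr::pull(.data$r)
  stop_if_not(sd(resid) > 0, "constant measurements: normality gate undefined")
  if (shapiro_wilk(resid)$p >= alpha) "anova_tukey" else "kruskal_conover"
}

#' Compare cuticle thickness across developmental phases
#'
#' Runs the branch selected by [choose_test()] and encodes the all-pairs
#' outcome as a compact-letter display (phases sharing a letter do not
#' differ at `alpha`).
#'
#' @inheritParams choose_test
#' @return A `phase_comparison`: `$branch`, `$letters` (a
#'   [anova_tukey()]-style `pairwise_letters` object) and `$shapiro` (the
#'   gate result, `NULL` for the two-phase branch).
#' @export
compare_phases <- function(data, alpha = 0.05) {
  data <- check_thickness(data)
  branch <- choose_test(data, alpha = alpha)
  phases <- unique(as.character(data$phase))
  shapiro <- NULL
  if (branch == "students_t") {
    a <- data$thickness_um[data$phase == phases[1]]
    b <- data$thickness_um[data$phase == phases[2]]
    tt <- students_t(a, b)
    pmat <- pair_matrix(paste(phases[2], phases[1], sep = "-"), tt$p, phases)
    letters <- cld_letters(pmat, alpha = alpha)
    pl <- new_pairwise_letters(
      letters, pmat,
      tibble::tibble(statistic = tt$t, df1 = tt$df, df2 = NA_real_,
                     p = tt$p, method = "Student's t"),
      alpha, "Student's t")
  } else {
    resid <- data |>
      dplyr::group_by(.data$phase) |>
      dplyr::mutate(r = .data$thickness_um - mean(.data$thickness_um)) |>
      dplyr::pull(.data$r)
    shapiro <- shapiro_wilk(resid)
    pl <- if (branch == "anova_tukey") {
      anova_tukey_vec(data$thickness_um, as.character(data$phase), alpha)
    } else {
      kruskal_conover_vec(data$thickness_um, as.character(data$phase), alpha)
    }
  }
  structure(list(branch = branch, letters = pl, shapiro = shapiro,
                 alpha = alpha),
            class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("<phase_comparison> branch: %s\n", x$branch))
  print(x$letters)
  invisible(x)
}

#' @method tidy phase_comparison
#' @export
tidy.phase_comparison <- function(x, ...) x$letters$letters

#' @method glance phase_comparison
#' @export
glance.phase_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(branch = x$branch), x$letters$omnibus,
                   tibble::tibble(shapiro_p = if (is.null(x$shapiro)) NA_real_
                                  else x$shapiro$p))
}
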