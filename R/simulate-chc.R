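# Synthetic GC-MS cuticular-hydrocarbon data. Peak areas are generated by
# inverting a known internal-standard calibration (amount -> area ratio ->
# area) and multiplying lognormal noise, so that the quantification stage
# can be tested as an exact round trip at zero noise.

default_compound_roster <- function() {
  tibble::tibble(
    compound_id = c("C23", "C25", "C27", "C29", "C31",
                    "C27:1", "C29:1", "11-MeC27"),
    class = c(rep("n_alkane", 5), "unsaturated", "unsaturated", "branched"),
    carbon_n = c(23, 25, 27, 29, 31, 27, 29, 28))
}

# Per-bee true amounts (ug). Foragers carry a few-fold more n-alkane and
# several-fold more unsaturated CHC than the earlier phases while branched
# alkanes stay level — the magnitudes reported for eusocial workers (total
# n-alkanes roughly doubling and unsaturated CHC rising ~7x by the forager
# phase), which also shifts the percent composition so that relative
# profiles separate foragers.
default_true_amounts <- function(roster, phases = c("Pbm", "Ne", "Fg")) {
  base <- setNames(c(2, 2.5, 3, 1.5, 1, 0.4, 0.5, 2), roster$compound_id)
  mult <- rbind(n_alkane = c(1, 1.2, 2.5),
                unsaturated = c(1, 1.5, 7),
                branched = c(1, 1, 1))[, seq_along(phases), drop = FALSE]
  colnames(mult) <- phases
  cls <- setNames(roster$class, roster$compound_id)
  tidyr::expand_grid(compound_id = roster$compound_id, phase = phases) |>
    dplyr::mutate(amount_ug = base[.data$compound_id] *
                    mult[cbind(cls[.data$compound_id], .data$phase)])
}

#' Configuration for the CHC simulator
#'
#' @param n_per_phase Named integer vector of individuals (or pools) sampled
#'   per phase. Defaults to the eusocial design, 15 bees per phase; use
#'   `c(Pbm = 4, Ne = 7, Fg = 7)` for the solitary-species design.
#' @param roster Compound roster: tibble with `compound_id`,
#'   `class` (`n_alkane`, `unsaturated` or `branched`) and `carbon_n`
#'   (chain length, within 20-35 so a calibration curve is assignable).
#' @param true_amounts Tibble `compound_id`/`phase`/`amount_ug`: true per-bee
#'   amounts planted in the data.
#' @param standard_levels Concentrations of the external n-alkane standard
#'   series in ug/ml, strictly increasing.
#' @param true_slope,true_intercept Named per-standard-curve (C23/C25/C32)
#'   parameters of the true calibration line amount = a * ratio + b.
#' @param is_area Internal-standard (alpha-cholestane) peak area planted in
#'   every run.
#' @param noise_cv Multiplicative lognormal noise coefficient of variation
#'   applied to analyte areas (0 = noise-free).
#' @param pool_size Bees per extract (1, or 3 for the small-bodied species
#'   whose extracts pool three individuals).
#' @param extract_volume_ml Resuspension volume of the extract in ml
#'   (0.160 default; 0.100 for the pooled species).
#' @param phases Ordered phase labels.
#' @param seed Integer seed.
#' @return A validated `chc_sim_config` list.
#' @export
chc_sim_config <- function(n_per_phase = c(Pbm = 15, Ne = 15, Fg = 15),
                           roster = default_compound_roster(),
                           true_amounts = NULL,
                           standard_levels = c(1.25, 2.5, 5, 10, 15, 20),
                           true_slope = c(C23 = 0.5, C25 = 0.6, C32 = 0.8),
                           true_intercept = c(C23 = 0, C25 = 0, C32 = 0),
                           is_area = 1e6,
                           noise_cv = 0.05,
                           pool_size = 1,
                           extract_volume_ml = 0.160,
                           phases = names(n_per_phase),
                           seed = 1L) {
  stop_if_not(length(n_per_phase) >= 2L && all(n_per_phase >= 2),
              "need at least 2 phases with >= 2 individuals each")
  stop_if_not(all(diff(standard_levels) > 0) && all(standard_levels > 0),
              "standard levels must be positive and strictly increasing")
  check_number(noise_cv, "noise_cv", min = 0)
  pool_size <- check_count(pool_size, "pool_size", min = 1L)
  check_number(is_area, "is_area", min = 1e-12)
  check_number(extract_volume_ml, "extract_volume_ml", min = 1e-6)
  roster <- tibble::as_tibble(roster)
  stop_if_not(all(c("compound_id", "class", "carbon_n") %in% names(roster)),
              "roster needs compound_id, class, carbon_n")
  stop_if_not(all(roster$carbon_n >= 20 & roster$carbon_n <= 35),
              "compound carbon numbers must lie in [20, 35] (no assignable curve otherwise)")
  stop_if_not(all(roster$class %in% c("n_alkane", "unsaturated", "branched")),
              "unknown compound class")
  stop_if_not(setequal(names(true_slope), c("C23", "C25", "C32")) &&
                setequal(names(true_intercept), c("C23", "C25", "C32")),
              "true calibration needs the C23, C25 and C32 curves")
  true_amounts <- true_amounts %||% default_true_amounts(roster, phases)
  stop_if_not(
    nrow(dplyr::anti_join(
      tidyr::expand_grid(compound_id = roster$compound_id, phase = phases),
      true_amounts, by = c("compound_id", "phase"))) == 0,
    "true_amounts must cover every compound x phase")
  structure(
    list(n_per_phase = n_per_phase, roster = roster,
         true_amounts = tibble::as_tibble(true_amounts),
         standard_levels = standard_levels, true_slope = true_slope,
         true_intercept = true_intercept, is_area = is_area,
         noise_cv = noise_cv, pool_size = pool_size,
         extract_volume_ml = extract_volume_ml, phases = phases,
         seed = as.integer(seed)),
    class = "chc_sim_config")
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Generate a seeded synthetic CHC dataset
#'
#' Produces a per-individual peak table, an external standard series and the
#' planted ground truth. Analyte areas follow the inverse of the true
#' calibration: `area/IS = (conc - b)/a`, where the extract concentration is
#' `amount_ug * pool_size / extract_volume_ml` and `a`, `b` belong to the
#' curve assigned by chain length ([assign_curve()]).
#'
#' @param config A [chc_sim_config()].
#' @return List with `peaks` (tibble: individual_id, phase, compound_id,
#'   class, carbon_n, area, is_area), `standards` (tibble: standard_id,
#'   level_ug_ml, area, is_area) and `truth` (the per-bee true amounts,
#'   tibble compound_id/phase/amount_ug).
#' @examples
#' sim <- generate_chc(chc_sim_config(noise_cv = 0, seed = 3))
#' head(sim$peaks)
#' @export
generate_chc <- function(config) {
  stop_if_not(inherits(config, "chc_sim_config"),
              "`config` must come from chc_sim_config()")
  with_seed_if(config$seed, {
    curves <- assign_curve(config$roster$carbon_n)
    roster <- dplyr::mutate(config$roster, standard_id = curves)
    indiv <- tibble::tibble(
      phase = rep(config$phases, config$n_per_phase[config$phases]),
      individual_id = unlist(lapply(config$phases, function(ph) {
        sprintf("%s_%02d", ph, seq_len(config$n_per_phase[[ph]]))
      })))
    peaks <- tidyr::expand_grid(indiv, roster) |>
      dplyr::inner_join(config$true_amounts, by = c("compound_id", "phase")) |>
      dplyr::mutate(
        conc = .data$amount_ug * config$pool_size / config$extract_volume_ml,
        ratio = (.data$conc - config$true_intercept[.data$standard_id]) /
          config$true_slope[.data$standard_id],
        area = .data$ratio * config$is_area *
          lognormal_noise(dplyr::n(), config$noise_cv),
        is_area = config$is_area) |>
      dplyr::select("individual_id", "phase", "compound_id", "class",
                    "carbon_n", "area", "is_area")
    standards <- tidyr::expand_grid(
      standard_id = names(config$true_slope),
      level_ug_ml = config$standard_levels) |>
      dplyr::mutate(
        ratio = (.data$level_ug_ml - config$true_intercept[.data$standard_id]) /
          config$true_slope[.data$standard_id],
        area = .data$ratio * config$is_area *
          lognormal_noise(dplyr::n(), config$noise_cv),
        is_area = config$is_area) |>
      dplyr::select("standard_id", "level_ug_ml", "area", "is_area")
    list(peaks = peaks, standards = standards, truth = config$true_amounts)
  })
}

#' Generate synthetic cuticle-thickness measurements
#'
#' Per-phase samples from a normal or lognormal family targeted at the
#' requested mean and standard deviation (the lognormal is re-parameterized
#' so its arithmetic moments match).
#'
#' @param phases Phase labels.
#' @param means,sds Target mean and SD per phase (recycled if scalar), in um.
#' @param family `"normal"` or `"lognormal"`.
#' @param n Measurements per phase (>= 2), recycled if scalar.
#' @param seed Integer seed.
#' @return Tibble with columns `phase` and `thickness_um`.
#' @examples
#' generate_thickness(c("Pbm", "Ne", "Fg"), means = c(2, 2, 5), sds = 0.3,
#'                    n = 10, seed = 1)
#' @export
generate_thickness <- function(phases, means, sds,
                               family = c("normal", "lognormal"),
                               n = 10, seed = NULL) {
  family <- match.arg(family)
  k <- length(phases)
  means <- rep_len(means, k); sds <- rep_len(sds, k); n <- rep_len(n, k)
  stop_if_not(all(n >= 2), "need n >= 2 measurements per phase")
  stop_if_not(all(means > 0) && all(sds >= 0), "means must be > 0, sds >= 0")
  with_seed_if(seed, {
    vals <- lapply(seq_len(k), function(i) {
      if (sds[i] == 0) return(rep(means[i], n[i]))
      if (family == "normal") {
        rnorm(n[i], means[i], sds[i])
      } else {
        sdlog <- sqrt(log(1 + (sds[i] / means[i])^2))
        rlnorm(n[i], meanlog = log(means[i]) - sdlog^2 / 2, sdlog = sdlog)
      }
    })
    tibble::tibble(phase = rep(phases, vapply(vals, length, integer(1))),
                   thickness_um = unlist(vals))
  })
}
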