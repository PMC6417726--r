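# Synthetic three-species expression data with planted cross-species
# profile classes. The design mirrors the comparative study the package
# serves: 3 species (two eusocial, one solitary) x 3 developmental phases
# (Pbm pharate adult, Ne newly emerged, Fg forager) x 3 replicates, each
# replicate a pooled-integument RNA-seq library.

#' Configuration for the expression simulator
#'
#' Planted profile classes (fractions of `n_genes`):
#' \describe{
#'   \item{eusocial_heterochronic}{both eusocial species share one phase
#'     profile; the solitary species carries an inverted (default) or flat
#'     profile — the heterochrony signature.}
#'   \item{all_shared}{all three species share the profile.}
#'   \item{solitary_shifted}{the solitary species shares the profile with
#'     eusocial species 1 only; species 2 peaks in a different phase.}
#'   \item{species_specific}{only species 1 carries the profile; the others
#'     are flat.}
#'   \item{flat}{identical means across phases in every species.}
#' }
#' Default fractions mirror the composition of a curated developmental-gene
#' panel in which roughly a fifth of orthologs carry the eusocial-shared
#' signature and a quarter show no phase structure.
#'
#' @param n_genes Number of genes per species.
#' @param species Species identifiers; species 1-2 are the eusocial pair,
#'   species 3 the solitary outgroup.
#' @param phases Ordered developmental phase labels.
#' @param n_reps Replicates per phase (>= 2).
#' @param baseline_mean Expected count of an unregulated gene.
#' @param dispersion Negative-binomial dispersion \eqn{\alpha} in the
#'   mean-dispersion parameterization (variance \eqn{\mu + \alpha\mu^2});
#'   0 yields deterministic counts equal to the class means.
#' @param fold_change Planted effect multiplier between extreme phases.
#' @param class_fractions Named fractions over the five classes, summing to 1.
#' @param solitary_profile `"inverted"` or `"flat"`: shape of the solitary
#'   species' profile for `eusocial_heterochronic` genes.
#' @param ortholog_dropout Fraction of solitary-species ortholog-map entries
#'   dropped (simulating transcripts not identified in that species).
#' @param seed Integer seed; required for reproducible generation.
#' @return A validated `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  species = c("Am", "Fv", "Ca"),
                                  phases = c("Pbm", "Ne", "Fg"),
                                  n_reps = 3,
                                  baseline_mean = 500,
                                  dispersion = 0.1,
                                  fold_change = 4,
                                  class_fractions = c(
                                    eusocial_heterochronic = 0.20,
                                    all_shared = 0.25,
                                    solitary_shifted = 0.20,
                                    species_specific = 0.10,
                                    flat = 0.25),
                                  solitary_profile = c("inverted", "flat"),
                                  ortholog_dropout = 0,
                                  seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_reps <- check_count(n_reps, "n_reps", min = 2L)
  check_number(baseline_mean, "baseline_mean", min = 1)
  check_number(dispersion, "dispersion", min = 0)
  check_number(fold_change, "fold_change", min = 1)
  check_number(ortholog_dropout, "ortholog_dropout", 0, 1)
  stop_if_not(length(species) == 3L, "exactly 3 species are modelled")
  stop_if_not(length(phases) >= 2L, "need at least 2 phases")
  cls <- c("eusocial_heterochronic", "all_shared", "solitary_shifted",
           "species_specific", "flat")
  stop_if_not(setequal(names(class_fractions), cls),
              "class_fractions must name exactly the five classes")
  class_fractions <- class_fractions[cls]
  stop_if_not(all(class_fractions >= 0) &&
                abs(sum(class_fractions) - 1) < 1e-9,
              "class fractions must be >= 0 and sum to 1")
  structure(
    list(n_genes = n_genes, species = species, phases = phases,
         n_reps = n_reps, baseline_mean = baseline_mean,
         dispersion = dispersion, fold_change = fold_change,
         class_fractions = class_fractions,
         solitary_profile = match.arg(solitary_profile),
         ortholog_dropout = ortholog_dropout, seed = as.integer(seed)),
    class = "expression_sim_config")
}

# Per-phase mean multipliers for one (class, species slot, direction).
# Direction alternates gene by gene (+1 = high early / declining, -1 =
# rising toward the forager phase) so that planted regulation is balanced in
# both directions, as in real integument data (cuticle-construction genes up
# early, chemoreception/detox genes up in foragers). Balance keeps library
# sizes comparable across phases, so per-million scaling does not imprint a
# spurious shared profile on unregulated genes.
class_profile <- function(config, class, slot, direction) {
  fc <- config$fold_change
  np <- length(config$phases)
  # a profile and its opposite direction are additive complements
  # (p and max+min-p), so +/- gene pairs sum to a phase-constant total and
  # planted regulation cancels out of the library sizes
  flip <- function(p, d) if (d > 0) p else max(p) + min(p) - p
  ramp <- function(d) flip(exp(seq(log(fc), log(1 / fc), length.out = np)), d)
  mid_peak <- function(d) {
    p <- rep(1, np); p[ceiling(np / 2)] <- fc
    flip(p, d)
  }
  flat <- rep(1, np)
  solitary <- switch(config$solitary_profile,
                     inverted = ramp(-direction), flat = flat)
  switch(class,
    eusocial_heterochronic = list(ramp(direction), ramp(direction), solitary),
    all_shared = list(ramp(direction), ramp(direction), ramp(direction)),
    solitary_shifted = list(ramp(direction), mid_peak(direction),
                            ramp(direction)),
    species_specific = list(ramp(direction), flat, flat),
    flat = list(flat, flat, flat))[[slot]]
}

expected_pattern_label <- function(class, solitary_profile) {
  unname(c(eusocial_heterochronic = "EUSOCIAL_SHARED",
           all_shared = "ALL_SHARED",
           solitary_shifted = "AM_CA_SHARED",
           species_specific = "NONE",
           flat = "NONE")[class])
}

#' Generate a seeded synthetic three-species expression study
#'
#' Draws negative-binomial counts around class-determined phase means for
#' each of three species, together with a cross-species ortholog map (with
#' optional dropout of solitary-species entries) and a ground-truth table of
#' planted classes.
#'
#' @param config An [expression_sim_config()].
#' @return A list with `studies` (named list of [expression_study()]
#'   objects), `ortholog_map` (tibble, one id column per species, `NA` =
#'   absent) and `truth` (tibble: `ortholog`, per-species gene ids, `class`,
#'   `expected_label`).
#' @examples
#' sim <- generate_expression(expression_sim_config(n_genes = 50, seed = 7))
#' sim$studies$Am
#' @export
generate_expression <- function(config) {
  stop_if_not(inherits(config, "expression_sim_config"),
              "`config` must come from expression_sim_config()")
  with_seed_if(config$seed, {
    n <- config$n_genes
    counts_per_class <- round(config$class_fractions * n)
    # rounding can drift by a gene or two; pad/trim the largest class
    drift <- n - sum(counts_per_class)
    counts_per_class[which.max(counts_per_class)] <-
      counts_per_class[which.max(counts_per_class)] + drift
    class_of <- rep(names(counts_per_class), counts_per_class)
    direction <- rep_len(c(1, -1), n)  # balanced regulation directions
    np <- length(config$phases); nr <- config$n_reps
    sample_meta <- tibble::tibble(
      sample_id = paste0(rep(config$phases, each = nr), "_", rep(seq_len(nr), np)),
      phase = rep(config$phases, each = nr),
      replicate = rep(seq_len(nr), np))
    ortholog <- sprintf("OG%05d", seq_len(n))
    studies <- list()
    for (s in seq_along(config$species)) {
      sp <- config$species[s]
      gene_ids <- paste0(sp, "_", ortholog)
      mu <- t(vapply(seq_len(n), function(gi) {
        rep(class_profile(config, class_of[gi], s, direction[gi]) *
              config$baseline_mean, each = nr)
      }, numeric(np * nr)))
      cnt <- if (config$dispersion == 0) {
        round(mu)
      } else {
        matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
               nrow = n)
      }
      dimnames(cnt) <- list(gene_ids, sample_meta$sample_id)
      studies[[sp]] <- expression_study(cnt, sample_meta, species = sp,
                                        phases = config$phases)
    }
    map <- tibble::tibble(!!config$species[1] := paste0(config$species[1], "_", ortholog),
                          !!config$species[2] := paste0(config$species[2], "_", ortholog),
                          !!config$species[3] := paste0(config$species[3], "_", ortholog))
    if (config$ortholog_dropout > 0) {
      drop <- sample.int(n, size = round(config$ortholog_dropout * n))
      map[[config$species[3]]][drop] <- NA_character_
    }
    truth <- tibble::tibble(
      ortholog = ortholog, class = class_of,
      expected_label = ifelse(
        is.na(map[[config$species[3]]]) & class_of == "eusocial_heterochronic",
        "EUSOCIAL_SHARED_SOLITARY_ABSENT",
        vapply(class_of, expected_pattern_label, character(1),
               solitary_profile = config$solitary_profile)))
    list(studies = studies, ortholog_map = map, truth = truth)
  })
}
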