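# Cross-species ortholog expression-profile correlation and the
# heterochrony-signature classification.
#
# Each ortholog's replicate-level expression profile (phases in order,
# replicates sorted within phase; length 9 in the 3x3 design) is compared
# between species pairs with Pearson correlation. A pair "passes positively"
# iff r >= r_min and p <= p_max (both bounds inclusive); "negatively or
# non-correlated" is the complement. With 9 paired points the critical |r|
# at p = 0.1 is about 0.58, so the r >= 0.6 and p <= 0.1 thresholds are
# nearly coincident — both are applied.

pattern_labels <- c("EUSOCIAL_SHARED", "EUSOCIAL_SHARED_SOLITARY_ABSENT",
                    "AM_CA_SHARED", "FV_CA_SHARED", "ALL_SHARED", "NONE")

#' Classify a heterochrony pattern from per-pair pass/fail/absent states
#'
#' Pure label function over the three species-pair outcomes. Species 1 and 2
#' are the eusocial pair; species 3 is the solitary outgroup, so
#' `eusocial` is the 1-2 pair, `am_ca` the 1-3 pair and `fv_ca` the 2-3
#' pair. States are `"pass"` (positively correlated at the thresholds),
#' `"fail"` (computed but not passing — including significantly negative),
#' or `"absent"` (a member gene missing, no correlation computable).
#'
#' Rules: all pass = `ALL_SHARED`; eusocial passes with both solitary pairs
#' failing = `EUSOCIAL_SHARED`; eusocial passes with the solitary member
#' absent from both its pairs = `EUSOCIAL_SHARED_SOLITARY_ABSENT` (a failed
#' solitary comparison outweighs an absent one); exactly one
#' solitary-containing pair passes while the eusocial pair does not =
#' `AM_CA_SHARED` / `FV_CA_SHARED`; everything else = `NONE`.
#'
#' @param eusocial,am_ca,fv_ca Pair states, each one of
#'   `"pass"`, `"fail"`, `"absent"`.
#' @return Label string.
#' @export
classify_pattern <- function(eusocial, am_ca, fv_ca) {
  states <- c(eusocial = eusocial, am_ca = am_ca, fv_ca = fv_ca)
  stop_if_not(all(states %in% c("pass", "fail", "absent")),
              "states must be 'pass', 'fail' or 'absent'")
  stop_if_not(!all(states == "absent"), "no computable pair")
  e <- eusocial == "pass"; s1 <- am_ca == "pass"; s2 <- fv_ca == "pass"
  if (e && s1 && s2) return("ALL_SHARED")
  if (e && !s1 && !s2) {
    if (am_ca == "absent" && fv_ca == "absent")
      return("EUSOCIAL_SHARED_SOLITARY_ABSENT")
    return("EUSOCIAL_SHARED")
  }
  if (!e && s1 && !s2) return("AM_CA_SHARED")
  if (!e && !s1 && s2) return("FV_CA_SHARED")
  "NONE"
}

pair_status <- function(r, p, r_min, p_max) {
  if (is.na(r)) return("absent")
  if (r >= r_min && p <= p_max) "pass" else "fail"
}

#' Correlate ortholog expression profiles across species
#'
#' For every ortholog-map row, computes Pearson correlation between the
#' replicate-level profiles ([profile_vector()]) of each species pair with
#' both members present, and classifies the heterochrony pattern
#' ([classify_pattern()]).
#'
#' @param studies Named list of three [expression_study()] objects; names
#'   must match the ortholog-map columns. The first two species are treated
#'   as the eusocial pair, the third as the solitary species.
#' @param ortholog_map Tibble with one gene-id column per species (`NA` =
#'   ortholog absent in that species).
#' @param r_min,p_max Positive-correlation thresholds (defaults 0.6, 0.1;
#'   both inclusive).
#' @param use `"replicates"` (default): pair all replicate-level values by
#'   phase and sorted replicate index; `"phase_means"`: pair the per-phase
#'   means (3 points — note p <= 0.1 then demands |r| close to 1).
#' @return Tibble with one row per map row: species ids, `r_*` and `p_*`
#'   per pair (NA when absent) and `label`.
#' @export
correlate_orthologs <- function(studies, ortholog_map, r_min = 0.6,
                                p_max = 0.1,
                                use = c("replicates", "phase_means")) {
  use <- match.arg(use)
  sp <- names(studies)
  stop_if_not(length(sp) == 3L && all(sp %in% names(ortholog_map)),
              "`studies` must be 3 named studies matching map columns")
  check_number(r_min, "r_min", -1, 1); check_number(p_max, "p_max", 0, 1)
  prof <- function(study, gene) {
    v <- profile_vector(study, gene)
    if (use == "phase_means") {
      ph <- sub("_[0-9]+$", "", names(v))
      v <- tapply(v, factor(ph, levels = unique(ph)), mean)
    }
    as.numeric(v)
  }
  pair_cor <- function(ga, gb, sa, sb) {
    if (is.na(ga) || is.na(gb)) return(c(r = NA_real_, p = NA_real_))
    res <- tryCatch(pearson_test(prof(studies[[sa]], ga),
                                 prof(studies[[sb]], gb)),
                    error = function(e) NULL)
    if (is.null(res)) return(c(r = NA_real_, p = NA_real_))
    c(r = res$r, p = res$p)
  }
  rows <- lapply(seq_len(nrow(ortholog_map)), function(i) {
    g <- vapply(sp, function(s) ortholog_map[[s]][[i]], character(1))
    c12 <- pair_cor(g[1], g[2], sp[1], sp[2])
    c13 <- pair_cor(g[1], g[3], sp[1], sp[3])
    c23 <- pair_cor(g[2], g[3], sp[2], sp[3])
    label <- tryCatch(
      classify_pattern(
        pair_status(c12[["r"]], c12[["p"]], r_min, p_max),
        pair_status(c13[["r"]], c13[["p"]], r_min, p_max),
        pair_status(c23[["r"]], c23[["p"]], r_min, p_max)),
      error = function(e) NA_character_)  # e.g. all profiles constant
    tibble::tibble(!!sp[1] := g[1], !!sp[2] := g[2], !!sp[3] := g[3],
                   r_12 = c12[["r"]], p_12 = c12[["p"]],
                   r_13 = c13[["r"]], p_13 = c13[["p"]],
                   r_23 = c23[["r"]], p_23 = c23[["p"]],
                   label = label)
  })
  dplyr::bind_rows(rows)
}

#' Count heterochrony-pattern calls per label
#'
#' @param calls Output of [correlate_orthologs()] (or any tibble with a
#'   `label` column).
#' @return Tibble `label`/`n` covering all six labels (zeros included);
#'   counts sum to the number of classified calls. Rows whose pattern could
#'   not be computed (`NA` label) are reported in the `n_unclassified`
#'   attribute.
#' @export
pattern_summary <- function(calls) {
  counts <- table(factor(calls$label, levels = pattern_labels))
  out <- tibble::tibble(label = pattern_labels, n = as.integer(counts))
  attr(out, "n_unclassified") <- sum(is.na(calls$label))
  out
}
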