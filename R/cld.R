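#' Compact-letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all groups;
#' for every significant pair, split any letter containing both members into
#' two copies (each missing one member of the pair), then absorb letters that
#' became subsets of others. The result satisfies the display contract both
#' ways: two groups share a letter if and only if their pairwise comparison
#' is non-significant at `alpha`.
#'
#' Letters are assigned deterministically: letter groups are ordered by the
#' first (then second, ...) group index they contain, in the input group
#' order.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group names as
#'   dimnames; the diagonal is ignored.
#' @param alpha Significance level; a pair with `p < alpha` must not share a
#'   letter.
#' @return Tibble with columns `group` and `letter` (a string, possibly of
#'   several letters).
#' @export
cld_letters <- function(p_matrix, alpha = 0.05) {
  groups <- rownames(p_matrix)
  stop_if_not(!is.null(groups) && identical(groups, colnames(p_matrix)),
              "`p_matrix` must have matching row/column group names")
  k <- length(groups)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (is.na(p_matrix[i, j]) || p_matrix[i, j] >= alpha) next
      hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
      if (!any(hit)) next
      split_sets <- unlist(lapply(sets[hit], function(s) {
        list(setdiff(s, i), setdiff(s, j))
      }), recursive = FALSE)
      sets <- c(sets[!hit], split_sets)
      # absorb: drop sets contained in another set
      keep <- vapply(seq_along(sets), function(a) {
        !any(vapply(seq_along(sets), function(b) {
          a != b && all(sets[[a]] %in% sets[[b]]) &&
            (length(sets[[a]]) < length(sets[[b]]) || a > b)
        }, logical(1)))
      }, logical(1))
      sets <- sets[keep]
    }
  }
  sets <- lapply(sets, sort)
  key <- vapply(sets, function(s) paste(sprintf("%04d", s), collapse = ""),
                character(1))
  sets <- sets[order(key)]
  lab <- letters[seq_along(sets)]
  out <- vapply(seq_len(k), function(g) {
    paste0(lab[vapply(sets, function(s) g %in% s, logical(1))], collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letter = out)
}
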