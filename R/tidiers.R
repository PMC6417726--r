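#' Tidy the pairwise comparisons behind a letter display
#'
#' @param x A `pairwise_letters` object.
#' @param ... Unused.
#' @return Tibble with one row per group pair: `group1`, `group2`,
#'   `p.value` (adjusted as the method prescribes) and `significant` at the
#'   display's alpha.
#' @method tidy pairwise_letters
#' @export
tidy.pairwise_letters <- function(x, ...) {
  groups <- rownames(x$p_pairwise)
  pairs <- combn(groups, 2)
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p.value = x$p_pairwise[cbind(pairs[1, ], pairs[2, ])],
    significant = .data$p.value < x$alpha)
}

#' @method glance pairwise_letters
#' @export
glance.pairwise_letters <- function(x, ...) {
  dplyr::bind_cols(x$omnibus, tibble::tibble(alpha = x$alpha))
}
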