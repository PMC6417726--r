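# Within-species gene co-expression networks by thresholded Pearson
# correlation over all samples (phases pooled), and cross-species edge
# intersection through the ortholog map.

#' Build a thresholded co-expression network
#'
#' All-pairs Pearson correlation over the samples of one species; an edge is
#' kept iff `|r| >= r_abs_min` and `p <= p_max` (bounds inclusive; p from
#' the t transform, no multiple-testing correction — the stringent r bound
#' dominates at these sample sizes). Genes with constant expression are
#' excluded with a warning.
#'
#' @param study An [expression_study()].
#' @param genes Optional character vector restricting the network to a gene
#'   subset (typically the differentially expressed set).
#' @param r_abs_min Absolute correlation threshold (default 0.95).
#' @param p_max p-value threshold (default 0.05).
#' @return A `coexpression_network`: `$species`, `$nodes` (genes tested) and
#'   `$edges` (tibble gene_a/gene_b/r/p/sign with gene_a < gene_b).
#' @export
build_network <- function(study, genes = NULL, r_abs_min = 0.95,
                          p_max = 0.05) {
  stop_if_not(inherits(study, "expression_study"), "`study` must be an expression_study")
  check_number(r_abs_min, "r_abs_min", 0, 1)
  check_number(p_max, "p_max", 0, 1)
  x <- study$normalized
  if (!is.null(genes)) {
    stop_if_not(length(genes) > 0, "empty gene subset")
    missing <- setdiff(genes, rownames(x))
    stop_if_not(length(missing) == 0, "genes not in study: %s",
                paste(head(missing, 3), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  stop_if_not(ncol(x) >= 3L, "need at least 3 samples")
  constant <- apply(x, 1, sd) == 0
  if (any(constant)) {
    warn(sprintf("excluding %d constant-expression gene(s) from the network",
                 sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  ids <- rownames(x)
  n <- ncol(x)
  edges <- if (length(ids) >= 2) {
    r <- cor(t(x))
    idx <- which(upper.tri(r), arr.ind = TRUE)
    rv <- r[idx]
    rv <- pmax(-1, pmin(1, rv))
    tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
    pv <- ifelse(abs(rv) == 1, 0, 2 * pt(-abs(tstat), df = n - 2))
    keep <- abs(rv) >= r_abs_min & pv <= p_max
    tibble::tibble(gene_a = ids[idx[keep, 1]], gene_b = ids[idx[keep, 2]],
                   r = rv[keep], p = pv[keep],
                   sign = ifelse(rv[keep] >= 0, "+", "-")) |>
      dplyr::mutate(swap = .data$gene_a > .data$gene_b,
                    tmp = ifelse(.data$swap, .data$gene_b, .data$gene_a),
                    gene_b = ifelse(.data$swap, .data$gene_a, .data$gene_b),
                    gene_a = .data$tmp) |>
      dplyr::select(-"swap", -"tmp") |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  } else {
    tibble::tibble(gene_a = character(), gene_b = character(),
                   r = numeric(), p = numeric(), sign = character())
  }
  structure(list(species = study$species, nodes = ids, edges = edges,
                 r_abs_min = r_abs_min, p_max = p_max),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %s: %d nodes, %d edges (|r| >= %g, p <= %g)\n",
              x$species, length(x$nodes), nrow(x$edges), x$r_abs_min, x$p_max))
  invisible(x)
}

#' @method tidy coexpression_network
#' @export
tidy.coexpression_network <- function(x, ...) x$edges

#' @method glance coexpression_network
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(species = x$species, n_nodes = length(x$nodes),
                 n_edges = nrow(x$edges),
                 n_positive = sum(x$edges$sign == "+"),
                 n_negative = sum(x$edges$sign == "-"))
}

#' Common interactions between two species' networks
#'
#' An edge (a1, a2) of `net_a` is common iff both endpoints map to genes of
#' `net_b` and the mapped edge exists in `net_b` — with the same correlation
#' sign when `match_sign` is `TRUE` (the default reading of a shared
#' interaction). The result is symmetric in the argument order up to id
#' relabeling.
#'
#' @param net_a,net_b [build_network()] results.
#' @param map Ortholog map tibble whose columns include the two species ids
#'   (`net_a$species`, `net_b$species`).
#' @param match_sign Require equal edge sign (default `TRUE`).
#' @return Tibble of common edges with the ids in both species and the sign.
#' @export
intersect_networks <- function(net_a, net_b, map, match_sign = TRUE) {
  sa <- net_a$species; sb <- net_b$species
  stop_if_not(all(c(sa, sb) %in% names(map)),
              "`map` must have columns '%s' and '%s'", sa, sb)
  lut <- setNames(map[[sb]], map[[sa]])
  lut <- lut[!is.na(names(lut)) & !is.na(lut)]
  key_b <- edge_keys(net_b$edges, match_sign)
  ea <- net_a$edges
  if (nrow(ea) == 0) return(common_edge_tibble(sa, sb))
  b1 <- unname(lut[ea$gene_a]); b2 <- unname(lut[ea$gene_b])
  mapped <- !is.na(b1) & !is.na(b2)
  cand <- ea[mapped, ]
  cb1 <- pmin(b1[mapped], b2[mapped]); cb2 <- pmax(b1[mapped], b2[mapped])
  kk <- paste(cb1, cb2, if (match_sign) cand$sign else "", sep = "|")
  hit <- kk %in% key_b
  out <- tibble::tibble(!!paste0(sa, "_1") := cand$gene_a[hit],
                        !!paste0(sa, "_2") := cand$gene_b[hit],
                        !!paste0(sb, "_1") := cb1[hit],
                        !!paste0(sb, "_2") := cb2[hit],
                        sign = cand$sign[hit])
  out
}

edge_keys <- function(edges, match_sign) {
  if (nrow(edges) == 0) return(character())
  paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b),
        if (match_sign) edges$sign else "", sep = "|")
}

common_edge_tibble <- function(sa, sb) {
  tibble::tibble(!!paste0(sa, "_1") := character(),
                 !!paste0(sa, "_2") := character(),
                 !!paste0(sb, "_1") := character(),
                 !!paste0(sb, "_2") := character(),
                 sign = character())
}

#' Common-interaction counts for every species pair
#'
#' @param nets Named list of [build_network()] results.
#' @param map Ortholog map covering all species in `nets`.
#' @param match_sign Passed to [intersect_networks()].
#' @return Tibble `species_a`/`species_b`/`n_common` for each unordered pair.
#' @export
shared_interactions_summary <- function(nets, map, match_sign = TRUE) {
  sp <- names(nets)
  pairs <- combn(sp, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(
      species_a = a, species_b = b,
      n_common = nrow(intersect_networks(nets[[a]], nets[[b]], map,
                                         match_sign)))
  })
}

#' Write a network as a SIF edge list with an attribute table
#'
#' @param net A [build_network()] result.
#' @param sif_path Path for the SIF file (`geneA (cc|cn) geneB`: `cc` =
#'   positive, `cn` = negative correlation).
#' @param attr_path Optional path for a tab-separated edge-attribute table
#'   (r, p, sign).
#' @return `sif_path`, invisibly.
#' @export
write_network_sif <- function(net, sif_path, attr_path = NULL) {
  rel <- ifelse(net$edges$sign == "+", "cc", "cn")
  writeLines(paste(net$edges$gene_a, rel, net$edges$gene_b), sif_path)
  if (!is.null(attr_path)) {
    utils::write.table(net$edges, attr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sif_path)
}
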