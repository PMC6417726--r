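#' Bundle a count matrix with sample metadata
#'
#' An `expression_study` ties a gene-by-sample integer count matrix to tidy
#' sample metadata (developmental phase, replicate) for one species, and
#' carries the library-size-normalized abundance matrix used by every
#' downstream stage.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param meta Data frame with columns `sample_id`, `phase`, `replicate`;
#'   one row per column of `counts`. Every phase must have at least 2
#'   replicates.
#' @param species Species identifier string.
#' @param phases Ordered phase labels; defaults to the order of first
#'   appearance in `meta`.
#' @return An `expression_study` object with elements `counts`, `normalized`
#'   (counts-per-million), `meta` (tibble) and `species`.
#' @export
expression_study <- function(counts, meta, species = "species1",
                             phases = NULL) {
  counts <- as.matrix(counts)
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "`counts` must be non-negative integers")
  stop_if_not(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` needs gene rownames and sample colnames")
  meta <- tibble::as_tibble(meta)
  stop_if_not(all(c("sample_id", "phase", "replicate") %in% names(meta)),
              "`meta` needs columns sample_id, phase, replicate")
  stop_if_not(setequal(meta$sample_id, colnames(counts)) &&
                nrow(meta) == ncol(counts),
              "`meta` must cover every sample column exactly once")
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  reps <- table(meta$phase)
  stop_if_not(all(reps >= 2L), "each phase needs at least 2 replicates")
  phases <- phases %||% unique(meta$phase)
  stop_if_not(setequal(phases, unique(meta$phase)), "`phases` mismatch `meta`")
  meta$phase <- factor(meta$phase, levels = phases)
  structure(
    list(counts = counts, normalized = cpm_normalize(counts), meta = meta,
         species = species, phases = phases),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%s)\n",
              x$species, nrow(x$counts), ncol(x$counts),
              paste(x$phases, collapse = " < ")))
  invisible(x)
}

#' Library-size normalization (counts per million)
#'
#' Scales every sample to an equal library size of one million; when gene
#' lengths are supplied the counts are first divided by length in kilobases,
#' giving an FPKM-like abundance.
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Optional per-gene lengths in bases.
#' @return Matrix of normalized abundances, same shape as `counts`.
#' @examples
#' cpm_normalize(matrix(c(10, 90, 20, 180), 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' @export
cpm_normalize <- function(counts, lengths = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(lengths)) {
    stop_if_not(length(lengths) == nrow(counts) && all(lengths > 0),
                "`lengths` must be positive, one per gene")
    counts <- counts / (lengths / 1000)
  }
  lib <- colSums(counts)
  stop_if_not(all(lib > 0), "a sample has zero total counts")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Replicate-level expression profile of one gene
#'
#' Returns the normalized abundances of `gene` ordered phase block by phase
#' block (phases in study order, replicates sorted within phase), the
#' canonical ordering used when pairing profiles across species.
#'
#' @param study An [expression_study()].
#' @param gene Gene id (rowname of the count matrix).
#' @return Named numeric vector of length phases x replicates.
#' @export
profile_vector <- function(study, gene) {
  stop_if_not(inherits(study, "expression_study"), "`study` must be an expression_study")
  stop_if_not(gene %in% rownames(study$counts), "gene '%s' not in study", gene)
  meta <- study$meta
  reps <- table(meta$phase)
  stop_if_not(length(unique(reps)) == 1L,
              "unequal replicate numbers across phases: profiles cannot align")
  ord <- order(as.integer(meta$phase), meta$replicate)
  ids <- meta$sample_id[ord]
  setNames(study$normalized[gene, ids], ids)
}

phase_samples <- function(study, phase) {
  study$meta$sample_id[as.character(study$meta$phase) == phase]
}
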