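# End-to-end orchestration of the comparative study workflow on synthetic
# data: simulate -> differential expression -> bootstrap clustering ->
# ortholog correlation -> co-expression networks -> CHC quantification ->
# thickness comparison, under one seeded configuration.

#' Configuration for a full synthetic study run
#'
#' All thresholds default to the study protocol: DEG filter q < 0.05,
#' |log2FC| >= 1, abundance floor 5; ortholog correlation r >= 0.6,
#' p <= 0.1; network |r| >= 0.95, p <= 0.05; 10,000 bootstrap replicates
#' per scale with the AU > 95 significance reading; alpha 0.05 elsewhere.
#'
#' @param seed Integer seed driving every stage.
#' @param out_dir Output directory (created if missing); default a fresh
#'   temporary directory.
#' @param n_genes Genes per species in the expression simulation.
#' @param expression Optional [expression_sim_config()] override.
#' @param q_max,min_abs_log2fc,min_abundance DEG filter thresholds.
#' @param de_method DE method, see [test_de()].
#' @param r_min,p_max Ortholog-correlation thresholds.
#' @param network_r_abs_min,network_p_max Co-expression edge thresholds.
#' @param nboot Bootstrap replicates per scale.
#' @param au_cutoff AU significance cutoff (percent).
#' @param alpha Significance level for letter displays and the normality
#'   gate.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L, out_dir = NULL, n_genes = 2000,
                         expression = NULL,
                         q_max = 0.05, min_abs_log2fc = 1,
                         min_abundance = 5, de_method = "nb_wald",
                         r_min = 0.6, p_max = 0.1,
                         network_r_abs_min = 0.95, network_p_max = 0.05,
                         nboot = 10000, au_cutoff = 95, alpha = 0.05) {
  check_number(q_max, "q_max", 0, 1); check_number(p_max, "p_max", 0, 1)
  check_number(min_abs_log2fc, "min_abs_log2fc", min = 0)
  check_number(min_abundance, "min_abundance", min = 0)
  check_number(r_min, "r_min", -1, 1)
  check_number(network_r_abs_min, "network_r_abs_min", 0, 1)
  check_number(network_p_max, "network_p_max", 0, 1)
  check_number(au_cutoff, "au_cutoff", 0, 100)
  check_number(alpha, "alpha", 0, 1)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(seed = seed, out_dir = out_dir, n_genes = n_genes,
         expression = expression, q_max = q_max,
         min_abs_log2fc = min_abs_log2fc, min_abundance = min_abundance,
         de_method = de_method, r_min = r_min, p_max = p_max,
         network_r_abs_min = network_r_abs_min,
         network_p_max = network_p_max, nboot = check_count(nboot, "nboot", 100L),
         au_cutoff = au_cutoff, alpha = alpha),
    class = "study_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic comparative study
#'
#' Executes every stage in dependency order on seeded synthetic data.
#' Failure of one species' stage is caught and recorded as a warning in the
#' report without aborting the other species.
#'
#' @param config A [study_config()].
#' @return A `run_report` list: `$seed`, `$stages` (per-stage result
#'   objects), `$counts` (headline numbers), `$files` (tibble path/md5),
#'   `$warnings`. The report (minus in-memory objects) is also written as
#'   `run_report.json` in the output directory.
#' @export
run_study <- function(config = study_config()) {
  stop_if_not(inherits(config, "study_config"), "`config` must be a study_config()")
  out_dir <- config$out_dir %||% tempfile("beecuticle_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)
  stage <- function(label, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(sprintf("%s: %s", label, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      note(sprintf("%s FAILED: %s", label, conditionMessage(e)))
      NULL
    })
  }
  files <- character()
  emit <- function(x, name) {
    files <<- c(files, write_tsv(x, file.path(out_dir, name)))
  }

  # -- stage 1: simulation ----------------------------------------------------
  expr_cfg <- config$expression %||%
    expression_sim_config(n_genes = config$n_genes,
                          ortholog_dropout = 0.05,
                          seed = child_seed(config$seed, 1L))
  sim <- generate_expression(expr_cfg)
  species <- names(sim$studies)
  for (sp in species) {
    emit(tibble::as_tibble(sim$studies[[sp]]$counts, rownames = "gene"),
         sprintf("expression_counts_%s.tsv", sp))
  }
  emit(sim$studies[[1]]$meta, "sample_metadata.tsv")
  emit(sim$ortholog_map, "ortholog_map.tsv")
  emit(sim$truth, "expression_truth.tsv")

  chc_designs <- list(
    list(sp = species[1], n = c(Pbm = 15, Ne = 15, Fg = 15), pool = 1L,
         vol = 0.160),
    list(sp = species[2], n = c(Pbm = 15, Ne = 15, Fg = 15), pool = 3L,
         vol = 0.100),
    list(sp = species[3], n = c(Pbm = 4, Ne = 7, Fg = 7), pool = 1L,
         vol = 0.160))
  chc_sims <- lapply(seq_along(chc_designs), function(i) {
    d <- chc_designs[[i]]
    cfg <- chc_sim_config(n_per_phase = d$n, pool_size = d$pool,
                          extract_volume_ml = d$vol,
                          seed = child_seed(config$seed, 10L + i))
    list(design = d, config = cfg, data = generate_chc(cfg))
  })
  names(chc_sims) <- species
  for (sp in species) {
    emit(chc_sims[[sp]]$data$peaks, sprintf("chc_peaks_%s.tsv", sp))
    emit(chc_sims[[sp]]$data$standards, sprintf("chc_standards_%s.tsv", sp))
  }

  # thickness designs: eusocial cuticle thickens after emergence (species 1
  # doubles Ne -> Fg); the solitary species triples Pbm -> Ne and is stable
  # to the forager phase
  thick_means <- list(c(2, 2, 4.2), c(1, 1.1, 1.3), c(1.5, 4.6, 4.5))
  thickness <- lapply(seq_along(species), function(i) {
    generate_thickness(c("Pbm", "Ne", "Fg"), means = thick_means[[i]],
                       sds = 0.12 * thick_means[[i]], n = 12,
                       seed = child_seed(config$seed, 20L + i))
  })
  names(thickness) <- species
  for (sp in species) emit(thickness[[sp]], sprintf("thickness_%s.tsv", sp))

  # -- stage 2: differential expression ---------------------------------------
  phases <- expr_cfg$phases
  phase_pairs <- combn(phases, 2)
  de <- list(); summaries <- list()
  for (sp in species) {
    res <- stage(sprintf("deg[%s]", sp), {
      recs <- purrr::map_dfr(seq_len(ncol(phase_pairs)), function(i) {
        test_de(sim$studies[[sp]], phase_pairs[1, i], phase_pairs[2, i],
                method = config$de_method)
      })
      degs <- filter_degs(recs, config$q_max, config$min_abs_log2fc,
                          config$min_abundance)
      emit(degs, sprintf("degs_%s.tsv", sp))
      list(records = recs, degs = degs,
           summary = upregulation_summary(degs))
    })
    de[sp] <- list(res)
    if (!is.null(res)) summaries[[sp]] <- res$summary
  }

  # -- stage 3: upregulation-proportion z tests -------------------------------
  prop_tests <- stage("proportions", {
    pairs <- combn(names(summaries), 2)
    cat_id <- paste0(phases[1], "_vs_", phases[3], ":", phases[1])
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      zt <- compare_proportions(summaries[[pairs[1, i]]],
                                summaries[[pairs[2, i]]], cat_id)
      tibble::tibble(species_a = pairs[1, i], species_b = pairs[2, i],
                     category = cat_id, z = zt$z, p = zt$p)
    })
  })
  if (!is.null(prop_tests)) emit(prop_tests, "proportion_tests.tsv")

  # -- stage 4: bootstrap clustering of samples on the DEG subset -------------
  trees <- list()
  for (sp in species) {
    trees[sp] <- list(stage(sprintf("cluster[%s]", sp), {
      genes <- unique(de[[sp]]$degs$gene)
      stop_if_not(length(genes) >= 3, "fewer than 3 DEGs to cluster on")
      tr <- multiscale_bootstrap(sim$studies[[sp]]$normalized[genes, ],
                                 metric = "correlation",
                                 nboot = config$nboot,
                                 seed = child_seed(config$seed, 30L))
      emit(tidy(tr), sprintf("expression_tree_%s.tsv", sp))
      write_supported_newick(tr, file.path(out_dir,
                                           sprintf("expression_tree_%s.nwk", sp)))
      files <- c(files, file.path(out_dir, sprintf("expression_tree_%s.nwk", sp)))
      tr
    }))
  }

  # -- stage 5: ortholog profile correlation ----------------------------------
  ortho <- stage("ortholog_correlation", {
    calls <- correlate_orthologs(sim$studies, sim$ortholog_map,
                                 r_min = config$r_min, p_max = config$p_max)
    emit(calls, "ortholog_pattern_calls.tsv")
    emit(pattern_summary(calls), "ortholog_pattern_summary.tsv")
    calls
  })

  # -- stage 6: co-expression networks and intersections ----------------------
  nets <- list()
  for (sp in species) {
    nets[sp] <- list(stage(sprintf("network[%s]", sp), {
      genes <- unique(de[[sp]]$degs$gene)
      stop_if_not(length(genes) >= 2, "fewer than 2 DEGs for a network")
      net <- build_network(sim$studies[[sp]], genes,
                           r_abs_min = config$network_r_abs_min,
                           p_max = config$network_p_max)
      write_network_sif(net, file.path(out_dir, sprintf("network_%s.sif", sp)),
                        file.path(out_dir, sprintf("network_%s_edges.tsv", sp)))
      files <- c(files, file.path(out_dir, sprintf("network_%s.sif", sp)))
      net
    }))
  }
  net_shared <- if (all(!vapply(nets, is.null, logical(1)))) {
    stage("network_intersection", {
      s <- shared_interactions_summary(nets, sim$ortholog_map)
      emit(s, "network_shared_interactions.tsv")
      s
    })
  } else {
    note("network_intersection: skipped (missing networks or ortholog map)")
    NULL
  }

  # -- stage 7: CHC quantification --------------------------------------------
  chc <- list()
  for (sp in species) {
    chc[sp] <- list(stage(sprintf("chc[%s]", sp), {
      s <- chc_sims[[sp]]
      curves <- fit_calibration(s$data$standards)
      rel <- normalize_relative(s$data$peaks, scope = "all")
      abs_q <- absolute_quantify(s$data$peaks, curves,
                                 pool_size = s$config$pool_size,
                                 extract_volume_ml = s$config$extract_volume_ml)
      totals <- chc_class_totals(abs_q)
      emit(tibble::as_tibble(curves), sprintf("chc_calibration_%s.tsv", sp))
      emit(rel, sprintf("chc_relative_%s.tsv", sp))
      emit(abs_q, sprintf("chc_absolute_%s.tsv", sp))
      class_letters <- per_class_phase_test(totals, alpha = config$alpha)
      emit(class_letters, sprintf("chc_class_letters_%s.tsv", sp))
      pca <- pca_loadings(rel)
      emit(pca$loadings, sprintf("chc_pca_loadings_%s.tsv", sp))
      pct_matrix <- rel |>
        dplyr::select("individual_id", "compound_id", "pct") |>
        tidyr::pivot_wider(names_from = "individual_id",
                           values_from = "pct")
      m <- as.matrix(pct_matrix[, -1])
      rownames(m) <- pct_matrix$compound_id
      tree <- multiscale_bootstrap(m, metric = "euclidean",
                                   nboot = config$nboot,
                                   seed = child_seed(config$seed, 40L))
      emit(tidy(tree), sprintf("chc_tree_%s.tsv", sp))
      list(curves = curves, relative = rel, absolute = abs_q,
           totals = totals, class_letters = class_letters, pca = pca,
           tree = tree)
    }))
  }

  # -- stage 8: thickness comparisons -----------------------------------------
  thick <- list()
  for (sp in species) {
    thick[sp] <- list(stage(sprintf("thickness[%s]", sp), {
      cmp <- compare_phases(thickness[[sp]], alpha = config$alpha)
      emit(tidy(cmp), sprintf("thickness_letters_%s.tsv", sp))
      cmp
    }))
  }

  counts <- list(
    n_genes = expr_cfg$n_genes,
    n_degs = lapply(de, function(d) if (is.null(d)) NA else
      length(unique(d$degs$gene))),
    ortholog_labels = if (is.null(ortho)) NULL else pattern_summary(ortho),
    network_edges = lapply(nets, function(n) if (is.null(n)) NA else
      nrow(n$edges)))
  file_tbl <- tibble::tibble(path = files,
                             md5 = unname(tools::md5sum(files)))
  report <- structure(
    list(seed = config$seed, out_dir = out_dir, config = config,
         stages = list(simulation = sim, chc_simulation = chc_sims,
                       thickness_data = thickness, de = de,
                       proportion_tests = prop_tests, trees = trees,
                       ortholog_calls = ortho, networks = nets,
                       network_shared = net_shared, chc = chc,
                       thickness = thick),
         counts = counts, files = file_tbl, warnings = warnings),
    class = "run_report")
  jsonlite::write_json(
    list(seed = config$seed,
         counts = list(n_genes = counts$n_genes, n_degs = counts$n_degs,
                       network_edges = counts$network_edges),
         files = file_tbl, warnings = warnings),
    file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, %d output files, %d warning(s)\n",
              x$seed, nrow(x$files), length(x$warnings)))
  cat(sprintf("outputs in %s\n", x$out_dir))
  invisible(x)
}
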