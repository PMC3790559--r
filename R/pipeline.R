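# End-to-end analysis pipeline: outlines -> eigenshape -> phylomorphospace
# / disparity-through-time / evolutionary model selection / PGLS / QC,
# driven by a single config and writing all stage outputs as CSV.

#' Default pipeline configuration
#'
#' @param tps path to the multi-specimen TPS outline file.
#' @param tree path to the Newick tree (branch lengths in time units).
#' @param specimens path to the specimen table CSV (specimen_id, species,
#'   clade, lifestyle, optional individual column for replicate sets).
#' @param isotopes optional path to the isotope table CSV (species, d13C,
#'   d15N).
#' @param output_dir directory for all stage outputs.
#' @param p_points resampling resolution (default 100).
#' @param axes_for_stats score axes used for ANOVA/CVA/PGLS (default 1:8,
#'   truncated to the available axes).
#' @param traits_to_fit axes fitted with BM/OU/EB (default ES1 and ES2).
#' @param dtt_n_sim,dtt_truncation,dtt_seed DTT null-envelope settings.
#' @param pgls_responses isotope columns regressed on the score axes.
#' @return a `"pipeline_config"` list.
#' @export
pipeline_config <- function(tps, tree, specimens, isotopes = NULL,
                            output_dir = "esmorph_out", p_points = 100L,
                            axes_for_stats = 1:8, traits_to_fit = 1:2,
                            dtt_n_sim = 1000L, dtt_truncation = 0.2,
                            dtt_seed = 1L,
                            pgls_responses = c("d13C", "d15N")) {
  structure(
    list(tps = tps, tree = tree, specimens = specimens, isotopes = isotopes,
         output_dir = output_dir, p_points = as.integer(p_points),
         axes_for_stats = as.integer(axes_for_stats),
         traits_to_fit = as.integer(traits_to_fit),
         dtt_n_sim = as.integer(dtt_n_sim), dtt_truncation = dtt_truncation,
         dtt_seed = as.integer(dtt_seed), pgls_responses = pgls_responses),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `"pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Run the full outline-to-comparative-analysis pipeline
#'
#' Stages: read inputs; resample outlines and compute phi-star shape
#' functions; eigenshape decomposition (scores, loadings, variance
#' fractions, broken-stick axis count); species-mean scores;
#' phylomorphospace projection of the first two axes; disparity through
#' time with BM envelope and MDI; BM/OU/EB model comparison per fitted
#' axis; PGLS of each isotope response on the score axes (species without
#' isotope values are pruned and logged); per-axis ANOVA and CVA on clades;
#' repeatability when the specimen table marks replicate sets via an
#' `individual` column. Every stage writes CSV into `output_dir`, the
#' effective config is serialized alongside, and a run log records every
#' pruning decision. The run is deterministic given the config.
#'
#' Species present in the outlines but absent from the tree are a hard
#' error (no silent dropping); tree tips without specimens are pruned with
#' a log entry.
#'
#' @param config a `"pipeline_config"` (or path to a YAML config).
#' @return invisibly, a list with all stage results (`eigenshape`,
#'   `species_scores`, `n_significant_axes`, `phylomorphospace`, `dtt`,
#'   `model_comparisons`, `pgls`, `anova`, `cva`, `repeatability`, `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  outlines <- read_tps(config$tps)
  tree <- ape::read.tree(config$tree)
  check_tree(tree, warn_ultrametric = TRUE)
  specimens <- read.csv(config$specimens, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "clade")
  if (!all(need %in% names(specimens))) {
    stop("specimen table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- vapply(outlines, function(o) o$specimen_id, character(1))
  unknown <- setdiff(ids, specimens$specimen_id)
  if (length(unknown) > 0) {
    stop("outlines without specimen-table rows: ",
         paste(unknown, collapse = ", "))
  }
  specimens <- specimens[match(ids, specimens$specimen_id), , drop = FALSE]
  missing_sp <- setdiff(unique(specimens$species), tree$tip.label)
  if (length(missing_sp) > 0) {
    stop("species present in outlines but absent from tree: ",
         paste(missing_sp, collapse = ", "))
  }
  extra_tips <- setdiff(tree$tip.label, unique(specimens$species))
  if (length(extra_tips) > 0) {
    tree <- ape::drop.tip(tree, extra_tips)
    note("pruned %d tree tips without specimens: %s", length(extra_tips),
         paste(extra_tips, collapse = ", "))
  }
  note("read %d outlines, %d species, tree depth %.4g", length(outlines),
       ape::Ntip(tree), tree_depth(tree))

  # eigenshape stage
  sfs <- lapply(outlines, function(o) {
    zahn_roskies(resample_equidistant(o, p = config$p_points))
  })
  es <- eigenshape(sfs)
  scores_df <- data.frame(specimen_id = es$specimen_ids,
                          as.data.frame(es$scores, row.names = NULL),
                          check.names = FALSE)
  write.csv(scores_df, file.path(out_dir, "scores.csv"), row.names = FALSE)
  write.csv(data.frame(point = seq_along(es$mean_phi), mean_phi = es$mean_phi,
                       as.data.frame(es$axes, check.names = FALSE)),
            file.path(out_dir, "loadings.csv"), row.names = FALSE)
  write.csv(data.frame(axis = paste0("ES", seq_along(es$variance_fraction)),
                       eigenvalue = es$eigenvalues,
                       variance_fraction = es$variance_fraction),
            file.path(out_dir, "variance_fractions.csv"), row.names = FALSE)
  n_sig <- broken_stick(es$variance_fraction)
  note("eigenshape: %d axes, %d significant under broken-stick, ES1 = %.1f%%",
       ncol(es$scores), n_sig, 100 * es$variance_fraction[1L])

  # species means over specimens (phylogeny-level analyses use these)
  sp_scores <- apply(es$scores, 2L, function(col) {
    tapply(col, specimens$species, mean)
  })
  sp_scores <- as.matrix(sp_scores)
  write.csv(data.frame(species = rownames(sp_scores),
                       as.data.frame(sp_scores, row.names = NULL),
                       check.names = FALSE),
            file.path(out_dir, "species_scores.csv"), row.names = FALSE)
  k_avail <- ncol(sp_scores)
  axes_stats <- config$axes_for_stats[config$axes_for_stats <= k_avail]

  # phylomorphospace (ES1 x ES2)
  pms <- phylomorphospace(tree, sp_scores, axis_pair = c(1L, 2L))
  write.csv(data.frame(node = c(seq_len(nrow(pms$tip_coords)),
                                nrow(pms$tip_coords) + seq_len(nrow(pms$node_coords))),
                       label = c(rownames(pms$tip_coords),
                                 rep("", nrow(pms$node_coords))),
                       rbind(pms$tip_coords, pms$node_coords)),
            file.path(out_dir, "phylomorphospace_coords.csv"),
            row.names = FALSE)
  write.csv(data.frame(parent = pms$edges[, 1L], child = pms$edges[, 2L]),
            file.path(out_dir, "phylomorphospace_edges.csv"),
            row.names = FALSE)

  # disparity through time on the statistics axes
  dtt_res <- disparity_through_time(tree, sp_scores[, axes_stats, drop = FALSE],
                                    n_sim = config$dtt_n_sim,
                                    truncation = config$dtt_truncation,
                                    seed = config$dtt_seed)
  write.csv(data.frame(relative_time = dtt_res$node_times,
                       observed = dtt_res$observed,
                       null_median = dtt_res$null_median),
            file.path(out_dir, "dtt_curve.csv"), row.names = FALSE)
  note("DTT: MDI = %.4f (%d simulations, truncation %.0f%%)", dtt_res$MDI,
       dtt_res$n_sim, 100 * dtt_res$truncation)

  # per-clade disparity
  clade_map <- setNames(specimens$clade, specimens$species)
  clade_map <- clade_map[!duplicated(names(clade_map))]
  cd <- clade_disparity(sp_scores[, axes_stats, drop = FALSE], clade_map)
  write.csv(cd, file.path(out_dir, "clade_disparity.csv"), row.names = FALSE)

  # evolutionary model comparison per fitted axis
  comparisons <- list()
  for (j in config$traits_to_fit[config$traits_to_fit <= k_avail]) {
    trait <- setNames(sp_scores[, j], rownames(sp_scores))
    fits <- lapply(c("BM", "OU", "EB"), function(m)
      fit_trait_model(tree, trait, model = m))
    cmp <- compare_models(fits)
    comparisons[[paste0("ES", j)]] <- cmp
    write.csv(as.data.frame(cmp),
              file.path(out_dir, sprintf("model_comparison_ES%d.csv", j)),
              row.names = FALSE)
    note("model fitting ES%d: best = %s (weight %.3f)", j,
         cmp$model[which.max(cmp$weight)], max(cmp$weight))
  }

  # PGLS of isotopes on score axes
  pgls_fits <- list()
  if (!is.null(config$isotopes)) {
    iso <- read.csv(config$isotopes, stringsAsFactors = FALSE)
    for (resp in intersect(config$pgls_responses, names(iso))) {
      y <- setNames(iso[[resp]], iso$species)
      y <- y[names(y) %in% tree$tip.label]
      n_excl <- ape::Ntip(tree) - sum(tree$tip.label %in% names(y))
      axes_pgls <- axes_stats
      max_axes <- sum(is.finite(y)) - 2L
      if (length(axes_pgls) > max_axes) {
        axes_pgls <- axes_pgls[seq_len(max(1L, max_axes))]
        note("PGLS %s: predictors reduced to ES%s (only %d species with data)",
             resp, paste(range(axes_pgls), collapse = "-"), sum(is.finite(y)))
      }
      fit <- pgls(tree, y, sp_scores[, axes_pgls, drop = FALSE])
      pgls_fits[[resp]] <- fit
      note("PGLS %s ~ %s: n = %d (%d species excluded, no isotope data), F(%d, %d) = %.3f, p = %.4g",
           resp, paste0("ES", paste(range(axes_stats), collapse = "-")),
           fit$n, n_excl, fit$df[1L], fit$df[2L], fit$F, fit$p_value)
      write.csv(cbind(term = rownames(fit$coefficients), fit$coefficients),
                file.path(out_dir, sprintf("pgls_%s.csv", resp)),
                row.names = FALSE)
    }
  }

  # specimen-level group statistics on clades
  anova_res <- NULL
  cva_res <- NULL
  if (length(unique(specimens$clade)) >= 2L) {
    anova_res <- anova_per_axis(es$scores[, axes_stats, drop = FALSE],
                                specimens$clade)
    write.csv(anova_res$anova, file.path(out_dir, "anova_per_axis.csv"),
              row.names = FALSE)
    cva_res <- tryCatch(
      cva_wilks(es$scores[, axes_stats, drop = FALSE], specimens$clade),
      error = function(e) {
        note("CVA skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(cva_res)) {
      write.csv(cva_res$wilks, file.path(out_dir, "cva_wilks.csv"),
                row.names = FALSE)
    }
  }

  # repeatability from replicate digitizations, if marked
  rep_res <- NULL
  if ("individual" %in% names(specimens) &&
      any(duplicated(stats::na.omit(specimens$individual)))) {
    has_ind <- !is.na(specimens$individual) & nzchar(specimens$individual)
    rep_res <- repeatability(es$scores[has_ind, axes_stats, drop = FALSE],
                             specimens$individual[has_ind])
    write.csv(rep_res, file.path(out_dir, "repeatability.csv"),
              row.names = FALSE)
    note("repeatability: R in [%.3f, %.3f] across %d axes", min(rep_res$R),
         max(rep_res$R), nrow(rep_res))
  }

  cfg_out <- config
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(eigenshape = es, species_scores = sp_scores,
                 n_significant_axes = n_sig, phylomorphospace = pms,
                 dtt = dtt_res, clade_disparity = cd,
                 model_comparisons = comparisons, pgls = pgls_fits,
                 anova = anova_res, cva = cva_res, repeatability = rep_res,
                 log = log_lines))
}
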