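## Pipeline orchestration: one configuration in, a run directory of stage
## outputs plus a provenance manifest out.

pipeline_config_keys <- c("seed", "simulate", "distance", "gene_models",
                          "coincidence", "specificity", "atlas", "sex_bias")

#' Run the expression-evolution pipeline
#'
#' Executes the stages in dependency order on a synthetic panel: panel
#' simulation, stationary-OU distances and NJ expression tree, per-gene
#' model selection and change events, coincidence/overlap summaries, tau
#' specificity, atlas homology scoring and sex-bias testing. Each stage is
#' optional; the manifest records the package version, seeds, parameters
#' and output checksums.
#'
#' @param config A named list, or the path to a YAML file. Top-level keys:
#'   \code{seed}; \code{simulate} (arguments to [sim_spec()]);
#'   \code{distance} (\code{tissue}, \code{outgroup}, \code{n_bootstrap});
#'   \code{gene_models} (\code{tissues}, \code{max_shifts},
#'   \code{max_genes}); \code{coincidence} (enabled when present);
#'   \code{specificity} (enabled when present); \code{atlas} (arguments to
#'   [simulate_atlas_pair()]); \code{sex_bias} (enabled when present).
#'   Unknown keys raise a validation error naming the key.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list of in-memory stage results; files and
#'   \code{manifest.json} are written under \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$simulate))
    stop("missing input: 'simulate' block is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(package = "exprevol",
                   version = as.character(utils::packageVersion("exprevol")),
                   seed = seed, config = config, stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    message(sprintf("[exprevol] stage %-12s %6.1fs", name, dt))
    manifest$stages[[name]] <<- list(seconds = round(dt, 2))
    val
  }

  ## stage: simulate
  spec <- do.call(sim_spec, c(config$simulate, list(seed = seed)))
  panel <- t_stage("simulate", simulate_panel(spec))
  write_panel(panel, file.path(out_dir, "panel"))
  manifest$stages$simulate$n_genes <- nrow(panel$tpm)
  manifest$stages$simulate$n_samples <- ncol(panel$tpm)
  results$panel <- panel

  ## stage: distances + NJ tree
  if (!is.null(config$distance)) {
    dc <- config$distance
    tiss <- dc$tissue %||% spec$tissues[1]
    sm <- species_mean_tpm(panel, tiss)
    results$distance <- t_stage("disttree", {
      d <- sou_distance(sm, min_tpm = dc$min_tpm %||% 1)
      tr <- nj_tree(sm, outgroup = dc$outgroup %||% spec$tree$tip.label[
        which.max(ape::node.depth.edgelength(spec$tree)[seq_along(spec$tree$tip.label)])],
        n_bootstrap = dc$n_bootstrap %||% 100, seed = seed)
      list(dist = d, tree = tr)
    })
    write_tsv(as.data.frame(results$distance$dist),
              file.path(out_dir, paste0("distance_", tiss, ".tsv")),
              seed = seed)
    write_species_tree(results$distance$tree,
                       file.path(out_dir, paste0("njtree_", tiss, ".nwk")),
                       validate = FALSE)
  }

  ## stage: per-gene model selection -> events
  events <- NULL
  if (!is.null(config$gene_models)) {
    gm <- config$gene_models
    tissues <- gm$tissues %||% spec$tissues
    results$fits <- t_stage("genemodels", {
      lapply(stats::setNames(tissues, tissues), function(tt) {
        traits <- panel_traits(panel, tt)
        if (!is.null(gm$max_genes)) traits <- traits[seq_len(
          min(gm$max_genes, length(traits)))]
        fit_gene_models(traits, spec$tree,
                        max_shifts = gm$max_shifts %||% 3, tissue = tt)
      })
    })
    events <- do.call(rbind, lapply(names(results$fits), function(tt)
      change_events(results$fits[[tt]], tissue = tt)))
    write_tsv(events, file.path(out_dir, "change_events.tsv"), seed = seed)
    fit_tab <- do.call(rbind, lapply(results$fits, gene_fit_table))
    write_tsv(fit_tab, file.path(out_dir, "gene_fits.tsv"), seed = seed)
    cls <- lapply(results$fits, classify_branches)
    frac <- do.call(rbind, lapply(names(cls), function(tt)
      data.frame(tissue = tt, t(cls[[tt]]$fractions))))
    write_tsv(frac, file.path(out_dir, "branch_classes.tsv"), seed = seed)
    manifest$stages$genemodels$n_events <- nrow(events)
    results$events <- events
  }

  ## stage: coincidence / overlap
  if (!is.null(config$coincidence) && !is.null(events)) {
    results$coincidence <- t_stage("coincidence", {
      list(overlap = tissue_overlap(events, spec$tissues),
           index = coincidental_index_all(events, length(spec$tissues)),
           vs_length = coincidence_vs_branch_length(events, spec$tree,
                                                    seed = seed))
    })
    write_tsv(results$coincidence$overlap,
              file.path(out_dir, "tissue_overlap.tsv"), seed = seed)
    write_tsv(results$coincidence$index,
              file.path(out_dir, "coincidental_index.tsv"), seed = seed)
  }

  ## stage: tau specificity across tissues
  if (!is.null(config$specificity)) {
    results$tau <- t_stage("tau", {
      by_tissue <- vapply(spec$tissues, function(tt)
        rowMeans(species_mean_tpm(panel, tt)), numeric(nrow(panel$tpm)))
      data.frame(gene = rownames(panel$tpm),
                 tau = apply(by_tissue, 1, tau),
                 stringsAsFactors = FALSE)
    })
    write_tsv(results$tau, file.path(out_dir, "tau_tissue.tsv"), seed = seed)
  }

  ## stage: atlas homology
  if (!is.null(config$atlas)) {
    results$homology <- t_stage("homology", {
      pair <- do.call(simulate_atlas_pair,
                      c(config$atlas, list(seed = seed)))
      ma <- find_markers(pair$atlas_a)
      mb <- find_markers(pair$atlas_b)
      sc <- homology_score(pair$atlas_a, pair$atlas_b, ma, mb)
      list(pair = pair, score = sc, matches = match_clusters(sc))
    })
    write_tsv(as.data.frame(results$homology$score),
              file.path(out_dir, "homology_score.tsv"), seed = seed)
  }

  ## stage: sex bias
  if (!is.null(config$sex_bias)) {
    results$sex_bias <- t_stage("sexbias", {
      counts <- panel_to_counts(panel, seed = seed)
      sexed <- panel$meta[panel$meta$sex %in% c("male", "female"), ]
      res <- nb_wald(counts, sexed)
      classify_bias(res)
    })
    write_tsv(results$sex_bias, file.path(out_dir, "sex_bias.tsv"),
              seed = seed)
    manifest$stages$sexbias$n_biased <-
      sum(results$sex_bias$bias != "none", na.rm = TRUE)
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest[.]json$", outputs)]
  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(results)
}
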