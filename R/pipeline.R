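# End-to-end orchestration with deterministic seeding and a run manifest.
# Each laboratory is analyzed independently (batch effects are never
# corrected across labs); shared variants feed the cross-laboratory
# tanglegram.

#' Default run configuration
#'
#' @param seed root seed; all stochastic stages derive their streams from
#'   it.
#' @param threshold cumulative-variance threshold for component retention.
#' @param k_range candidate cluster counts for the validity vote.
#' @param L tanglegram norm exponent.
#' @param panel a [panel_spec()] (its own seed is overridden by `seed`).
#' @param profiles class profiles for simulation.
#' @param score_map isoform/domain score maps.
#' @param misclassification_rate registry simulation noise.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, threshold = 0.85, k_range = 2:8, L = 1.5,
                       panel = panel_spec(seed = seed),
                       profiles = default_class_profiles(panel$assay_variables),
                       score_map = default_position_scores(),
                       misclassification_rate = 0.1) {
  stopifnot(threshold > 0, threshold <= 1)
  panel$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), threshold = threshold,
                 k_range = k_range, L = L, panel = panel,
                 profiles = profiles, score_map = score_map,
                 misclassification_rate = misclassification_rate),
            class = "run_config")
}

#' Simulate panel, reference, registry and truth files
#'
#' Writes `panel.tsv`, `references.tsv`, `annotations.tsv`, `registry.tsv`
#' and `truth.tsv` (truth labels are kept in their own file, never in the
#' dataset payload).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
simulate_datasets <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- generate_panel(config$panel, config$profiles)
  refs <- generate_references(config$panel, config$profiles)
  registry <- generate_registry(panel$truth, seed = config$seed,
                                misclassification_rate = config$misclassification_rate)
  ann <- rbind(as.data.frame(panel$annotations),
               as.data.frame(refs$annotations))
  ann$gnomad_count[match(registry$variant, ann$variant)] <-
    registry$gnomad_count
  files <- c(panel = file.path(out_dir, "panel.tsv"),
             references = file.path(out_dir, "references.tsv"),
             annotations = file.path(out_dir, "annotations.tsv"),
             registry = file.path(out_dir, "registry.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_functional_table(panel$dataset, files[["panel"]])
  write_functional_table(refs$dataset, files[["references"]])
  write_annotation_table(variant_annotation(ann), files[["annotations"]])
  write_registry_table(registry, files[["registry"]])
  write_tsv(panel$truth, files[["truth"]])
  invisible(files)
}

#' Run the full stratification pipeline
#'
#' Simulates (or loads) the two-laboratory panel, then for each laboratory:
#' polish -> PCA -> component selection -> k-means with validity vote ->
#' Ward clustering -> zone annotation; applies the reclassification rule
#' engine to registry variants and writes the registry impact report.
#' When at least two laboratories share variants, the shared-variant
#' dendrograms are untangled and the tanglegram emitted. Every artifact is
#' written to `out_dir` together with a manifest (configuration, seed,
#' package version, artifact hashes); a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param inputs optional named list of file paths (`panel`, `references`,
#'   `annotations`, `registry`) to analyze instead of simulating.
#' @return invisibly, a list with per-lab `hnf1a_strat` fits, the
#'   `reclass_report`, the `tanglegram` (or NULL) and the artifact paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(inputs)) {
    inputs <- simulate_datasets(config, file.path(out_dir, "input"))
  }
  panel_ds <- read_functional_table(inputs[["panel"]])
  refs_ds <- read_functional_table(inputs[["references"]])
  ann <- read_annotation_table(inputs[["annotations"]])
  registry <- read_registry_table(inputs[["registry"]])

  labs <- sort(unique(panel_ds$lab))
  all_ds <- functional_dataset(rbind(as.data.frame(panel_ds),
                                     as.data.frame(refs_ds)),
                               "CONTROL_NORMALIZED")
  cfg <- polish_config(score_map = config$score_map)
  artifacts <- character(0)
  fits <- list()
  zone_rows <- list()
  for (lab in labs) {
    sub <- functional_dataset(
      as.data.frame(all_ds)[all_ds$lab == lab, , drop = FALSE],
      "CONTROL_NORMALIZED")
    fit <- stratify_variants(sub, ann, threshold = config$threshold,
                             k_range = config$k_range, seed = config$seed,
                             config = cfg)
    fits[[lab]] <- fit
    p <- file.path(out_dir, paste0("polished_", lab, ".tsv"))
    write_polished_matrix(fit$polished, p)
    s <- file.path(out_dir, paste0("pca_scores_", lab, ".tsv"))
    write_tsv(data.frame(variant = rownames(fit$pca$scores),
                         fit$pca$scores, check.names = FALSE), s)
    a <- file.path(out_dir, paste0("kmeans_", lab, ".tsv"))
    write_tsv(data.frame(variant = names(fit$kmeans$assignment),
                         cluster = unname(fit$kmeans$assignment)), a)
    d <- file.path(out_dir, paste0("dendrogram_", lab, ".nwk"))
    write_newick(as_dtree(fit$ward), d)
    artifacts <- c(artifacts, p, s, a, d)
    if (!is.null(fit$zones)) {
      z <- file.path(out_dir, paste0("zones_", lab, ".tsv"))
      write_tsv(as.data.frame(fit$zones), z)
      artifacts <- c(artifacts, z)
      vz <- variant_zones(fit$kmeans$assignment, fit$zones)
      zone_rows[[lab]] <- data.frame(variant = names(vz), zone = unname(vz),
                                     lab = lab, stringsAsFactors = FALSE)
    }
  }

  tangle <- NULL
  if (length(labs) >= 2L) {
    shared <- intersect(dtree_leaves(as_dtree(fits[[labs[1L]]]$ward)),
                        dtree_leaves(as_dtree(fits[[labs[2L]]]$ward)))
    if (length(shared) >= 2L) {
      tangle <- untangle(fits[[labs[1L]]]$ward, fits[[labs[2L]]]$ward,
                         L = config$L)
      tp <- file.path(out_dir, "tanglegram.json")
      write_tanglegram(tangle, tp)
      artifacts <- c(artifacts, tp)
    }
  }

  report <- NULL
  if (length(zone_rows)) {
    zones_all <- do.call(rbind, zone_rows)
    # first lab's zone call wins where a shared variant was zoned twice
    zones_first <- zones_all[!duplicated(zones_all$variant), , drop = FALSE]
    overlap <- merge(as.data.frame(registry),
                     merge(zones_first, as.data.frame(ann)[
                       c("variant", "exon")], by = "variant"),
                     by = "variant")
    overlap$band <- frequency_band(overlap$gnomad_count)
    proposals <- reclassify(overlap)
    report <- registry_report(proposals, n_registry_total = nrow(registry),
                              registry_id = unique(registry$registry_id)[1L])
    rp <- file.path(out_dir, "reclassification.tsv")
    write_tsv(proposals, rp)
    sj <- file.path(out_dir, "report.json")
    jsonlite::write_json(report[c("registry_id", "n_registry", "n_overlap",
                                  "n_reclassified", "pct_of_registry",
                                  "pct_of_overlap")],
                         sj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c(artifacts, rp, sj)
  }

  manifest <- list(
    package = "hnf1astrat",
    version = as.character(utils::packageVersion("hnf1astrat")),
    seed = config$seed,
    threshold = config$threshold,
    k_range = as.integer(config$k_range),
    L = config$L,
    panel = unclass(config$panel),
    inputs = as.list(inputs),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) unname(tools::md5sum(f)))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fits = fits, report = report, tanglegram = tangle,
                 artifacts = c(artifacts, mp), out_dir = out_dir))
}
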