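#' Run the full tissue-specificity analysis
#'
#' Orchestrates validate -> average replicates -> classify -> composition ->
#' sample correlation -> (optional) compartment enrichment -> sharing network,
#' writing every stage output plus a JSON run manifest of parameters, package
#' version and input checksums so a run can be reproduced exactly. Any stage
#' error aborts with the stage name and cause.
#'
#' @param config Either a list or the path to a YAML file with entries:
#'   `matrix` and `annotation` (input TSV paths, required), `target` tissue
#'   (required), `outdir` (required), and optionally `detection_cutoff`
#'   (default 1), `fold` (5), `group_min` (2), `group_max` (7),
#'   `similarity_filter` (`"all"` or `"detected_in_either"`), `isolates`
#'   (character vector of isolate compartments, e.g. `c("islet","exocrine")`,
#'   mapped through the annotation's `compartment` column), `exclude_parent`
#'   (default `TRUE`), `include_enriched_in_network` (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage result (`profile`, `classes`,
#'   `composition`, `correlation`, `compartments`, `network`, `manifest`).
#' @export
run_tissuespec <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(detection_cutoff = 1, fold = 5, group_min = 2L,
                   group_max = 7L, similarity_filter = "all",
                   isolates = NULL, exclude_parent = TRUE,
                   include_enriched_in_network = TRUE)
  cfg <- modifyList(defaults, config)
  for (key in c("matrix", "annotation", "target", "outdir")) {
    if (is.null(cfg[[key]])) abort(paste0("config is missing '", key, "'"))
  }
  for (key in c("matrix", "annotation")) {
    if (!file.exists(cfg[[key]])) {
      abort(paste0("input file not found: ", cfg[[key]]))
    }
  }
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[tissuespec] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  fpkm <- stage("validate", {
    x <- read_fpkm_table(cfg$matrix)
    validate_annotation(read_sample_annotation(cfg$annotation), fpkm = x)
    x
  })
  annotation <- read_sample_annotation(cfg$annotation)
  say(nrow(fpkm), " genes x ", ncol(fpkm) - 1L, " samples")

  profile <- stage("average", average_replicates(fpkm, annotation, compartment = "whole"))
  say(ncol(profile) - 1L, " tissues after replicate averaging")

  classes <- stage("classify", classify_tissue_specificity(
    profile, cfg$target, detection_cutoff = cfg$detection_cutoff,
    fold = cfg$fold, group_min = cfg$group_min, group_max = cfg$group_max
  ))
  cen <- category_census(classes)
  say("census: ", paste(cen$category, cen$n_genes, sep = "=", collapse = ", "))
  write_classification(classes, file.path(cfg$outdir, "classifications.tsv"))

  composition <- stage("compose", composition_summary(
    profile, classes, cfg$target, cutoff = cfg$detection_cutoff
  ))
  write_composition(composition, file.path(cfg$outdir, "composition.tsv"))

  correlation <- stage("correlate", spearman_matrix(
    fpkm, gene_filter = cfg$similarity_filter, cutoff = cfg$detection_cutoff
  ))
  write_cor_matrix(correlation, file.path(cfg$outdir, "correlations.tsv"))

  compartments <- NULL
  if (!is.null(cfg$isolates)) {
    compartments <- stage("compartments", {
      iso_prof <- NULL
      for (iso in cfg$isolates) {
        p <- average_replicates(fpkm, annotation, compartment = iso)
        p <- p[, c("gene", setdiff(names(p), "gene"))]
        names(p)[-1] <- paste0(iso, "_isolate")
        iso_prof <- if (is.null(iso_prof)) p else left_join(iso_prof, p, by = "gene")
      }
      isolate_enrichment(
        profile, iso_prof, cfg$target, exclude_parent = cfg$exclude_parent,
        detection_cutoff = cfg$detection_cutoff, fold = cfg$fold,
        group_min = cfg$group_min, group_max = cfg$group_max
      )
    })
    write_compartments(compartments, file.path(cfg$outdir, "compartments.tsv"))
  }

  network <- stage("network", build_sharing_network(
    classes, cfg$target, include_enriched = cfg$include_enriched_in_network
  ))
  write_sharing_network(network, cfg$outdir)

  manifest <- list(
    package = "tissuespec",
    version = as.character(utils::packageVersion("tissuespec")),
    parameters = cfg[setdiff(names(cfg), "outdir")],
    inputs = list(
      matrix = list(path = cfg$matrix, md5 = unname(tools::md5sum(cfg$matrix))),
      annotation = list(path = cfg$annotation,
                        md5 = unname(tools::md5sum(cfg$annotation)))
    ),
    census = setNames(as.list(cen$n_genes), as.character(cen$category))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("outputs written to ", cfg$outdir)

  invisible(list(profile = profile, classes = classes,
                 composition = composition, correlation = correlation,
                 compartments = compartments, network = network,
                 manifest = manifest))
}
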