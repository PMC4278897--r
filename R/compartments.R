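#' Partition three gene sets into the seven Venn regions
#'
#' Exclusive region counts for three sets (e.g. islet-elevated,
#' exocrine-elevated, whole-tissue-elevated gene sets).
#'
#' @param a,b,c Character vectors of gene identifiers.
#' @param names Labels for the three sets (used in the `region` column).
#' @return Tibble with columns `region` (e.g. `"a_only"`, `"a_and_b"`,
#'   `"a_and_b_and_c"`) and `count`; the seven counts sum to
#'   `|a ∪ b ∪ c|`.
#' @examples
#' venn_partition(c("x", "y"), c("y", "z"), "z")
#' @export
venn_partition <- function(a, b, c, names = c("a", "b", "c")) {
  stopifnot(length(names) == 3L)
  a <- unique(as.character(a)); b <- unique(as.character(b)); c <- unique(as.character(c))
  all_genes <- union(union(a, b), c)
  in_a <- all_genes %in% a
  in_b <- all_genes %in% b
  in_c <- all_genes %in% c
  code <- in_a + 2L * in_b + 4L * in_c
  region_labels <- c(
    paste0(names[1], "_only"),
    paste0(names[2], "_only"),
    paste0(names[1], "_and_", names[2]),
    paste0(names[3], "_only"),
    paste0(names[1], "_and_", names[3]),
    paste0(names[2], "_and_", names[3]),
    paste0(names[1], "_and_", names[2], "_and_", names[3])
  )
  counts <- vapply(1:7, function(k) sum(code == k), integer(1))
  tibble(region = region_labels, count = counts)
}

#' Compartment enrichment from isolate preparations
#'
#' Finds genes elevated in purified isolate preparations (e.g. islet and
#' exocrine fractions of the pancreas) that whole-tissue profiling misses:
#' each isolate is appended as the target "tissue" to the comparison panel
#' and the standard six-category classification is run. Because the isolates
#' derive from the parent tissue, the parent is excluded from the comparison
#' panel by default (`exclude_parent = TRUE`) so that its shared transcripts
#' cannot mask isolate enrichment. The whole-tissue elevated set comes from
#' the standard run on the full panel.
#'
#' @param tissue_profile Whole-tissue profile (`gene` + one column per tissue,
#'   including `target`).
#' @param isolate_profile Isolate profile (`gene` + one column per isolate
#'   preparation, replicate-averaged); isolate names must not collide with
#'   tissue names.
#' @param target Parent tissue label in `tissue_profile`.
#' @param exclude_parent Drop the parent tissue from the comparison panel when
#'   classifying isolates (default `TRUE`).
#' @inheritParams classify_gene
#' @return Object of class `"compartment_result"`: list with `elevated` (named
#'   list of gene sets, one per isolate plus `whole`), `venn` (region counts),
#'   `isolate_only` (genes elevated in some isolate but not in whole tissue),
#'   `status` (per-gene tibble with the whole-tissue category and an
#'   `isolate_status` annotation such as `"islet enriched"`), and
#'   `classifications` (the per-isolate classification tables).
#' @export
isolate_enrichment <- function(tissue_profile, isolate_profile, target,
                               exclude_parent = TRUE, detection_cutoff = 1,
                               fold = 5, group_min = 2L, group_max = 7L) {
  tissue_profile <- validate_fpkm(tissue_profile)
  isolate_profile <- validate_fpkm(isolate_profile)
  isolates <- names(isolate_profile)[-1]
  overlap <- intersect(isolates, names(tissue_profile)[-1])
  if (length(overlap) > 0L) {
    abort(paste0("isolate name collides with a tissue: ", overlap[1]))
  }
  sd_size <- length(setdiff(tissue_profile$gene, isolate_profile$gene)) +
    length(setdiff(isolate_profile$gene, tissue_profile$gene))
  if (sd_size > 0L) {
    abort(paste0("gene sets differ between tissue and isolate profiles ",
                 "(symmetric difference of size ", sd_size, ")"))
  }
  isolate_profile <- isolate_profile[match(tissue_profile$gene, isolate_profile$gene), ]

  comparison <- tissue_profile
  if (exclude_parent) {
    comparison <- comparison[, names(comparison) != target]
  }

  whole_cl <- classify_tissue_specificity(
    tissue_profile, target,
    detection_cutoff = detection_cutoff, fold = fold,
    group_min = group_min, group_max = group_max
  )
  elevated <- list()
  classifications <- list()
  for (iso in isolates) {
    panel <- comparison
    panel[[iso]] <- isolate_profile[[iso]]
    cl <- classify_tissue_specificity(
      panel, iso,
      detection_cutoff = detection_cutoff, fold = fold,
      group_min = group_min, group_max = group_max
    )
    classifications[[iso]] <- cl
    elevated[[iso]] <- elevated_genes(cl)
  }
  elevated$whole <- elevated_genes(whole_cl)

  sets <- elevated[c(isolates, "whole")]
  venn <- if (length(isolates) == 2L) {
    venn_partition(sets[[1]], sets[[2]], sets$whole,
                   names = c(isolates, "whole"))
  } else {
    NULL
  }
  isolate_only <- setdiff(unique(unlist(elevated[isolates])), elevated$whole)

  status <- tidy.spec_class(whole_cl)[, c("gene", "category")]
  iso_status <- vapply(status$gene, function(g) {
    hits <- isolates[vapply(isolates, function(iso) g %in% elevated[[iso]], logical(1))]
    if (length(hits) == 0L) NA_character_ else paste(paste(hits, "enriched"), collapse = "; ")
  }, character(1))
  status$isolate_status <- unname(iso_status)

  structure(
    list(elevated = elevated, venn = venn, isolate_only = isolate_only,
         status = status, classifications = classifications),
    class = "compartment_result",
    target = target, exclude_parent = exclude_parent
  )
}

#' @exportS3Method generics::tidy
tidy.compartment_result <- function(x, ...) {
  x$status
}

#' @exportS3Method generics::glance
glance.compartment_result <- function(x, ...) {
  sizes <- lapply(x$elevated, length)
  tibble(!!!sizes, isolate_only = length(x$isolate_only))
}

#' Write compartment results
#'
#' Writes the per-gene status table and, alongside it, a `venn.tsv` of
#' exclusive region counts.
#'
#' @param result A [isolate_enrichment()] result.
#' @param path Output path for the status table; the Venn counts are written
#'   next to it as `<dir>/venn.tsv`.
#' @return `path`, invisibly.
#' @export
write_compartments <- function(result, path) {
  out <- result$status
  out$category <- as.character(out$category)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  if (!is.null(result$venn)) {
    readr::write_tsv(result$venn, file.path(dirname(path), "venn.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}
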