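#' Build the tissue-sharing network of group-enriched genes
#'
#' Groups the group-enriched genes by their exact tissue combination and
#' emits a bipartite network: one "combo" node per distinct tissue
#' combination (gene count, display size = square root of the gene count) and
#' one node per member tissue, with edges connecting each combo to its
#' tissues. Tissue-enriched genes are represented as the singleton combo
#' `{target}` by default, matching plots that show enriched and
#' group-enriched genes together. Also tallies, per non-target tissue, how
#' many group-enriched genes share their enrichment with that tissue.
#'
#' @param classes Classification tibble from [classify_tissue_specificity()]
#'   (the `group` column must be populated for group-enriched genes).
#' @param target Target tissue label; defaults to the table's own target.
#' @param include_enriched Represent tissue-enriched genes as the singleton
#'   combo (default `TRUE`).
#' @return Object of class `"sharing_network"`: list with `nodes` (tibble
#'   `id`, `type` = combo/tissue, `gene_count`, `size`), `edges` (tibble
#'   `combo_id`, `tissue`) and `tissue_tally` (tibble `tissue`, `n_genes`).
#'   Combos are ordered by size then lexicographically; node ids join member
#'   tissues with `"+"`.
#' @export
build_sharing_network <- function(classes, target = NULL,
                                  include_enriched = TRUE) {
  target <- target %||% attr(classes, "target")
  if (is.null(target)) abort("target tissue must be given")
  grp <- classes[classes$category == "group_enriched", , drop = FALSE]
  if (any(is.na(grp$group) | grp$group == "")) {
    bad <- grp$gene[which(is.na(grp$group) | grp$group == "")[1]]
    abort(paste0("group_enriched gene without a group: ", bad))
  }
  combos <- lapply(strsplit(grp$group, ";", fixed = TRUE), sort)
  if (include_enriched) {
    n_enr <- sum(classes$category == "tissue_enriched")
    combos <- c(combos, rep(list(target), n_enr))
  }
  if (length(combos) == 0L) {
    empty_nodes <- tibble(id = character(), type = character(),
                          gene_count = integer(), size = numeric())
    return(structure(
      list(nodes = empty_nodes,
           edges = tibble(combo_id = character(), tissue = character()),
           tissue_tally = tibble(tissue = character(), n_genes = integer())),
      class = "sharing_network", target = target
    ))
  }
  key <- vapply(combos, paste, character(1), collapse = "+")
  tab <- table(key)
  ids <- names(tab)
  sizes <- lengths(strsplit(ids, "+", fixed = TRUE))
  ord <- order(sizes, ids)
  ids <- ids[ord]
  counts <- as.integer(tab[ids])

  combo_nodes <- tibble(
    id = ids, type = "combo",
    gene_count = counts, size = sqrt(counts)
  )
  edges <- tibble(
    combo_id = rep(ids, times = lengths(strsplit(ids, "+", fixed = TRUE))),
    tissue = unlist(strsplit(ids, "+", fixed = TRUE))
  )
  tissue_nodes <- tibble(
    id = sort(unique(edges$tissue)), type = "tissue",
    gene_count = NA_integer_, size = NA_real_
  )
  # Per-tissue sharing tally: group-enriched genes only, non-target tissues.
  shared <- unlist(lapply(strsplit(grp$group, ";", fixed = TRUE),
                          setdiff, y = target))
  tally <- if (length(shared) == 0L) {
    tibble(tissue = character(), n_genes = integer())
  } else {
    tibble(tissue = shared) %>%
      count(.data$tissue, name = "n_genes") %>%
      arrange(dplyr::desc(.data$n_genes), .data$tissue)
  }

  structure(
    list(nodes = bind_rows(combo_nodes, tissue_nodes), edges = edges,
         tissue_tally = tally),
    class = "sharing_network", target = target
  )
}

#' @exportS3Method generics::tidy
tidy.sharing_network <- function(x, ...) {
  x$tissue_tally
}

#' @exportS3Method generics::glance
glance.sharing_network <- function(x, ...) {
  combo <- x$nodes[x$nodes$type == "combo", , drop = FALSE]
  tibble(
    target = attr(x, "target"),
    n_combos = nrow(combo),
    n_tissues = sum(x$nodes$type == "tissue"),
    n_genes = sum(combo$gene_count)
  )
}

#' Write a sharing network as node and edge tables
#'
#' Emits `nodes.tsv` (id, type, gene_count, size) and `edges.tsv`
#' (combo_id, tissue), directly loadable by generic graph viewers.
#'
#' @param network A [build_sharing_network()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sharing_network <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(network$nodes, file.path(dir, "nodes.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(network$edges, file.path(dir, "edges.tsv"), progress = FALSE)
  invisible(dir)
}
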