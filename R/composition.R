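#' Decompose the target tissue's mRNA pool by specificity category
#'
#' For each of the six categories, sums the target tissue's mean FPKM over the
#' category's genes and divides by the summed FPKM of all genes. FPKM is a
#' relative abundance unit, so the per-category fraction estimates the share
#' of the tissue's mRNA molecules carried by that category's genes; fractions
#' sum to 1. An `elevated` attribute aggregates the three elevated categories.
#'
#' @param profile Tissue profile tibble (`gene` + FPKM column per tissue).
#' @param classes Classification tibble covering every gene of `profile`.
#' @param target Target tissue label.
#' @return Tibble of class `"mrna_pool"` with columns `category`, `n_genes`,
#'   `total_fpkm`, `mrna_fraction`; attributes `target`, `elevated_fraction`,
#'   `elevated_n`.
#' @examples
#' prof <- tibble::tibble(gene = c("a", "b"), pancreas = c(680, 320), liver = c(1, 300))
#' cl <- classify_tissue_specificity(prof, "pancreas")
#' mrna_pool_fractions(prof, cl, "pancreas")
#' @export
mrna_pool_fractions <- function(profile, classes, target) {
  profile <- validate_fpkm(profile)
  if (!target %in% names(profile)[-1]) {
    abort(paste0("target tissue '", target, "' is not a column of the profile"))
  }
  missing <- setdiff(profile$gene, classes$gene)
  if (length(missing) > 0L) {
    abort(paste0("classification missing ", length(missing),
                 " gene(s), e.g. '", missing[1], "'"))
  }
  cat_of <- setNames(as.character(classes$category), classes$gene)
  df <- tibble(
    gene = profile$gene,
    fpkm = profile[[target]],
    category = factor(cat_of[profile$gene], levels = SPEC_CATEGORIES)
  )
  total <- sum(df$fpkm)
  out <- df %>%
    group_by(.data$category, .drop = FALSE) %>%
    summarise(n_genes = n(), total_fpkm = sum(.data$fpkm), .groups = "drop") %>%
    mutate(mrna_fraction = if (total > 0) .data$total_fpkm / total else NA_real_)
  elev <- as.character(out$category) %in% ELEVATED_CATEGORIES
  structure(
    out,
    class = c("mrna_pool", class(out)),
    target = target,
    elevated_fraction = if (total > 0) sum(out$total_fpkm[elev]) / total else NA_real_,
    elevated_n = sum(out$n_genes[elev])
  )
}

#' Fraction of genes detected in the target tissue
#'
#' Share of all genes in the profile whose target-tissue FPKM meets the
#' detection cutoff. The denominator is every gene in the input matrix.
#'
#' @inheritParams mrna_pool_fractions
#' @param cutoff FPKM detection limit (> 0).
#' @return A single fraction in `[0, 1]`.
#' @export
expressed_fraction <- function(profile, target, cutoff = 1) {
  profile <- validate_fpkm(profile)
  stopifnot(cutoff > 0)
  if (!target %in% names(profile)[-1]) {
    abort(paste0("target tissue '", target, "' is not a column of the profile"))
  }
  mean(profile[[target]] >= cutoff)
}

#' Dynamic range of expression in the target tissue
#'
#' Minimum FPKM over detected genes, the overall maximum FPKM, and their
#' ratio.
#'
#' @inheritParams expressed_fraction
#' @return Tibble with one row: `min_detected`, `max`, `ratio`.
#' @export
dynamic_range <- function(profile, target, cutoff = 1) {
  profile <- validate_fpkm(profile)
  if (!target %in% names(profile)[-1]) {
    abort(paste0("target tissue '", target, "' is not a column of the profile"))
  }
  v <- profile[[target]]
  det <- v[v >= cutoff]
  if (length(det) == 0L) {
    abort("no detected genes in the target tissue")
  }
  tibble(min_detected = min(det), max = max(v), ratio = max(v) / min(det))
}

#' Composition summary for a target tissue
#'
#' Convenience wrapper: per-category gene counts and mRNA-pool fractions plus
#' the expressed fraction and dynamic range in one object.
#'
#' @inheritParams mrna_pool_fractions
#' @param cutoff FPKM detection limit.
#' @return List with elements `pool` ([mrna_pool_fractions()] result),
#'   `expressed_fraction` and `dynamic_range`.
#' @export
composition_summary <- function(profile, classes, target, cutoff = 1) {
  list(
    pool = mrna_pool_fractions(profile, classes, target),
    expressed_fraction = expressed_fraction(profile, target, cutoff),
    dynamic_range = dynamic_range(profile, target, cutoff)
  )
}

#' @exportS3Method generics::glance
glance.mrna_pool <- function(x, ...) {
  tibble(
    target = attr(x, "target"),
    elevated_n = attr(x, "elevated_n"),
    elevated_fraction = attr(x, "elevated_fraction")
  )
}

#' Write a composition table
#'
#' Category rows (category, n_genes, mrna_fraction) followed by summary lines
#' for the expressed fraction and dynamic range.
#'
#' @param composition Result of [composition_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path) {
  pool <- composition$pool
  rows <- tibble(
    key = as.character(pool$category),
    n_genes = as.character(pool$n_genes),
    value = format(pool$mrna_fraction, digits = 15, trim = TRUE)
  )
  dr <- composition$dynamic_range
  extra <- tibble(
    key = c("expressed_fraction", "dynamic_range_min_detected",
            "dynamic_range_max", "dynamic_range_ratio"),
    n_genes = "",
    value = format(c(composition$expressed_fraction, dr$min_detected,
                     dr$max, dr$ratio), digits = 15, trim = TRUE)
  )
  readr::write_tsv(bind_rows(rows, extra), path, progress = FALSE)
  invisible(path)
}
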