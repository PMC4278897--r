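#' Tissue-specific score
#'
#' Ratio of the target tissue's FPKM to the maximum FPKM in any other tissue.
#' By convention the score is `Inf` when the target is positive and every
#' other tissue is exactly 0, `0` when the target is 0 and some other tissue
#' is positive, and `NA` when all tissues are 0.
#'
#' @param row Named numeric vector of per-tissue FPKM (names are tissue labels).
#' @param target Target tissue label; must be present in `row` along with at
#'   least one other tissue.
#' @return A single numeric score (possibly `Inf` or `NA`).
#' @examples
#' specificity_score(c(pancreas = 10, liver = 2, brain = 1), "pancreas") # 5
#' @export
specificity_score <- function(row, target) {
  if (!target %in% names(row)) {
    abort(paste0("target tissue '", target, "' absent from row"))
  }
  if (length(row) < 2L) {
    abort("row must contain the target and at least one other tissue")
  }
  tv <- unname(row[[target]])
  om <- max(row[names(row) != target])
  score_convention(tv, om)
}

# Shared score convention for scalar or vector inputs.
score_convention <- function(target_val, other_max) {
  s <- target_val / other_max
  s[other_max == 0 & target_val > 0] <- Inf
  s[other_max > 0 & target_val == 0] <- 0
  s[other_max == 0 & target_val == 0] <- NA_real_
  s
}

#' Find the smallest enriched group of tissues
#'
#' Searches for the smallest tissue set G containing the target, with
#' `group_min <= |G| <= group_max`, whose minimum FPKM is at least
#' `fold` times the maximum FPKM of every tissue outside G. Implemented as a
#' sorted-prefix scan: tissues are sorted by FPKM descending (ties broken by
#' tissue label), and prefixes of size `group_min..group_max` containing the
#' target are tested. Any qualifying set is necessarily such a prefix, so the
#' scan is exact.
#'
#' @inheritParams specificity_score
#' @param fold Enrichment fold threshold (inclusive, `>= fold`).
#' @param group_min,group_max Allowed group sizes.
#' @return Character vector of tissue labels (including the target, in
#'   descending FPKM order), or `NULL` when no qualifying group exists.
#' @export
find_enriched_group <- function(row, target, fold = 5, group_min = 2L,
                                group_max = 7L) {
  if (!target %in% names(row)) {
    abort(paste0("target tissue '", target, "' absent from row"))
  }
  n <- length(row)
  ord <- order(-row, names(row))
  sv <- unname(row[ord])
  labs <- names(row)[ord]
  pos_t <- match(target, labs)
  kmax <- min(group_max, n - 1L)
  for (k in seq(from = group_min, by = 1L, length.out = max(0L, kmax - group_min + 1L))) {
    if (pos_t <= k && sv[k] >= fold * sv[k + 1L]) {
      return(labs[seq_len(k)])
    }
  }
  NULL
}

#' Classify one gene's per-tissue profile
#'
#' Applies the six-category scheme for a single gene. Rules are tested in
#' precedence order: not detected (target FPKM below the detection cutoff),
#' tissue enriched (target at least `fold` times every other tissue), group
#' enriched (a 2-7 tissue group including the target is `fold`-fold above all
#' the rest), tissue enhanced (target at least `fold` times the mean FPKM over
#' all tissues), expressed in all (detected in every tissue), and mixed (the
#' remainder). Fold comparisons and the detection cutoff are inclusive (`>=`).
#'
#' @inheritParams find_enriched_group
#' @param detection_cutoff FPKM detection limit (default 1, roughly one mRNA
#'   per cell).
#' @return One-row tibble with `gene` (NA here; filled by
#'   [classify_tissue_specificity()]), `category`, `score`, `group`
#'   (semicolon-joined tissues, `NA` unless group enriched), and `n_detected`.
#' @export
classify_gene <- function(row, target, detection_cutoff = 1, fold = 5,
                          group_min = 2L, group_max = 7L) {
  prof <- tibble(gene = "g", !!!as.list(row))
  res <- classify_tissue_specificity(
    prof, target,
    detection_cutoff = detection_cutoff, fold = fold,
    group_min = group_min, group_max = group_max
  )
  as_tibble(res)[, c("category", "score", "group", "n_detected")]
}

#' Classify every gene of a tissue profile
#'
#' Assigns each gene exactly one of the six specificity categories for the
#' chosen target tissue, together with its tissue-specific score, its enriched
#' tissue group (when group enriched) and the number of tissues in which it is
#' detected. Genes classified tissue enriched, group enriched or tissue
#' enhanced are jointly termed "elevated".
#'
#' @param profile Tissue profile tibble (`gene` + one FPKM column per tissue),
#'   e.g. from [average_replicates()].
#' @param target Target tissue label (a column of `profile`).
#' @inheritParams classify_gene
#' @return A tibble of class `"spec_class"` with columns `gene`,
#'   `category` (factor over [spec_categories()]), `score`, `group`,
#'   `n_detected`, carrying the classification parameters as attributes.
#'   Use [glance()] for the category census and [category_census()] for a
#'   per-category count table.
#' @examples
#' prof <- tibble::tibble(gene = c("a", "b"),
#'                        pancreas = c(10, 0.5), liver = c(1, 0), brain = c(2, 0))
#' classify_tissue_specificity(prof, "pancreas")
#' @export
classify_tissue_specificity <- function(profile, target, detection_cutoff = 1,
                                        fold = 5, group_min = 2L, group_max = 7L) {
  profile <- validate_fpkm(profile)
  tissues <- names(profile)[-1]
  if (!target %in% tissues) {
    abort(paste0("target tissue '", target, "' is not a column of the profile"))
  }
  if (length(tissues) < 2L) {
    abort("profile must contain the target and at least one other tissue")
  }
  stopifnot(detection_cutoff > 0, fold > 1, group_min >= 2L, group_min <= group_max)

  m <- as.matrix(profile[, -1, drop = FALSE])
  nt <- ncol(m)
  tcol <- m[, target]
  other <- m[, setdiff(tissues, target), drop = FALSE]
  other_max <- do.call(pmax, c(as.data.frame(other), list(na.rm = FALSE)))
  score <- unname(score_convention(unname(tcol), unname(other_max)))
  n_detected <- rowSums(m >= detection_cutoff)
  row_mean <- rowMeans(m)

  detected <- tcol >= detection_cutoff
  category <- rep(NA_character_, nrow(m))
  group <- rep(NA_character_, nrow(m))

  category[!detected] <- "not_detected"
  enriched <- detected & (tcol >= fold * other_max)
  category[enriched] <- "tissue_enriched"

  # Group search only where the higher-precedence rules did not fire.
  todo <- which(is.na(category))
  for (i in todo) {
    g <- find_enriched_group(m[i, ], target, fold = fold,
                             group_min = group_min, group_max = group_max)
    if (!is.null(g)) {
      category[i] <- "group_enriched"
      group[i] <- paste(g, collapse = ";")
    }
  }

  left <- is.na(category)
  enhanced <- left & (tcol >= fold * row_mean)
  category[enhanced] <- "tissue_enhanced"
  left <- is.na(category)
  category[left & n_detected == nt] <- "expressed_in_all"
  category[is.na(category)] <- "mixed"

  out <- tibble(
    gene = profile$gene,
    category = factor(category, levels = SPEC_CATEGORIES),
    score = score,
    group = group,
    n_detected = as.integer(n_detected)
  )
  structure(
    out,
    class = c("spec_class", class(out)),
    target = target,
    params = list(detection_cutoff = detection_cutoff, fold = fold,
                  group_min = as.integer(group_min), group_max = as.integer(group_max)),
    tissues = tissues
  )
}

#' Category census of a classification
#'
#' Counts genes per specificity category (all six categories always appear,
#' zero-filled) plus the elevated total.
#'
#' @param classes A classification tibble from [classify_tissue_specificity()].
#' @return Tibble with columns `category`, `n_genes`.
#' @export
category_census <- function(classes) {
  tab <- table(factor(classes$category, levels = SPEC_CATEGORIES))
  tibble(category = factor(SPEC_CATEGORIES, levels = SPEC_CATEGORIES),
         n_genes = as.integer(tab))
}

#' Gene identifiers of elevated genes
#'
#' @param classes A classification tibble.
#' @return Character vector of genes whose category is tissue enriched, group
#'   enriched or tissue enhanced.
#' @export
elevated_genes <- function(classes) {
  classes$gene[classes$category %in% ELEVATED_CATEGORIES]
}

#' @exportS3Method generics::tidy
tidy.spec_class <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @exportS3Method generics::glance
glance.spec_class <- function(x, ...) {
  cen <- category_census(x)
  wide <- as.list(setNames(cen$n_genes, as.character(cen$category)))
  tibble(
    target = attr(x, "target") %||% NA_character_,
    n_genes = nrow(x),
    !!!wide,
    elevated = sum(cen$n_genes[as.character(cen$category) %in% ELEVATED_CATEGORIES])
  )
}

#' Write a classification table
#'
#' TSV with columns gene, category, score (`inf` for the infinite sentinel,
#' `NA` when undefined), group (semicolon-joined tissues) and n_detected.
#'
#' @param classes Classification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classes, path) {
  out <- tidy.spec_class(classes)
  out$score <- ifelse(is.infinite(out$score), "inf",
                      ifelse(is.na(out$score), "NA", format(out$score, digits = 15, trim = TRUE)))
  out$category <- as.character(out$category)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
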