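# Independent brute-force oracles and fixture builders. These never call the
# code paths they check.

# Exhaustive group search: enumerate every subset of size gmin..gmax that
# contains the target and test the qualifying predicate directly.
# Returns list(found, min_size, sets) where sets holds all qualifying subsets
# of the minimal size (as sorted label vectors).
exhaustive_group_search <- function(row, target, fold = 5, gmin = 2, gmax = 7) {
  tissues <- names(row)
  others <- setdiff(tissues, target)
  n <- length(tissues)
  for (k in gmin:min(gmax, n - 1)) {
    hits <- list()
    for (idx in utils::combn(length(others), k - 1, simplify = FALSE)) {
      members <- c(target, others[idx])
      outside <- setdiff(tissues, members)
      if (min(row[members]) >= fold * max(row[outside])) {
        hits[[length(hits) + 1L]] <- sort(members)
      }
    }
    if (length(hits) > 0L) {
      return(list(found = TRUE, min_size = k, sets = hits))
    }
  }
  list(found = FALSE, min_size = NA_integer_, sets = list())
}

# The qualifying predicate itself, for checking a returned group.
group_qualifies <- function(row, members, fold = 5) {
  outside <- setdiff(names(row), members)
  min(row[members]) >= fold * max(row[outside])
}

# Spearman rho via explicit average-rank computation and the Pearson sum
# formula (no rank(), no cor()).
manual_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Random per-tissue FPKM row with zeros and ties, target guaranteed detected.
random_row <- function(n_tissues = 10, target = "t01") {
  tissues <- sprintf("t%02d", seq_len(n_tissues))
  v <- round(stats::rlnorm(n_tissues, meanlog = 1, sdlog = 2), 1)
  v[stats::runif(n_tissues) < 0.2] <- 0
  names(v) <- tissues
  v[target] <- max(v[target], 1)
  v
}

# Small wide FPKM fixture: gene column + named sample columns from a matrix.
fpkm_tbl <- function(m, genes = sprintf("g%d", seq_len(nrow(m)))) {
  tibble::tibble(gene = genes, !!!as.list(as.data.frame(m)))
}

annotation_tbl <- function(sample_id, tissue, compartment = "whole",
                           lane = NA_character_) {
  tibble::tibble(
    sample_id = sample_id, tissue = tissue,
    donor = paste0("d", seq_along(sample_id)),
    compartment = compartment, lane = lane
  )
}
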