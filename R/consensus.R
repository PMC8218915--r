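# Consensus layer: aggregate selected gene sets across repeated runs or
# datasets and extract genes recurring in pairwise intersections.

#' Genes recurring in pairwise intersections of selection sets
#'
#' All unordered pairs of entries are intersected; the module is the union
#' of those intersections, and each gene's support is the number of pairs
#' whose intersection contains it (equivalently, `choose(k, 2)` for a
#' gene occurring in `k` entries). Genes below `min_support` pairs are
#' dropped. With `harmonize = TRUE` gene ids are matched case-insensitively
#' across entries (symbol-style harmonisation); ids that still match
#' nothing pass through untouched.
#'
#' @param collection a `SelectionCollection` from [stability_select()], or
#'   any named list of non-empty character vectors (one per dataset/run).
#' @param min_support minimum number of supporting pairs (default 1).
#' @param harmonize case-fold gene ids before matching (default `FALSE`).
#' @return A `BiomarkerModule`: list with `genes` (character, by
#'   decreasing support then id) and `support` (named integer, pairs per
#'   gene). Empty when no gene recurs — not an error.
#' @examples
#' pairwise_recurrence(list(a = c("A", "B", "C"),
#'                          b = c("B", "C", "D"),
#'                          c = "E"))
#' @export
pairwise_recurrence <- function(collection, min_support = 1L,
                                harmonize = FALSE) {
  entries <- if (inherits(collection, "SelectionCollection"))
    collection$entries else collection
  if (!is.list(entries) || length(entries) < 2L)
    stop("at least two selection sets are required")
  if (is.null(names(entries)) || anyDuplicated(names(entries)))
    stop("entries must have unique names")
  if (any(lengths(entries) == 0L)) stop("selection sets must be non-empty")
  entries <- lapply(entries, function(e) unique(as.character(e)))
  key <- if (harmonize) function(x) toupper(x) else identity
  # display casing: first occurrence wins
  all_ids <- unlist(entries, use.names = FALSE)
  display <- all_ids[!duplicated(key(all_ids))]
  names(display) <- key(display)
  occ <- table(unlist(lapply(entries, function(e) unique(key(e))),
                      use.names = FALSE))
  support <- occ * (occ - 1L) / 2L  # pairs containing the gene
  support <- support[support >= max(1L, min_support)]
  genes <- display[names(support)]
  sup <- as.integer(support)
  ord <- order(-sup, genes, method = "radix")
  structure(list(genes = unname(genes[ord]),
                 support = stats::setNames(sup[ord], unname(genes[ord]))),
            class = "BiomarkerModule")
}

#' @export
print.BiomarkerModule <- function(x, ...) {
  cat(sprintf("BiomarkerModule: %d gene(s)\n", length(x$genes)))
  if (length(x$genes)) {
    show <- utils::head(x$genes, 10L)
    cat("  ", paste(sprintf("%s(%d)", show, x$support[show]),
                    collapse = " "), "\n")
    if (length(x$genes) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Repeated pipeline runs for stability selection
#'
#' Runs [run_frl()] once per seed on the same matrix and collects the
#' selected gene sets; feed the result to [pairwise_recurrence()] to
#' extract the recurring (stable) genes.
#'
#' @param mat labelled [expression_matrix()].
#' @param config an [frl_config()].
#' @param seeds integer vector of length >= 2, one pipeline run per seed.
#' @return A `SelectionCollection`: list with `entries` (named list of
#'   gene-id vectors) and `provenance` (data frame: name, seed, n_selected).
#' @export
stability_select <- function(mat, config = frl_config(), seeds = 1:5) {
  if (length(seeds) < 2L) stop("at least two seeds are required")
  entries <- vector("list", length(seeds))
  names(entries) <- sprintf("run%02d_seed%d", seq_along(seeds), seeds)
  for (i in seq_along(seeds)) {
    res <- run_frl(mat, config, seed = seeds[i])
    entries[[i]] <- res$selected_features
  }
  structure(list(entries = entries,
                 provenance = data.frame(name = names(entries),
                                         seed = as.integer(seeds),
                                         n_selected = lengths(entries))),
            class = "SelectionCollection")
}

#' @export
print.SelectionCollection <- function(x, ...) {
  cat(sprintf("SelectionCollection: %d entries\n", length(x$entries)))
  print(x$provenance, row.names = FALSE)
  invisible(x)
}
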