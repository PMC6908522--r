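## Cross-study consensus: probe-to-gene collapse, the gene x study
## direction matrix, and the "winner DEG" vote-counting rule — a gene
## wins in a direction when it is called in that direction in at least
## `min_total` of the studies AND at least `min_lc` of the lung-cancer
## studies. Under the 6 LC + 4 LD design this reproduces "same direction
## in >= 7 of 10 sets including >= 5 of the 6 lung-cancer sets", which
## implies at least one or two supporting other-lung-disease sets.

#' Collapse a probe-level SAM result to gene level
#'
#' Each gene is represented by its mapped probe with maximum `|d|` (ties
#' broken by the lexicographically smallest probe label); the gene
#' inherits that probe's statistics. Unmapped probes are dropped and
#' counted in attribute `n_unmapped`.
#'
#' @param sam a `SamResult` whose features are probes.
#' @param probe_map named character vector probe -> gene symbol, as from
#'   [read_probe_map()].
#' @return a `SamResult` whose features are gene symbols.
#' @export
collapse_to_genes <- function(sam, probe_map) {
  tab <- sam$table
  mapped <- tab$feature %in% names(probe_map)
  if (!any(mapped))
    stop_consensus("no probes of study '%s' appear in the probe map", sam$study_id)
  n_unmapped <- sum(!mapped)
  tab <- tab[mapped, , drop = FALSE]
  tab$gene <- unname(probe_map[tab$feature])
  ## representative probe: max |d|, then smallest probe label
  tab <- tab[order(tab$gene, -abs(tab$d), tab$feature), , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  tab$feature <- tab$gene
  tab$gene <- NULL
  rownames(tab) <- NULL
  out <- sam
  out$table <- tab
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build the gene x study direction matrix
#'
#' Entry is the call direction (`+1`/`-1`) when the gene is called at
#' `q < q_threshold` in that study, else `0`. The gene universe is the
#' union over studies; genes absent from a study's platform get `0`,
#' with the absence recorded in a separate logical mask.
#'
#' @param sam_list list of (gene-level) `SamResult` objects with unique
#'   study ids.
#' @param q_threshold call threshold applied to the stored q-values.
#' @return an object of class `ConsensusTable`: `directions` (integer
#'   matrix genes x studies), `absent` (logical mask, same shape),
#'   `disease_class` (per study).
#' @export
direction_matrix <- function(sam_list, q_threshold = 0.01) {
  if (!length(sam_list)) stop_consensus("need at least one study")
  ids <- vapply(sam_list, `[[`, character(1), "study_id")
  if (anyDuplicated(ids))
    stop_consensus("duplicate study ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- sort(unique(unlist(lapply(sam_list, function(s) s$table$feature))))
  dirs <- matrix(0L, length(genes), length(ids), dimnames = list(genes, ids))
  absent <- matrix(TRUE, length(genes), length(ids), dimnames = list(genes, ids))
  for (j in seq_along(sam_list)) {
    tab <- sam_list[[j]]$table
    idx <- match(tab$feature, genes)
    absent[idx, j] <- FALSE
    called <- tab$q < q_threshold
    dirs[idx[called], j] <- as.integer(tab$direction[called])
  }
  structure(list(directions = dirs, absent = absent,
                 disease_class = vapply(sam_list, `[[`, character(1),
                                        "disease_class")),
            class = "ConsensusTable")
}

#' Apply the winner-DEG consensus rule
#'
#' A gene is a winner in direction `sigma` iff at least `min_total`
#' studies and at least `min_lc` LC studies call it in direction
#' `sigma`. With `min_total` above half the studies a gene cannot win in
#' both directions, so the up/down winner sets are disjoint.
#'
#' @param table a `ConsensusTable`.
#' @param min_total minimum supporting studies overall.
#' @param min_lc minimum supporting lung-cancer studies.
#' @return list with `up`, `down` (character gene sets) and `support`, a
#'   data frame (gene, direction, n_support, n_lc_support) for winners.
#' @export
winner_genes <- function(table, min_total = 7, min_lc = 5) {
  cls <- table$disease_class
  n_lc <- sum(cls == "LC")
  if (min_lc > n_lc)
    stop_config("min_lc = %d exceeds the %d LC studies", min_lc, n_lc)
  d <- table$directions
  lc <- cls == "LC"
  win_dir <- function(sigma) {
    hit <- d == sigma
    total <- rowSums(hit)
    lc_hit <- rowSums(hit[, lc, drop = FALSE])
    rownames(d)[total >= min_total & lc_hit >= min_lc]
  }
  up <- win_dir(1L); down <- win_dir(-1L)
  both <- intersect(up, down)
  if (length(both))
    warning("genes winning in both directions (min_total too small): ",
            paste(both, collapse = ", "))
  sup <- function(g, sigma) {
    hit <- d[g, , drop = FALSE] == sigma
    data.frame(gene = g, direction = sigma, n_support = rowSums(hit),
               n_lc_support = rowSums(hit[, lc, drop = FALSE]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  support <- rbind(if (length(up)) sup(up, 1L), if (length(down)) sup(down, -1L))
  list(up = up, down = down,
       support = support %||% data.frame(gene = character(0),
                                         direction = integer(0),
                                         n_support = integer(0),
                                         n_lc_support = integer(0)))
}
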