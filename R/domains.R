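# Domain-composition comparison across a gene's validated protein isoforms.
# Four set relations between two isoforms' domain sets:
#   1_superset        one set strictly contains the other
#   2_partial_overlap sets share some domains and each has its own
#   3_disjoint        no domain in common
#   4_identical       same set
# Domains are compared as sets of accession strings; copy number is ignored.

DOMAIN_CATEGORIES <- c("1_superset", "2_partial_overlap", "3_disjoint",
                       "4_identical")

#' Classify the relation between two domain sets
#'
#' @param a,b nonempty character vectors of domain identifiers
#' @return one of `"4_identical"`, `"1_superset"`, `"2_partial_overlap"`,
#'   `"3_disjoint"`
#' @export
classify_domain_relation <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("no domains assigned")
  inter <- intersect(a, b)
  if (length(inter) == length(a) && length(inter) == length(b)) "4_identical"
  else if (length(inter) == length(a) || length(inter) == length(b)) "1_superset"
  else if (length(inter) == 0L) "3_disjoint"
  else "2_partial_overlap"
}

# divergence order used to aggregate >2 isoforms: the most divergent pair
# labels the gene (identical < superset < partial < disjoint)
.divergence_rank <- c("4_identical" = 1L, "1_superset" = 2L,
                      "2_partial_overlap" = 3L, "3_disjoint" = 4L)

#' Classify one gene from its validated isoforms' domain sets
#'
#' With more than two isoforms the gene is labelled by its most divergent
#' pairwise relation; the full pair list is retained for audit.
#'
#' @param domain_sets named list (isoform id -> character vector of domains);
#'   isoforms with zero domains are dropped with a reason
#' @return list: `category` (or `NA` when < 2 isoforms carry domains),
#'   `isoform_ids`, `pairs` (data.table of pairwise relations), `skipped`
#'   (reason string or NULL)
#' @export
classify_gene <- function(domain_sets) {
  keep <- lengths(lapply(domain_sets, unique)) > 0L
  dropped <- names(domain_sets)[!keep]
  domain_sets <- domain_sets[keep]
  if (length(domain_sets) < 2L)
    return(list(category = NA_character_, isoform_ids = names(domain_sets),
                pairs = NULL,
                skipped = paste0("fewer than 2 isoforms with domains",
                                 if (length(dropped))
                                   paste0(" (no domains: ",
                                          paste(dropped, collapse = ","), ")")
                                 else "")))
  ids <- names(domain_sets)
  cmb <- utils::combn(length(ids), 2L)
  pairs <- data.table::data.table(
    isoform_a = ids[cmb[1L, ]], isoform_b = ids[cmb[2L, ]],
    relation = vapply(seq_len(ncol(cmb)), function(k)
      classify_domain_relation(domain_sets[[cmb[1L, k]]],
                               domain_sets[[cmb[2L, k]]]), character(1L)))
  worst <- pairs$relation[which.max(.divergence_rank[pairs$relation])]
  list(category = worst, isoform_ids = ids, pairs = pairs, skipped = NULL)
}

#' Categorize all genes in a domain-assignment table
#'
#' @param domain_table output of [read_domain_table()] (or a `data.table`
#'   with `protein_id`, `gene_id`, `domain_set` list-column)
#' @param validated_ids optional character vector restricting to validated
#'   protein isoforms
#' @return list: `categories` (`data.table` gene_id, category, n_isoforms),
#'   `counts` (named integer vector over the four categories), `skipped`
#'   (`data.table` gene_id, reason)
#' @export
classify_domain_table <- function(domain_table, validated_ids = NULL) {
  dt <- data.table::as.data.table(domain_table)
  if (is.null(dt$domain_set))
    dt$domain_set <- lapply(strsplit(as.character(dt$domains), ";",
                                     fixed = TRUE),
                            function(x) unique(x[nzchar(x)]))
  if (!is.null(validated_ids)) dt <- dt[dt$protein_id %in% validated_ids]
  res <- list(); skipped <- list()
  for (g in unique(dt$gene_id)) {
    sub <- dt[dt$gene_id == g]
    sets <- setNames(sub$domain_set, sub$protein_id)
    cl <- classify_gene(sets)
    if (is.na(cl$category))
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        gene_id = g, reason = cl$skipped)
    else
      res[[length(res) + 1L]] <- data.table::data.table(
        gene_id = g, category = cl$category,
        n_isoforms = length(cl$isoform_ids))
  }
  categories <- if (length(res)) data.table::rbindlist(res) else
    data.table::data.table(gene_id = character(), category = character(),
                           n_isoforms = integer())
  counts <- setNames(integer(length(DOMAIN_CATEGORIES)), DOMAIN_CATEGORIES)
  tab <- table(categories$category)
  counts[names(tab)] <- as.integer(tab)
  list(categories = categories, counts = counts,
       skipped = if (length(skipped)) data.table::rbindlist(skipped) else
         data.table::data.table(gene_id = character(), reason = character()))
}
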