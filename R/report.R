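# Study summary surfaces: tissue overlap arithmetic, protein molecular
# weights, and hypergeometric term enrichment.

#' Overlap summary of two identifier sets
#'
#' Exact set arithmetic plus the shares conventionally reported alongside a
#' two-set Venn diagram (integer-rounded percents).
#'
#' @param set_a,set_b character vectors (duplicates ignored)
#' @return list: n_a, n_b, n_intersection, n_union, n_a_specific,
#'   n_b_specific, share_intersection_of_union, share_intersection_of_a,
#'   share_intersection_of_b (integer percents)
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  ni <- length(intersect(a, b)); nu <- length(union(a, b))
  stopifnot(nu == length(a) + length(b) - ni)  # Venn identity, always checked
  list(n_a = length(a), n_b = length(b), n_intersection = ni, n_union = nu,
       n_a_specific = length(a) - ni, n_b_specific = length(b) - ni,
       share_intersection_of_union = if (nu) percent_of(ni, nu, 0L) else 0,
       share_intersection_of_a = if (length(a)) percent_of(ni, length(a), 0L) else 0,
       share_intersection_of_b = if (length(b)) percent_of(ni, length(b), 0L) else 0)
}

# average residue masses (Da); intact-protein MW = sum + one water
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water, in kilodaltons.
#'
#' @param protein_seq amino-acid string over the 20 standard residues
#' @return mass in kDa
#' @export
molecular_weight <- function(protein_seq) {
  if (!nzchar(protein_seq)) stop("empty protein sequence")
  res <- strsplit(toupper(protein_seq), "")[[1L]]
  bad <- setdiff(res, names(AVG_RESIDUE_MASS))
  if (length(bad))
    stop("nonstandard residue '", bad[1L], "' in protein sequence")
  (sum(AVG_RESIDUE_MASS[res]) + WATER_MASS) / 1000
}

#' Molecular-weight histogram of a protein set
#'
#' @param proteins named character vector of sequences
#' @param bin_kda bin width in kDa (default 5)
#' @return `data.table`: bin_lo, bin_hi, n
#' @export
mw_histogram <- function(proteins, bin_kda = 5) {
  mw <- vapply(proteins, molecular_weight, numeric(1L))
  lo <- floor(mw / bin_kda) * bin_kda
  tab <- table(lo)
  data.table::data.table(bin_lo = as.numeric(names(tab)),
                         bin_hi = as.numeric(names(tab)) + bin_kda,
                         n = as.integer(tab))
}

#' Hypergeometric enrichment of annotation terms
#'
#' Upper-tail hypergeometric test per term: the probability of observing at
#' least `k` selected genes in a term of size `K`, drawing `n` genes from a
#' universe of `N`. Terms with raw p < `alpha` are reported enriched
#' (matching common annotation-tool practice); Benjamini-Hochberg adjusted
#' values are emitted alongside as the statistically safer criterion.
#'
#' @param term_sets named list: term -> character vector of gene ids (subsets
#'   of `universe`)
#' @param selected character vector, subset of `universe`
#' @param universe character vector of all gene ids
#' @param alpha raw-p cutoff, default 0.05
#' @return `data.table`: term, k, K, n, N, p, p_bh, enriched (raw p < alpha)
#' @export
hypergeom_enrich <- function(term_sets, selected, universe, alpha = 0.05) {
  universe <- unique(universe); selected <- unique(selected)
  if (!length(universe) || !length(selected))
    stop("empty universe or selection")
  if (!all(selected %in% universe))
    stop("selected genes not all in universe")
  n <- length(selected); N <- length(universe)
  rows <- lapply(names(term_sets), function(tm) {
    term <- unique(intersect(term_sets[[tm]], universe))
    K <- length(term)
    k <- length(intersect(term, selected))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.table::data.table(term = tm, k = k, K = K, n = n, N = N, p = p)
  })
  res <- data.table::rbindlist(rows)
  res$p_bh <- p.adjust(res$p, method = "BH")
  res$enriched <- res$p < alpha
  data.table::setorder(res, p)
  res[]
}
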