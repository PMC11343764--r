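#' Per-tip speciation-rate tables
#'
#' A `tip_rates` object is a data frame with columns `species` and `rate`
#' (events per lineage per Myr, strictly positive), carrying a `source`
#' attribute (`"dr"`, `"imported"` or `"synthetic"`) and, when derived
#' from a tree, a hash of that tree's topology and branch lengths.
#'
#' @param species Character vector of species names.
#' @param rate Positive numeric rates.
#' @param source Provenance tag.
#' @param tree Optional `phylo` the rates refer to (hashed for later
#'   consistency checks).
#' @return A `tip_rates` data frame.
#' @export
tip_rates <- function(species, rate, source = "imported", tree = NULL) {
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("duplicate species in rate table: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("non-positive rate for: ",
         paste(species[!is.finite(rate) | rate <= 0], collapse = ", "))
  out <- data.frame(species = species, rate = as.numeric(rate),
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  if (!is.null(tree)) attr(out, "tree_hash") <- hash_tree(tree)
  class(out) <- c("tip_rates", "data.frame")
  out
}

hash_tree <- function(tree) {
  txt <- ape::write.tree(tree)
  # small rolling hash; only used to flag tree/rates mismatches
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 2^31
}

#' Tip speciation rates by the DR (inverse equal-splits) statistic
#'
#' For tip `i` with root-to-tip edge lengths `l_1..l_N` ordered
#' pendant-first, the equal-splits measure is
#' `ES_i = sum_j l_j (1/2)^(j-1)` and `DR_i = 1 / ES_i`.  Any root edge
#' above the basal split is excluded (there are no splits above it to
#' weight).  DR is a tree-shape proxy for the recent speciation rate; it
#' applies no sampling-fraction correction.
#'
#' @param tree Rooted `phylo` with positive branch lengths.
#' @return A [tip_rates] object with `source = "dr"`.
#' @export
dr_statistic <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  len_to_parent <- numeric(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  len_to_parent[tree$edge[, 2L]] <- tree$edge.length
  root <- ntip + 1L
  pend <- len_to_parent[seq_len(ntip)]
  if (any(pend == 0))
    stop("zero-length pendant edge for tip(s): ",
         paste(tree$tip.label[pend == 0], collapse = ", "),
         " (DR undefined)")
  es <- numeric(ntip)
  for (i in seq_len(ntip)) {
    node <- i
    w <- 1
    acc <- 0
    while (node != root) {
      acc <- acc + len_to_parent[node] * w
      w <- w / 2
      node <- parent_of[node]
    }
    es[i] <- acc
  }
  tip_rates(tree$tip.label, 1 / es, source = "dr", tree = tree)
}

#' Read and validate an externally computed tip-rate table
#'
#' Reads a two-column CSV (`species,rate`), e.g. mean tip speciation rates
#' exported from a BAMM analysis, and validates it against a tree's tip
#' set when one is supplied.
#'
#' @param path CSV path with header `species,rate`.
#' @param tree Optional `phylo`; species must match its tips exactly.
#' @return A [tip_rates] object with `source = "imported"`.
#' @export
read_tiprate_table <- function(path, tree = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "rate") %in% names(tab)))
    stop("rate table must have columns 'species' and 'rate'")
  rates <- tip_rates(tab$species, tab$rate, source = "imported", tree = tree)
  if (!is.null(tree)) {
    extra <- setdiff(rates$species, tree$tip.label)
    missing <- setdiff(tree$tip.label, rates$species)
    if (length(extra))
      stop("species not in tree: ", paste(extra, collapse = ", "))
    if (length(missing))
      stop("tree tips missing from table: ",
           paste(missing, collapse = ", "))
  }
  rates
}
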