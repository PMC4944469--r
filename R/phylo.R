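#' Read / write a Newick phylogeny
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()] that
#' validate the result (unique tip labels, >= 2 tips, non-negative branch
#' lengths) so downstream covariance construction is safe.
#'
#' @param path file path.
#' @return `read_newick`: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("failed to parse Newick file: ", path, call. = FALSE)
  }
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (ape::Ntip(tree) < 2) stop("tree needs at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels must be unique", call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  invisible(tree)
}

# fold species names to a canonical form: trim, lower case,
# underscores -> spaces, collapse whitespace
normalize_species <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("_", " ", x, fixed = TRUE)
  gsub("[[:space:]]+", " ", x)
}

#' Prune a tree to the species of a dataset
#'
#' Species names are matched to tip labels after whitespace trimming,
#' case folding and underscore/space normalization. The tree is pruned to
#' the matched tips; species without a tip are reported and must be
#' excluded from phylogenetic analyses.
#'
#' @param tree an `ape::phylo`.
#' @param species_list character vector of species names (duplicates fine).
#' @return list with `tree` (pruned; tip labels renamed to the dataset
#'   spellings), `matched` (character), `unmatched` (character).
#' @export
prune_and_match <- function(tree, species_list) {
  sp <- unique(species_list)
  key_tree <- normalize_species(tree$tip.label)
  key_sp <- normalize_species(sp)
  idx <- match(key_sp, key_tree)
  matched <- sp[!is.na(idx)]
  unmatched <- sp[is.na(idx)]
  if (length(unmatched)) {
    warning("species not found on tree (excluded from phylogenetic analyses): ",
            paste(unmatched, collapse = ", "))
  }
  if (length(matched) < 2) {
    stop("fewer than 2 species match the tree; cannot run phylogenetic model",
         call. = FALSE)
  }
  keep <- tree$tip.label[idx[!is.na(idx)]]
  pruned <- ape::keep.tip(tree, keep)
  # keep.tip re-roots at the MRCA of the kept tips; carry the dropped
  # basal path as a root edge so shared-history covariances are preserved
  if (length(keep) < ape::Ntip(tree)) {
    depths <- ape::node.depth.edgelength(tree)
    mrca_depth <- if (length(keep) == 1) 0 else
      depths[ape::getMRCA(tree, keep)]
    stem <- (tree$root.edge %||% 0) + mrca_depth
    if (stem > 0) pruned$root.edge <- (pruned$root.edge %||% 0) + stem
  }
  # relabel tips with the dataset spellings so joins are exact
  m <- match(normalize_species(pruned$tip.label), key_sp)
  pruned$tip.label <- sp[m]
  list(tree = pruned, matched = matched, unmatched = unmatched)
}

#' Species covariance matrix of a tree
#'
#' Entry (i, j) is the shared branch length from the root to the most
#' recent common ancestor of tips i and j — the Brownian-motion trait
#' covariance. A root edge (e.g. the stem retained by
#' [prune_and_match()]) is shared by all tips and added to every entry.
#' With `scale_to_unit_height = TRUE` the matrix is divided by its
#' maximum diagonal, so an ultrametric tree has unit diagonals and the
#' phylogenetic variance component is comparable across trees.
#'
#' @param tree an `ape::phylo`.
#' @param scale_to_unit_height divide by the maximum diagonal.
#' @return symmetric positive semidefinite matrix with species dimnames.
#' @export
vcv_matrix <- function(tree, scale_to_unit_height = TRUE) {
  V <- ape::vcv(tree)
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    V <- V + tree$root.edge
  }
  if (scale_to_unit_height) V <- V / max(diag(V))
  V
}

#' Pagel-lambda transform of a species covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving diagonals
#' untouched: `lambda = 0` gives independent species, `lambda = 1` the
#' full Brownian expectation.
#'
#' @param V species covariance matrix.
#' @param lambda in \[0, 1\].
#' @return transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  W <- V * lambda
  diag(W) <- diag(V)
  W
}
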