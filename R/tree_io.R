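#' Read a phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the assembly
#' analyses need: unique tip labels and non-negative branch lengths, which are
#' required for patristic distances and betaMNTD.
#'
#' @param path path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick in ", path)
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths (required for betaMNTD)")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must be non-negative and non-missing")
  }
  tree
}

#' Write a tree as newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return Invisibly, `tree`.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Patristic (path-length) distances between tree tips
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return Symmetric tip-by-tip matrix of path lengths, zero diagonal.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' patristic_distances(tr)["A", c("B", "C")] # 2, 4
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
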