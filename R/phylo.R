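#' Read a newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract assumed
#' downstream: unique tip labels, branch lengths present (or imputed as a
#' stated constant), non-negative lengths, a single root.
#'
#' @param source path to a newick file, or (with `text = TRUE`) the newick
#'   string itself.
#' @param text logical; treat `source` as the newick string.
#' @param impute_length `NULL` (default: missing branch lengths are an error)
#'   or a single non-negative number used for every edge when the file carries
#'   no lengths.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(source, text = FALSE, impute_length = NULL) {
  tree <- suppressWarnings(
    if (text) ape::read.tree(text = source) else ape::read.tree(source)
  )
  if (is.null(tree)) stop("malformed newick: parser returned no tree")
  validate_phylogeny(tree, impute_length = impute_length)
}

#' Write a tree as newick text
#'
#' @param tree a `phylo` object.
#' @param file optional path; if omitted the newick string is returned.
#' @return the newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

validate_phylogeny <- function(tree, impute_length = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (is.null(impute_length)) {
      stop("tree has no branch lengths (set impute_length to impute a constant)")
    }
    stopifnot(is.numeric(impute_length), impute_length >= 0)
    tree$edge.length <- rep(impute_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must be non-negative and non-missing")
  }
  tree
}

#' Substitute stand-in tips for missing species
#'
#' Source phylogenies often lack some study species; the convention is to take
#' the closest relative available in the genus or family and relabel that tip
#' to the missing species. Topology and branch lengths are untouched.
#'
#' @param tree a `phylo` object.
#' @param table data frame with columns `missing_species` (new label) and
#'   `stand_in` (existing tip to relabel), or a named character vector
#'   `c(stand_in = missing_species)` is not accepted — use the data frame.
#' @return the relabeled tree.
#' @export
substitute_tips <- function(tree, table) {
  tree <- validate_phylogeny(tree)
  if (nrow(table) == 0L) return(tree)
  stopifnot(all(c("missing_species", "stand_in") %in% names(table)))
  absent <- setdiff(table$stand_in, tree$tip.label)
  if (length(absent)) {
    stop("stand-in tip(s) absent from tree: ", paste(absent, collapse = ", "))
  }
  clash <- intersect(table$missing_species, setdiff(tree$tip.label, table$stand_in))
  if (length(clash)) {
    stop("target label(s) already present in tree: ",
         paste(clash, collapse = ", "))
  }
  idx <- match(table$stand_in, tree$tip.label)
  tree$tip.label[idx] <- table$missing_species
  validate_phylogeny(tree)
}

#' Expand species tips to population-level tips
#'
#' Each listed tip is replaced by a polytomy of its population labels, each on
#' a pendant branch of length `epsilon/2`, so that populations of one species
#' sit at inter-population distance `epsilon` (effectively zero) while staying
#' distinguishable in the correlation matrix. Distances between tips of
#' different species change by at most `epsilon`. Singleton population lists
#' simply relabel the tip.
#'
#' @param tree a `phylo` object.
#' @param multiplicity named list: `tip label -> character vector of
#'   population labels`. Tips not listed are left alone.
#' @param epsilon inter-population distance; must be positive and below 1e-5.
#' @return the expanded tree.
#' @export
expand_populations <- function(tree, multiplicity, epsilon = 1e-6) {
  tree <- validate_phylogeny(tree)
  stopifnot(is.numeric(epsilon), epsilon > 0)
  if (epsilon >= 1e-5) {
    stop("epsilon must be << 1e-5 so populations are effectively coincident")
  }
  if (length(multiplicity) == 0L) return(tree)
  stopifnot(!is.null(names(multiplicity)),
            all(names(multiplicity) %in% tree$tip.label))
  new_labels <- unlist(multiplicity, use.names = FALSE)
  if (anyDuplicated(new_labels)) {
    stop("duplicated population label(s): ",
         paste(unique(new_labels[duplicated(new_labels)]), collapse = ", "))
  }
  clash <- intersect(new_labels, setdiff(tree$tip.label, names(multiplicity)))
  if (length(clash)) {
    stop("population label(s) collide with existing tips: ",
         paste(clash, collapse = ", "))
  }
  for (sp in names(multiplicity)) {
    pops <- multiplicity[[sp]]
    stopifnot(length(pops) >= 1L)
    if (length(pops) == 1L) {
      tree$tip.label[tree$tip.label == sp] <- pops
      next
    }
    pend <- epsilon / 2
    sub_txt <- paste0("(", paste0(pops, ":", format(pend, scientific = FALSE),
                                  collapse = ","), ");")
    sub <- ape::read.tree(text = sub_txt)
    sub$root.edge <- 0
    tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == sp))
  }
  validate_phylogeny(tree)
}

#' Prune a tree to a set of tips
#'
#' Induced subtree on `labels`: unary internal nodes are suppressed with their
#' branch lengths summed, so pairwise tip distances are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param labels tip labels to keep.
#' @return the pruned tree.
#' @export
prune_to <- function(tree, labels) {
  tree <- validate_phylogeny(tree)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  if (setequal(labels, tree$tip.label)) return(tree)
  ape::keep.tip(tree, labels)
}

#' Brownian-motion correlation matrix of a phylogeny
#'
#' Under Brownian motion the covariance between two tips is the shared branch
#' length on their root-to-tip paths (the depth of their most recent common
#' ancestor); the correlation divides by the geometric mean of the two tip
#' depths, so non-ultrametric trees are handled without assuming equal depths.
#' The result is symmetric, has unit diagonal, entries in \[0, 1\], and is
#' positive semidefinite.
#'
#' @param tree a rooted `phylo` object with all root-to-tip depths positive.
#' @param ridge optional non-negative ridge added to the diagonal
#'   (`R + ridge * I`, default 0) for downstream solves that report
#'   near-singularity; a message is emitted whenever it is active.
#' @return correlation matrix with tip labels as dimnames.
#' @export
bm_correlation <- function(tree, ridge = 0) {
  tree <- validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  depths <- diag(V)
  if (any(depths <= 0)) {
    stop("zero-depth tip(s): ",
         paste(rownames(V)[depths <= 0], collapse = ", "),
         " (correlation undefined)")
  }
  R <- V / sqrt(outer(depths, depths))
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (ridge > 0) {
    message("bm_correlation: adding ridge ", ridge, " to the diagonal")
    R <- R + diag(ridge, nrow(R))
    R <- R / R[1, 1]  # keep unit diagonal after the ridge
  }
  R
}

#' Write a labeled correlation matrix as CSV
#'
#' @param R square labeled matrix.
#' @param file output path.
#' @export
write_correlation_csv <- function(R, file) {
  utils::write.csv(as.data.frame(R), file, row.names = TRUE)
  invisible(file)
}

#' Read a substitution table (missing_species, stand_in) from CSV
#'
#' @param file path to a two-column CSV.
#' @return data frame with columns `missing_species`, `stand_in`.
#' @export
read_substitution_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("missing_species", "stand_in") %in% names(tab)))
  tab
}
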