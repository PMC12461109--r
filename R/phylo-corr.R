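#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Every edge must carry a
#' branch length and tip labels must be unique; violations raise informative
#' errors. Trees are returned as standard `"phylo"` objects so that all of
#' \pkg{ape} remains available downstream.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @return A `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  off <- newick_syntax_offset(text)
  if (!is.na(off)) {
    stop(sprintf("malformed Newick string near character offset %d", off),
         call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string (could not be parsed)", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop("every edge must have a branch length", call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  }
  tree
}

# Cheap syntactic scan: returns the 1-based character offset of the first
# structural problem (unbalanced parenthesis or missing terminal ';'), NA if
# the string looks structurally sound. Finer-grained syntax is left to ape.
newick_syntax_offset <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  if (!any(chars == ";")) return(length(chars))
  NA_integer_
}

#' Read a set of trees (one Newick string per line)
#'
#' @param path Path to a file with one Newick tree per line.
#' @return A list of `"phylo"` objects.
#' @export
read_tree_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no trees found in ", path, call. = FALSE)
  lapply(lines, parse_newick)
}

#' Write a set of trees, one Newick string per line
#'
#' @param trees A `"phylo"` object or list of them.
#' @param path Output file path.
#' @export
write_tree_set <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr) ape::write.tree(tr), character(1))
  writeLines(txt, path)
  invisible(path)
}

# Root-to-tip depth of every tip, in tree units.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

#' Phylogenetic correlation matrix from an ultrametric tree
#'
#' Builds the species-by-species correlation matrix `C` whose entry (j,k) is
#' the shared root-to-divergence path length of species j and k divided by the
#' total tree depth. The tree is implicitly normalised to unit depth, so `C`
#' is a correlation matrix (unit diagonal) regardless of the time units of the
#' input tree. Non-ultrametric trees are rejected: the Pagel's-lambda
#' machinery in this package assumes a correlation structure, and silently
#' coercing a non-clock tree would change the model.
#'
#' @param tree A `"phylo"` object, ultrametric within `tol` (relative
#'   root-to-tip depth spread).
#' @param species Character vector of species to keep, in the desired matrix
#'   order. Defaults to all tips in the tree's own order. Tips not listed are
#'   pruned before the computation.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return A symmetric positive semi-definite matrix with unit diagonal and
#'   `species` as dimnames.
#' @examples
#' correlation_from_tree(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
correlation_from_tree <- function(tree, species = NULL, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(species)) species <- tree$tip.label
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp) > 0L) {
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species)) stop("duplicated species requested", call. = FALSE)
  if (length(species) < ape::Ntip(tree)) {
    tree <- ape::keep.tip(tree, species)
  }
  dep <- tip_depths(tree)
  depth <- max(dep)
  if (depth <= 0) stop("tree has zero depth", call. = FALSE)
  if ((max(dep) - min(dep)) / depth > tol) {
    stop("tree is not ultrametric within tolerance; ",
         "normalize root-to-tip depths (e.g. with ape::chronos) before use",
         call. = FALSE)
  }
  V <- ape::vcv.phylo(tree)           # shared path lengths, tree units
  C <- V / depth
  diag(C) <- 1                        # exact unit diagonal by construction
  C <- (C + t(C)) / 2
  C <- C[species, species, drop = FALSE]
  validate_phylo_corr(C)
  C
}

#' Validate a phylogenetic correlation matrix
#'
#' Checks symmetry, unit diagonal, entries in `[0, 1]` and positive
#' semi-definiteness (smallest eigenvalue >= -1e-8).
#'
#' @param C Square numeric matrix with species dimnames.
#' @return `C`, invisibly, if valid; otherwise an error.
#' @export
validate_phylo_corr <- function(C) {
  stopifnot(is.matrix(C), is.numeric(C), nrow(C) == ncol(C))
  if (is.null(rownames(C)) || !identical(rownames(C), colnames(C))) {
    stop("correlation matrix must carry matching species dimnames",
         call. = FALSE)
  }
  if (max(abs(C - t(C))) > 1e-10) stop("matrix not symmetric", call. = FALSE)
  if (max(abs(diag(C) - 1)) > 1e-10) stop("diagonal must be 1", call. = FALSE)
  if (min(C) < -1e-10 || max(C) > 1 + 1e-10) {
    stop("entries must lie in [0, 1]", call. = FALSE)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(C)
}

#' Pagel's lambda transform of a correlation matrix
#'
#' Multiplies all off-diagonal entries by `lam`, leaving the diagonal at 1:
#' `lam = 1` preserves the full phylogenetic correlation, `lam = 0` yields the
#' identity (no phylogenetic signal). Equivalently
#' `lam * C + (1 - lam) * I`, which keeps the result positive semi-definite
#' for `lam` in `[0, 1]`.
#'
#' @param C Phylogenetic correlation matrix (see [correlation_from_tree()]).
#' @param lam Scalar in `[0, 1]`.
#' @return The transformed correlation matrix.
#' @export
lambda_transform <- function(C, lam) {
  stopifnot(is.numeric(lam), length(lam) == 1L)
  if (is.na(lam) || lam < 0 || lam > 1) {
    stop("lam must lie in [0, 1]", call. = FALSE)
  }
  out <- lam * C
  diag(out) <- 1
  out
}
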