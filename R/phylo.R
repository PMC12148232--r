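#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates the result for use in
#' comparative analyses: the tree must be rooted, tip labels must be unique,
#' and branch lengths (if present) must be finite and non-negative. Files with
#' a `.phy` extension are treated as plain newick, as is common for composite
#' supertrees. Internal node labels are retained but ignored downstream.
#'
#' @param path Path to a newick file.
#' @return An object of class `"phylo"`. If the file carries no branch
#'   lengths the returned tree has `attr(tree, "missing_lengths") = TRUE`
#'   rather than silently zeroed lengths.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) stop("newick parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("newick parse error in '", path,
                          "': no tree could be read", call. = FALSE)
  validate_phylo(tree)
}

#' Parse a newick string
#'
#' @param text A newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @return A validated `"phylo"` object (see [read_newick()]).
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("newick parse error: no tree could be read",
                          call. = FALSE)
  validate_phylo(tree)
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    attr(tree, "missing_lengths") <- TRUE
  } else {
    if (any(!is.finite(tree$edge.length)))
      stop("non-finite branch lengths", call. = FALSE)
    if (any(tree$edge.length < 0))
      stop("negative branch lengths", call. = FALSE)
  }
  tree
}

#' Write a phylogeny to a newick file
#'
#' Round-trip safe within double precision (lengths written with 12
#' significant digits).
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Assign branch lengths to a topology by Nee's method
#'
#' Composite supertrees have no meaningful branch lengths. Nee's method (as
#' implemented in Mesquite) sets the height of every internal node above the
#' tips to the natural log of its number of descendant tips, with all tips at
#' height 0; each branch length is then the parent height minus the child
#' height. The result is ultrametric. Any existing branch lengths are
#' discarded.
#'
#' @param tree A `"phylo"` object (topology only is used).
#' @return A `"phylo"` object with Nee branch lengths. A warning is emitted
#'   for zero-length branches arising from nodes whose parent subtends the
#'   same number of tips (unifurcation-like configurations).
#' @export
nee_branch_lengths <- function(tree) {
  tree <- validate_phylo(tree)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  ntips_below <- integer(n_tip + n_node)
  ntips_below[seq_len(n_tip)] <- 1L
  # postorder edge traversal accumulates descendant-tip counts
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
  }
  height <- ifelse(ntips_below > 1L, log(ntips_below), 0)
  el <- height[tree$edge[, 1]] - height[tree$edge[, 2]]
  if (any(el == 0))
    warning("zero-length branches produced (parent and child subtend equal tip counts)")
  tree$edge.length <- el
  attr(tree, "missing_lengths") <- NULL
  tree
}

#' Phylogenetic covariance matrix
#'
#' Builds the Brownian-motion covariance structure of a tree: entry (i, j) is
#' the shared path length from the root to the most recent common ancestor of
#' tips i and j, and the diagonal holds root-to-tip lengths.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return A symmetric matrix with tip labels as dimnames and attribute
#'   `"lambda" = 1`.
#' @export
phylo_covariance <- function(tree) {
  tree <- validate_phylo(tree)
  if (is.null(tree$edge.length) || isTRUE(attr(tree, "missing_lengths")))
    stop("tree has no branch lengths; edges ",
         paste(seq_len(nrow(tree$edge)), collapse = ","), " are unlengthed")
  C <- ape::vcv.phylo(tree)
  attr(C, "lambda") <- 1
  C
}

#' Pagel's lambda transformation of a covariance matrix
#'
#' Multiplies the off-diagonal entries by `lam` and leaves the diagonal
#' unchanged. `lam = 1` returns the input; `lam = 0` gives the star-phylogeny
#' (diagonal) structure. The result is positive semi-definite for any
#' `lam` in \[0, 1\].
#'
#' @param C Covariance matrix from [phylo_covariance()].
#' @param lam Scalar in \[0, 1\].
#' @return Transformed covariance matrix; attribute `"lambda"` is updated
#'   multiplicatively.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  d <- diag(C)
  C2 <- C * lam
  diag(C2) <- d
  attr(C2, "lambda") <- lam * (attr(C, "lambda") %||% 1)
  C2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescale a tree by Pagel's lambda
#'
#' Tree-space equivalent of [lambda_transform()]: internal edges are
#' multiplied by `lam` and each terminal edge is extended so every
#' root-to-tip distance is preserved. The covariance matrix of the rescaled
#' tree equals the lambda-transformed covariance of the original.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param lam Scalar in \[0, 1\].
#' @return A rescaled `"phylo"` object.
#' @export
lambda_rescale_tree <- function(tree, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  tree <- validate_phylo(tree)
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tip_edge <- tree$edge[, 2] <= n_tip
  el <- tree$edge.length * lam
  el[tip_edge] <- el[tip_edge] + (1 - lam) * depth[tree$edge[tip_edge, 2]]
  tree$edge.length <- el
  tree
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts algorithm: standardized differences at each
#' internal node of a bifurcating tree, computed in postorder with ancestral
#' values by precision-weighted averaging and branch-length adjustment.
#' Polytomies are resolved deterministically (left-to-right, zero-length
#' internal branches) before computation. A contrast whose expected variance
#' is zero is an error unless the two descendant values are equal (the
#' contrast is then 0); zero-variance contrasts with equal values are given a
#' nominal variance of the smallest positive branch-length sum times 1e-6 so
#' downstream regressions remain defined.
#'
#' @param tree A `"phylo"` object with branch lengths, pruned to the tips in
#'   `values`.
#' @param values Named numeric vector; names must match `tree$tip.label`.
#' @return An object of class `"contrast_set"`: a list with `contrasts`
#'   (standardized, length n tips - 1), `expected_variances` (branch-length
#'   sums), and `node_ids` (internal node numbers of the resolved tree).
#' @export
independent_contrasts <- function(tree, values) {
  tree <- validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(names(values)))
    stop("'values' must be named by tip label")
  if (!setequal(names(values), tree$tip.label))
    stop("tip labels and value names do not match")
  if (any(is.na(values))) stop("missing trait values; prune first")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  n_tip <- length(tree$tip.label)
  x <- numeric(n_tip + tree$Nnode)
  x[seq_len(n_tip)] <- values[tree$tip.label]
  bl_adj <- numeric(n_tip + tree$Nnode)      # adjusted pendant length per node
  bl_adj[tree$edge[, 2]] <- tree$edge.length
  pos <- tree$edge.length[tree$edge.length > 0]
  v_floor <- if (length(pos)) min(pos) * 1e-6 else 1e-6

  eo <- ape::reorder.phylo(tree, "postorder")
  nodes <- unique(eo$edge[, 1])              # postorder internal nodes
  contrasts <- numeric(length(nodes))
  variances <- numeric(length(nodes))
  children <- split(eo$edge[, 2], eo$edge[, 1])
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    ch <- children[[as.character(nd)]]
    stopifnot(length(ch) == 2L)
    v1 <- bl_adj[ch[1]]; v2 <- bl_adj[ch[2]]
    vs <- v1 + v2
    d <- x[ch[1]] - x[ch[2]]
    if (vs <= 0) {
      if (abs(d) > 1e-12)
        stop("zero expected variance with unequal descendant values at node ", nd)
      vs_used <- v_floor
    } else vs_used <- vs
    contrasts[k] <- if (d == 0) 0 else d / sqrt(vs_used)
    variances[k] <- vs_used
    x[nd] <- if (d == 0 || vs <= 0) x[ch[1]]
             else (x[ch[1]] / v1 + x[ch[2]] / v2) / (1 / v1 + 1 / v2)
    if (d != 0 && vs > 0 && (v1 == 0 || v2 == 0)) # zero-length child dominates
      x[nd] <- if (v1 == 0) x[ch[1]] else x[ch[2]]
    bl_adj[nd] <- bl_adj[nd] + if (vs <= 0) 0 else v1 * v2 / vs
  }
  structure(list(contrasts = contrasts, expected_variances = variances,
                 node_ids = nodes),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Independent contrasts:", length(x$contrasts), "contrasts\n")
  print(summary(x$contrasts))
  invisible(x)
}

#' Prune a tree and trait table to a shared species set
#'
#' @param tree A `"phylo"` object.
#' @param species Character vector of tip labels to keep.
#' @return Pruned `"phylo"` object.
#' @export
prune_to <- function(tree, species) {
  keep <- intersect(tree$tip.label, species)
  if (length(keep) < 2L) stop("fewer than two matching tips")
  ape::keep.tip(tree, keep)
}

#' Export a covariance matrix as labelled CSV
#'
#' @param C Covariance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariance_csv <- function(C, path) {
  utils::write.csv(as.data.frame(C), path, row.names = TRUE)
  invisible(path)
}
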