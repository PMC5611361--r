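#' Parse and validate a newick phylogeny
#'
#' Reads a newick string or file via `ape` and enforces the requirements of
#' contrast-based analyses: rooted, strictly binary, unique tip labels, and
#' finite positive branch lengths on every edge. Polytomies are rejected with
#' a pointer to `ape::multi2di()` rather than silently resolved.
#'
#' @param text Newick string (starting with "(") or path to a newick file.
#' @return A validated `ape::phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  tr <- if (grepl("^\\s*\\(", text)) ape::read.tree(text = text)
        else ape::read.tree(file = text)
  if (is.null(tr)) stop("parse error: not a well-formed newick tree")
  validate_phylogeny(tr)
}

#' @rdname parse_newick
#' @param tree An `ape::phylo` object to validate in place.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("parse error: expected a 'phylo' tree")
  if (anyDuplicated(tree$tip.label))
    stop("parse error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree))
    stop("parse error: tree must be rooted")
  if (!ape::is.binary(tree))
    stop("parse error: tree contains polytomies; resolve them first ",
         "(e.g. ape::multi2di) before computing contrasts")
  if (is.null(tree$edge.length))
    stop("parse error: tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0))
    stop("parse error: all branch lengths must be finite and positive")
  tree
}

#' Write a phylogeny as newick
#'
#' @param tree `ape::phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when writing to file.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Phylogenetically independent contrasts for one trait
#'
#' Felsenstein's pruning algorithm: in post-order, the contrast at an internal
#' node with daughter values `x_L`, `x_R` on (possibly extended) branches
#' `v_L`, `v_R` is `(x_L - x_R) / sqrt(v_L + v_R)`; the node is then assigned
#' the 1/v-weighted average of its daughters and its parent-side branch is
#' extended by `v_L v_R / (v_L + v_R)`. Under Brownian motion the `n - 1`
#' contrasts are independent standard-normal up to the common rate.
#'
#' Traits are expected on the scale of analysis (here: log10 species means).
#'
#' @param tree Validated phylogeny ([parse_newick()]).
#' @param trait Named numeric vector of tip values; names must cover every
#'   tip label.
#' @param trait_name Optional label stored with the result.
#' @return Object of class `contrast_set`: data frame with `node` (internal
#'   node id) and `contrast`, plus attributes `trait` and `node_order`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 2, B = 4, C = 9))
#' @export
pic_contrasts <- function(tree, trait, trait_name = deparse(substitute(trait))) {
  validate_phylogeny(tree)
  tips <- tree$tip.label
  if (is.null(names(trait)))
    stop("invalid-argument: trait vector must be named by tip label")
  missing_tips <- setdiff(tips, names(trait))
  if (length(missing_tips))
    stop("invalid-argument: no trait value for tip(s): ",
         paste(missing_tips, collapse = ", "))
  if (any(!is.finite(trait[tips])))
    stop("invalid-argument: non-finite trait value for tip(s): ",
         paste(tips[!is.finite(trait[tips])], collapse = ", "))

  ntip <- length(tips)
  nnode <- tree$Nnode
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length

  xval <- c(as.numeric(trait[tips]), rep(NA_real_, nnode))
  vadd <- numeric(ntip + nnode) # branch extension accumulated at each node
  contrasts <- numeric(nnode)
  cnode <- integer(nnode)
  ci <- 0L
  # postorder edges come in daughter pairs for a binary tree
  for (i in seq(1L, nrow(edge), by = 2L)) {
    parent <- edge[i, 1L]
    d1 <- edge[i, 2L]; d2 <- edge[i + 1L, 2L]
    v1 <- elen[i] + vadd[d1]
    v2 <- elen[i + 1L] + vadd[d2]
    ci <- ci + 1L
    cnode[ci] <- parent
    contrasts[ci] <- (xval[d1] - xval[d2]) / sqrt(v1 + v2)
    xval[parent] <- (xval[d1] / v1 + xval[d2] / v2) / (1 / v1 + 1 / v2)
    vadd[parent] <- v1 * v2 / (v1 + v2)
  }
  ord <- order(cnode)
  out <- data.frame(node = cnode[ord], contrast = contrasts[ord])
  structure(out, class = c("contrast_set", "data.frame"),
            trait = trait_name, node_order = cnode[ord],
            tree_id = ape::write.tree(tree))
}

#' Correlation between two sets of independent contrasts
#'
#' Contrasts have an arbitrary joint sign per node, so their correlation is
#' computed through the origin: `r = sum(u w) / sqrt(sum(u^2) sum(w^2))`. The
#' two-sided p-value uses `t = r sqrt((n - 1) / (1 - r^2))` with `n - 1` df,
#' `n` the number of contrasts (one df spent on forcing the line through the
#' origin).
#'
#' @param cs1,cs2 `contrast_set`s from the same tree (identical node order).
#' @return List with `r`, `p_value`, `df`.
#' @export
pic_correlation <- function(cs1, cs2) {
  stopifnot(inherits(cs1, "contrast_set"), inherits(cs2, "contrast_set"))
  if (!identical(attr(cs1, "node_order"), attr(cs2, "node_order")) ||
      !identical(attr(cs1, "tree_id"), attr(cs2, "tree_id")))
    stop("invalid-argument: contrast sets come from different trees or node orders")
  u <- cs1$contrast
  w <- cs2$contrast
  denom <- sqrt(sum(u^2) * sum(w^2))
  if (denom == 0) return(list(r = NA_real_, p_value = NA_real_,
                              df = length(u) - 1L))
  r <- sum(u * w) / denom
  n <- length(u)
  df <- n - 1L
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p_value = p, df = df)
}

#' Contrasts for every trait of a species table
#'
#' @param tree Validated phylogeny covering all species in `table`.
#' @param logm Matrix of log10 species means (rownames = species).
#' @return Named list of `contrast_set`s.
#' @export
pic_table <- function(tree, logm) {
  traits <- colnames(logm)
  setNames(lapply(traits, function(tr) {
    v <- setNames(logm[, tr], rownames(logm))
    pic_contrasts(tree, v, trait_name = tr)
  }), traits)
}
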