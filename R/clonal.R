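#' Allele-fraction matrix utilities
#'
#' An AF matrix has one row per variant and one column per lesion, with
#' entries in [0, 1].  `binarize()` converts it to a presence matrix at
#' the deep-sequencing detection cutoff.
#'
#' @param af_matrix numeric matrix, variants x lesions, values in [0, 1].
#' @param threshold presence threshold in (0, 1); default 0.01, the
#'   deep-seq detection cutoff.
#' @return logical matrix of the same shape.
#' @export
binarize <- function(af_matrix, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (any(af_matrix < 0 | af_matrix > 1)) stop("AFs must be in [0, 1]")
  af_matrix >= threshold
}

#' Truncal variant set
#'
#' Variants present in every lesion — attributed to the common ancestor
#' clone of all analyzed lesions.
#'
#' @param presence logical presence matrix (variants x lesions) from
#'   [binarize()].
#' @return character vector of truncal variant names.
#' @export
truncal_set <- function(presence) {
  if (ncol(presence) < 1) stop("need at least one lesion")
  rownames(presence)[rowSums(presence) == ncol(presence)]
}

#' Order lesions into a clone tree from an AF matrix
#'
#' Lesions with identical presence patterns are merged into one node
#' (e.g. three lymph-node deposits sharing every variant form a single
#' "LN" node).  Nodes are partially ordered by strict containment of
#' their variant sets; the returned tree is the Hasse diagram of that
#' order (a forest when no chain exists).  Each edge parent -> child is
#' annotated with the variants newly present in the child (`gained`) and
#' the shared variants whose mean child AF is at least `increase_ratio`
#' times the mean parent AF (`increased`, with fold-changes).
#'
#' @param af_matrix numeric matrix, variants x lesions (dimnames
#'   required).
#' @param threshold presence threshold (see [binarize()]).
#' @param increase_ratio fold-change needed to flag an AF increase along
#'   an edge (default 1.5).
#' @return object of class `clone_tree`: list with `nodes` (list:
#'   id, lesions, variants), `edges` (list: parent, child, gained,
#'   increased, fold) and `presence`.  Node ids are the sorted lesion
#'   labels joined with "+"; ties are ordered lexicographically.
#' @export
order_lesions <- function(af_matrix, threshold = 0.01, increase_ratio = 1.5) {
  if (is.null(rownames(af_matrix)) || is.null(colnames(af_matrix)))
    stop("af_matrix needs variant rownames and lesion colnames")
  pres <- binarize(af_matrix, threshold)
  pat <- apply(pres, 2, function(v) paste(as.integer(v), collapse = ""))
  groups <- split(colnames(af_matrix), pat)
  nodes <- lapply(groups, function(lesions) {
    lesions <- sort(lesions)
    list(id = paste(lesions, collapse = "+"), lesions = lesions,
         variants = rownames(pres)[pres[, lesions[1]]])
  })
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  nodes <- nodes[order(names(nodes))]
  ids <- names(nodes)
  vsets <- lapply(nodes, `[[`, "variants")

  strictly_contains <- function(a, b) # b strict superset of a
    all(a %in% b) && length(b) > length(a)
  edges <- list()
  for (child in ids) for (parent in ids) {
    if (parent == child) next
    if (!strictly_contains(vsets[[parent]], vsets[[child]])) next
    # covering relation: no intermediate node between parent and child
    inter <- any(vapply(ids, function(m) {
      m != parent && m != child &&
        strictly_contains(vsets[[parent]], vsets[[m]]) &&
        strictly_contains(vsets[[m]], vsets[[child]])
    }, logical(1)))
    if (inter) next
    shared <- intersect(vsets[[parent]], vsets[[child]])
    p_af <- rowMeans(af_matrix[shared, nodes[[parent]]$lesions, drop = FALSE])
    c_af <- rowMeans(af_matrix[shared, nodes[[child]]$lesions, drop = FALSE])
    fold <- ifelse(p_af > 0, c_af / p_af, Inf)
    inc <- shared[fold >= increase_ratio]
    edges[[length(edges) + 1]] <- list(
      parent = parent, child = child,
      gained = sort(setdiff(vsets[[child]], vsets[[parent]])),
      increased = sort(inc),
      fold = stats::setNames(fold, shared))
  }
  structure(list(nodes = nodes, edges = edges, presence = pres,
                 threshold = threshold, increase_ratio = increase_ratio),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d nodes, %d edges\n", length(x$nodes),
              length(x$edges)))
  for (e in x$edges) {
    ann <- c(if (length(e$gained)) paste0("+", e$gained),
             if (length(e$increased)) paste0("\u2191", e$increased))
    cat(sprintf("  %s -> %s%s\n", e$parent, e$child,
                if (length(ann)) paste0("  [", paste(ann, collapse = ", "), "]")
                else ""))
  }
  invisible(x)
}

#' Assign a sample to its clone-tree node
#'
#' Returns the deepest node whose full variant set the sample carries
#' (AF at or above the tree's presence threshold); a CTC pool carrying
#' every lesion variant is placed at the terminal node.  A sample lacking
#' any truncal variant is unassigned (`NA`).
#'
#' @param af_vector named numeric vector of sample AFs over the tree's
#'   variants.
#' @param tree a `clone_tree`.
#' @return node id (character) or `NA_character_` when unassigned.
#' @export
assign_sample <- function(af_vector, tree) {
  miss <- setdiff(rownames(tree$presence), names(af_vector))
  if (length(miss)) stop("sample vector lacks variants: ",
                         paste(miss, collapse = ", "))
  carried <- names(af_vector)[af_vector >= tree$threshold]
  ok <- Filter(function(nd) all(nd$variants %in% carried), tree$nodes)
  if (length(ok) == 0) return(NA_character_)
  depth <- vapply(ok, function(nd) length(nd$variants), numeric(1))
  ok[[order(-depth, vapply(ok, `[[`, "", "id"))[1]]]$id
}

#' Serialize a clone tree
#'
#' @param tree a `clone_tree`.
#' @return JSON string (nodes, edges with annotations) via
#'   `clone_tree_json()`; Graphviz DOT via `clone_tree_dot()`.
#' @export
clone_tree_json <- function(tree) {
  jsonlite::toJSON(list(
    nodes = lapply(unname(tree$nodes), function(nd)
      list(id = nd$id, lesions = nd$lesions, variants = nd$variants)),
    edges = lapply(tree$edges, function(e)
      list(parent = e$parent, child = e$child, gained = e$gained,
           increased = e$increased))
  ), auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname clone_tree_json
#' @export
clone_tree_dot <- function(tree) {
  lines <- c("digraph clone_tree {")
  for (nd in tree$nodes)
    lines <- c(lines, sprintf('  "%s";', nd$id))
  for (e in tree$edges) {
    ann <- c(if (length(e$gained)) paste0("+", e$gained),
             if (length(e$increased)) paste0("^", e$increased))
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                              e$parent, e$child, paste(ann, collapse = " ")))
  }
  paste(c(lines, "}"), collapse = "\n")
}
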