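#' Labeled phylogeny with a foreground/background branch partition
#'
#' Wraps an [ape::phylo] tree together with a per-branch partition label.
#' Branch-site and clade models allow selection parameters to differ on a
#' small set of a-priori "foreground" branches; all other branches are
#' background. Labels follow the PAML `#1` dialect in Newick input/output.
#'
#' @param phy An `ape::phylo` object (rooted representation; reversible-model
#'   likelihoods are invariant to the root placement).
#' @param foreground Logical vector over edges (rows of `phy$edge`), or a
#'   character vector of tip labels whose pendant branches are foreground.
#' @return An object of class `labeled_tree` with elements `phylo` and
#'   `foreground` (logical per edge row).
#' @export
labeled_tree <- function(phy, foreground = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  nedge <- nrow(phy$edge)
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0.1")
    phy$edge.length <- rep(0.1, nedge)
  }
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  if (is.null(foreground)) foreground <- rep(FALSE, nedge)
  if (is.character(foreground)) {
    miss <- setdiff(foreground, phy$tip.label)
    if (length(miss)) stop("unknown tip(s): ", paste(miss, collapse = ", "))
    tips <- match(foreground, phy$tip.label)
    foreground <- phy$edge[, 2] %in% tips
  }
  if (length(foreground) != nedge) stop("foreground must have one entry per edge")
  if (all(foreground)) stop("at least one branch must be background")
  structure(list(phylo = phy, foreground = as.logical(foreground)),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("Labeled tree: ", length(x$phylo$tip.label), " tips, ",
      sum(x$foreground), " foreground branch(es)\n", sep = "")
  invisible(x)
}

#' Parse a Newick string or file with PAML '#1' branch labels
#'
#' Branches tagged `#1` (after a tip name, a closing parenthesis, or a branch
#' length) are foreground; untagged branches are background. Bootstrap or
#' other support values on internal nodes are ignored with a warning.
#' Missing branch lengths default to 0.1 with a warning.
#'
#' @param text Newick string (used if `file` is NULL).
#' @param file Path to a Newick file.
#' @return A `labeled_tree`.
#' @examples
#' read_labeled_tree("((A:0.1 #1,B:0.2):0.05,C:0.3);")
#' @export
read_labeled_tree <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  txt <- trimws(text)
  op <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  cl <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (op != cl) {
    offs <- which(cumsum((strsplit(txt, "")[[1]] == "(") -
                           (strsplit(txt, "")[[1]] == ")")) < 0)
    stop("malformed Newick: unbalanced parentheses",
         if (length(offs)) paste0(" at character ", offs[1]) else "")
  }
  if (!grepl(";\\s*$", txt)) stop("malformed Newick: missing terminal ';'")
  # normalize '#k' placement: attach tag to the preceding label, moving tags
  # that follow a branch length (\"A:0.1#1\") in front of the colon
  txt <- gsub("\\s*#\\s*([0-9]+)", "#\\1", txt)
  txt <- gsub(":([0-9eE.+-]+)#([0-9]+)", "#\\2:\\1", txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL)
  if (is.null(phy)) stop("malformed Newick: ", substr(txt, 1, 40), "...")
  ntip <- length(phy$tip.label)
  fg_nodes <- integer(0)
  tag <- regmatches(phy$tip.label, regexpr("#[0-9]+$", phy$tip.label))
  has <- grepl("#[0-9]+$", phy$tip.label)
  if (any(has)) {
    lev <- as.integer(sub("#", "", tag))
    fg_nodes <- c(fg_nodes, which(has)[lev >= 1L])
    phy$tip.label <- sub("#[0-9]+$", "", phy$tip.label)
  }
  if (!is.null(phy$node.label)) {
    hasn <- grepl("#[0-9]+$", phy$node.label)
    if (any(hasn)) {
      lev <- as.integer(sub(".*#", "", phy$node.label[hasn]))
      fg_nodes <- c(fg_nodes, (ntip + which(hasn))[lev >= 1L])
      phy$node.label <- sub("#[0-9]+$", "", phy$node.label)
    }
    if (any(nzchar(phy$node.label))) {
      warning("internal node labels/support values ignored")
    }
    phy$node.label <- NULL
  }
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0.1")
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  }
  labeled_tree(phy, foreground = phy$edge[, 2] %in% fg_nodes)
}

#' Write a labeled tree to Newick with '#1' tags
#'
#' @param tree A `labeled_tree`.
#' @param file Optional output path; if NULL the Newick string is returned.
#' @export
write_labeled_tree <- function(tree, file = NULL) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  fg_child <- phy$edge[tree$foreground, 2]
  tips <- fg_child[fg_child <= ntip]
  phy$tip.label[tips] <- paste0(phy$tip.label[tips], "#1")
  nodes <- fg_child[fg_child > ntip]
  if (length(nodes)) {
    phy$node.label <- rep("", phy$Nnode)
    phy$node.label[nodes - ntip] <- "#1"
  }
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

# canonical key for the unrooted bipartition induced by each edge;
# stable across rerooting, used to carry foreground labels over
edge_keys_for <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  post <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ref <- min(phy$tip.label)
  all_tips <- phy$tip.label
  vapply(seq_len(nrow(phy$edge)), function(e) {
    tips <- below[[phy$edge[e, 2]]]
    if (ref %in% tips) tips <- setdiff(all_tips, tips)
    paste(sort(tips), collapse = "|")
  }, character(1))
}

#' Reroot a labeled tree at an internal node
#'
#' Produces a topology-equivalent rooted representation with the given node
#' as root. Branch lengths, total tree length, the multiset of leaf-to-leaf
#' path lengths, and foreground labels (carried over by unrooted
#' bipartition) are preserved. Reversible-model likelihoods are invariant
#' under this operation.
#'
#' @param tree A `labeled_tree`.
#' @param node Internal node number (ape numbering) to become the root, or a
#'   tip label / tip number whose parent becomes the root.
#' @return A `labeled_tree`.
#' @export
reroot_tree <- function(tree, node) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (is.character(node)) {
    node <- match(node, phy$tip.label)
    if (is.na(node)) stop("unknown tip label")
  }
  if (node > ntip + phy$Nnode || node < 1) stop("unknown node: ", node)
  if (node <= ntip) node <- phy$edge[phy$edge[, 2] == node, 1]
  root <- ntip + 1L
  if (node == root) return(tree)
  fg_keys <- edge_keys_for(tree)[tree$foreground]
  target_key <- {
    keys <- edge_keys_for(tree)
    e <- which(phy$edge[, 2] == node)
    keys[e]
  }
  un <- ape::unroot(phy)
  # find the node in the unrooted tree carrying the same bipartition
  un_tree <- labeled_tree(un, foreground = rep(FALSE, nrow(un$edge)))
  un_keys <- edge_keys_for(un_tree)
  e_new <- which(un_keys == target_key)
  cand <- un$edge[e_new, 2]
  cand <- cand[cand > length(un$tip.label)]
  if (!length(cand)) { # node became the basal node of the unrooted store
    new_phy <- un
  } else {
    new_phy <- ape::root(un, node = cand[1], resolve.root = FALSE)
  }
  new_keys <- edge_keys_for(labeled_tree(new_phy,
                                         foreground = rep(FALSE, nrow(new_phy$edge))))
  labeled_tree(new_phy, foreground = new_keys %in% fg_keys)
}
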