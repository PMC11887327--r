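#' Parse and validate a rooted binary phylogenetic tree
#'
#' Reads a Newick string (or file) into an [ape::phylo] object and validates
#' the structural assumptions of the tree-based test: the tree must be rooted,
#' every internal node must have exactly two children, and leaf labels must be
#' unique. Branch lengths, if present, are ignored by all downstream code; only
#' the topology and the left/right order of children (as listed in the Newick
#' string) matter.
#'
#' @param text Newick string (e.g. `"((A,B),C);"`). Exactly one of `text` or
#'   `file` must be given.
#' @param file Path to a Newick file.
#' @param resolve How to handle multifurcating (non-binary) nodes: `"error"`
#'   (default, strict rejection) or `"multi2di"`, which resolves them
#'   deterministically in input order via [ape::multi2di] with
#'   `random = FALSE`.
#' @return A validated `phylo` object in cladewise order.
#' @examples
#' tr <- parse_tree("((A,B),C);")
#' ape::Ntip(tr)
#' @export
parse_tree <- function(text = NULL, file = NULL,
                       resolve = c("error", "multi2di")) {
  resolve <- match.arg(resolve)
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  }
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
    ),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick: could not parse a tree", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  # an unrooted tree is a multifurcation at the root for our purposes
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    if (resolve == "error") {
      stop("non-binary node: tree contains multifurcations or an unrooted ",
           "root (use resolve = \"multi2di\" to resolve deterministically)",
           call. = FALSE)
    }
    tr <- ape::multi2di(tr, random = FALSE)
  }
  if (!ape::is.rooted(tr) || !ape::is.binary(tr)) {
    stop("tree must be rooted and binary", call. = FALSE)
  }
  ape::reorder.phylo(tr, "cladewise")
}

# Children of an internal node in Newick (cladewise) order: the first row of
# the edge matrix gives the first-listed ("left") child.
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

# Tip labels descending from a node (the node itself if it is a tip).
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    if (nd <= ntip) out <- c(out, tree$tip.label[nd]) else {
      stack <- c(node_children(tree, nd), stack)
    }
  }
  out
}

#' Enumerate the test nodes of a genus
#'
#' For a genus with `M1` leaves on a rooted binary tree there are `M1 - 1`
#' internal nodes in its subtree. Each internal node `k` defines a test node
#' whose left and right leaf sets `L_k` and `R_k` are the leaves under its
#' first- and second-listed child. Nodes are numbered `k = 1, 2, ...` by
#' pre-order traversal starting from the subtree root, so `k = 1` is always
#' the genus root split. The pooled statistic (node 0, the whole genus against
#' its reference) is not enumerated here; it always exists, so the number of
#' per-genus statistics is `M1` even for a single-taxon genus.
#'
#' @param tree A validated `phylo` tree (see [parse_tree()]).
#' @param genus_taxa Character vector of leaf labels belonging to the genus.
#' @param genus Optional genus name carried into the result.
#' @param monophyly `"strict"` errors when the smallest clade containing the
#'   genus leaves also contains foreign leaves; `"lenient"` prunes the foreign
#'   leaves from the spanning clade (with a message) and enumerates nodes on
#'   the pruned subtree.
#' @return A `genus_partition` list with elements `genus`, `member_taxa`
#'   (ordered as in the subtree), `other_taxa`, `test_nodes` (tibble with
#'   columns `k`, `left`, `right`; list-columns of leaf labels), `M1`, and
#'   `excluded` (foreign leaves pruned in lenient mode).
#' @examples
#' tr <- parse_tree("((A,B),C);")
#' gp <- enumerate_test_nodes(tr, c("A", "B", "C"))
#' gp$test_nodes
#' @export
enumerate_test_nodes <- function(tree, genus_taxa, genus = NULL,
                                 monophyly = c("strict", "lenient")) {
  monophyly <- match.arg(monophyly)
  genus_taxa <- as.character(genus_taxa)
  if (length(genus_taxa) == 0L) stop("empty genus", call. = FALSE)
  missing <- setdiff(genus_taxa, tree$tip.label)
  if (length(missing)) {
    stop("genus taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  other <- setdiff(tree$tip.label, genus_taxa)
  excluded <- character(0)

  if (length(genus_taxa) == 1L) {
    return(structure(
      list(genus = genus %||% NA_character_, member_taxa = genus_taxa,
           other_taxa = other,
           test_nodes = tibble::tibble(k = integer(0), left = list(),
                                       right = list()),
           M1 = 1L, excluded = excluded),
      class = "genus_partition"))
  }

  mrca <- ape::getMRCA(tree, genus_taxa)
  clade_tips <- node_tips(tree, mrca)
  foreign <- setdiff(clade_tips, genus_taxa)
  sub <- ape::extract.clade(tree, mrca)
  if (length(foreign)) {
    if (monophyly == "strict") {
      stop("genus is not monophyletic on the tree; foreign leaves in its ",
           "clade: ", paste(foreign, collapse = ", "), call. = FALSE)
    }
    message("pruning ", length(foreign),
            " foreign leaves from the genus clade: ",
            paste(foreign, collapse = ", "))
    sub <- ape::drop.tip(sub, foreign)
    excluded <- foreign
  }
  sub <- ape::reorder.phylo(sub, "cladewise")

  ntip <- length(sub$tip.label)
  root <- ntip + 1L
  ks <- integer(0)
  lefts <- list()
  rights <- list()
  stack <- root
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    if (nd <= ntip) next
    ch <- node_children(sub, nd)
    ks <- c(ks, length(ks) + 1L)
    lefts[[length(ks)]] <- node_tips(sub, ch[[1L]])
    rights[[length(ks)]] <- node_tips(sub, ch[[2L]])
    stack <- c(ch, stack) # pre-order: node, then its children left-first
  }
  member <- node_tips(sub, root)

  structure(
    list(genus = genus %||% NA_character_, member_taxa = member,
         other_taxa = other,
         test_nodes = tibble::tibble(k = ks, left = lefts, right = rights),
         M1 = length(member), excluded = excluded),
    class = "genus_partition")
}

#' @export
print.genus_partition <- function(x, ...) {
  cat("<genus_partition> ", x$genus, ": M1 = ", x$M1, ", ",
      nrow(x$test_nodes), " test nodes, ", length(x$other_taxa),
      " taxa outside the genus\n", sep = "")
  invisible(x)
}

# Prune a tree to the retained taxa (after filtering) so that genus clades
# are evaluated on the working leaf set.
prune_tree_to <- function(tree, taxa) {
  drop <- setdiff(tree$tip.label, taxa)
  if (!length(drop)) return(tree)
  if (length(drop) >= length(tree$tip.label) - 1L) {
    stop("fewer than two taxa left on the tree after filtering",
         call. = FALSE)
  }
  ape::reorder.phylo(ape::drop.tip(tree, drop), "cladewise")
}

#' Partition all taxa into genera
#'
#' Builds one [enumerate_test_nodes()] partition per genus present in the
#' taxonomy map, restricted to taxa present in the tree.
#'
#' @param tree A validated `phylo` tree.
#' @param taxonomy Data frame with columns `taxon_id` and `genus`.
#' @inheritParams enumerate_test_nodes
#' @return Named list of `genus_partition` objects.
#' @export
genus_partitions <- function(tree, taxonomy,
                             monophyly = c("strict", "lenient")) {
  monophyly <- match.arg(monophyly)
  stopifnot(all(c("taxon_id", "genus") %in% names(taxonomy)))
  taxonomy <- taxonomy[taxonomy$taxon_id %in% tree$tip.label, , drop = FALSE]
  sets <- split(as.character(taxonomy$taxon_id), taxonomy$genus)
  purrr::imap(sets, function(tx, g) {
    enumerate_test_nodes(tree, tx, genus = g, monophyly = monophyly)
  })
}
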