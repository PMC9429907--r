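# Phylogenetic calling of sporulation-like sigma factors.
#
# A phage protein is called sporulation-like when its tip falls inside the
# clade spanned by the bacterial sporulation-specific reference sigma factors,
# excluding the subclade spanned by sigB and its relatives (general stress
# sigma factors that sit inside the larger clade but are not sporulation
# associated).

#' Read a newick tree with tip annotations
#'
#' @param newick Path to a newick file, or a newick string.
#' @param metadata Data frame with columns `tip`, `source` (`"phage"` or
#'   `"bacterial"`) and optionally `family` for bacterial reference tips.
#' @param root Rooting directive for unrooted inputs: a character vector of
#'   outgroup tip labels, the string `"midpoint"`, or `NULL` (error if the
#'   input is unrooted).
#' @return An `annotated_tree`: list with `tree` (an [ape::read.tree()]
#'   phylo) and `meta` (the metadata, row-matched to tip labels).
#' @export
read_annotated_newick <- function(newick, metadata, root = NULL) {
  tree <- if (file.exists(newick)) ape::read.tree(newick)
          else ape::read.tree(text = newick)
  if (is.null(tree)) stop("read_annotated_newick: newick did not parse")
  if (!all(c("tip", "source") %in% names(metadata)))
    stop("read_annotated_newick: metadata needs columns tip, source")
  missing <- setdiff(tree$tip.label, metadata$tip)
  if (length(missing))
    stop("read_annotated_newick: tip(s) missing metadata: ",
         paste(missing, collapse = ", "))
  bad <- setdiff(metadata$source, c("phage", "bacterial"))
  if (length(bad))
    stop("read_annotated_newick: source must be phage|bacterial, got: ",
         paste(bad, collapse = ", "))
  if (!ape::is.rooted(tree)) {
    if (is.null(root))
      stop("read_annotated_newick: tree is unrooted; supply an outgroup or 'midpoint'")
    if (identical(root, "midpoint")) {
      tree <- phangorn::midpoint(tree)
    } else {
      tree <- ape::root(tree, outgroup = root, resolve.root = TRUE)
    }
  }
  meta <- metadata[match(tree$tip.label, metadata$tip), , drop = FALSE]
  rownames(meta) <- NULL
  out <- list(tree = tree, meta = meta)
  class(out) <- "annotated_tree"
  out
}

# tip labels descending from a node (node may itself be a tip)
.tips_of_node <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  idx <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  tree$tip.label[idx]
}

# MRCA defined for 1+ tips (single tip is its own ancestor set)
.mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("reference tip(s) absent from tree: ",
         paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

#' Members of the sporulation clade, excluding the sigB subclade
#'
#' The sporulation clade is the tip set of the most recent common ancestor of
#' the sporulation reference tips; the excluded subclade is the tip set of
#' the MRCA of the sigB reference tips. Phage tips inside the clade but
#' outside the exclusion are called sporulation-like.
#'
#' @param atree An [read_annotated_newick()] object.
#' @param spore_reference_tips Bacterial tips delimiting the sporulation clade.
#' @param sigb_reference_tips Bacterial tips delimiting the sigB subclade.
#' @return A `clade_call` list: `clade_tips`, `excluded_subclade_tips`,
#'   `member_phage_tips`.
#' @export
sporulation_clade_members <- function(atree, spore_reference_tips,
                                      sigb_reference_tips) {
  stopifnot(inherits(atree, "annotated_tree"))
  if (length(spore_reference_tips) == 0 || length(sigb_reference_tips) == 0)
    stop("sporulation_clade_members: reference tip sets must be non-empty")
  tree <- atree$tree
  clade <- .tips_of_node(tree, .mrca_node(tree, spore_reference_tips))
  excl <- .tips_of_node(tree, .mrca_node(tree, sigb_reference_tips))
  if (!all(excl %in% clade))
    warning("sigB subclade is not nested within the sporulation clade; ",
            "applying exclusion set-wise")
  phage_tips <- atree$meta$tip[atree$meta$source == "phage"]
  members <- setdiff(intersect(clade, phage_tips), excl)
  out <- list(clade_tips = clade, excluded_subclade_tips = excl,
              member_phage_tips = members)
  class(out) <- "clade_call"
  out
}

#' Maximal phage-only clades
#'
#' Finds the maximal monophyletic clades whose tips are all phage-encoded.
#' Each returned clade's parent clade contains at least one bacterial tip;
#' singleton clades are allowed; together the clades cover every phage tip
#' exactly once.
#'
#' @param atree An [read_annotated_newick()] object (rooted).
#' @return List of character vectors of tip labels (possibly empty).
#' @export
phage_only_clades <- function(atree) {
  stopifnot(inherits(atree, "annotated_tree"))
  tree <- atree$tree
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  is_phage_tip <- atree$meta$source[match(tree$tip.label, atree$meta$tip)] == "phage"
  if (!any(is_phage_tip)) return(list())
  all_phage <- logical(nnode)
  all_phage[seq_len(ntip)] <- is_phage_tip
  desc <- phangorn::Descendants(tree, (ntip + 1):nnode, type = "tips")
  all_phage[(ntip + 1):nnode] <- vapply(desc, function(i) all(is_phage_tip[i]), TRUE)
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  maximal <- which(all_phage &
                     (seq_len(nnode) == root | !all_phage[pmax(parent, 1L)]))
  lapply(maximal, function(nd) .tips_of_node(tree, nd))
}
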