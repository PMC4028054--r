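#' The fixed five-taxon rosid tree
#'
#' Topology `(Pt,(Cp,(Th,(At,Br))))`: poplar (Pt) as the fabid outgroup,
#' papaya (Cp) sister to the core Brassicales, and the focal taxon Th
#' (Cleomaceae) sister to the Brassicaceae pair At + Br. Internal nodes
#' are labelled `root`, `malvids`, `coreBrassicales`, `Brassicaceae`.
#'
#' @param newick Optional newick string for reuse with other clades; it
#'   must contain the focal taxon as a leaf.
#' @param focal Focal taxon leaf name (default `"Th"`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
taxon_tree <- function(newick = NULL, focal = "Th") {
  if (is.null(newick)) {
    newick <- "(Pt,(Cp,(Th,(At,Br)Brassicaceae)coreBrassicales)malvids)root;"
  }
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse newick tree")
  if (!(focal %in% tree$tip.label)) {
    stop("focal taxon ", focal, " is not a leaf of the tree")
  }
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    lab <- tree$node.label %||% rep("", tree$Nnode)
    lab[!nzchar(lab)] <- paste0("node", which(!nzchar(lab)))
    tree$node.label <- lab
  }
  tree
}

#' @keywords internal
node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else tree$node.label[node - ntip]
}

#' @keywords internal
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

#' @keywords internal
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= ntip) out <- c(out, tree$tip.label[v])
    else stack <- c(stack, node_children(tree, v))
  }
  out
}

#' Build per-contig taxon presence vectors from hit tables
#'
#' A contig is scored present in a comparator taxon iff it has at least
#' one hit to that taxon with e-value at or below the cutoff (default
#' 1e-10). Contigs without any qualifying hit anywhere receive an
#' all-FALSE vector — the candidate lineage-specific set.
#'
#' @param hit_tables Named list of forward hit `data.frame`s (contigs as
#'   queries), one per comparator taxon, e.g.
#'   `list(At = ..., Br = ..., Cp = ..., Pt = ...)`.
#' @param evalue_cutoff Positive e-value cutoff.
#' @param contig_ids Contig universe; defaults to all query identifiers
#'   seen in any table (contigs absent from every table can only be
#'   included by passing the universe explicitly).
#' @return A `data.frame` with `contig_id` and one logical column per
#'   taxon.
#' @export
presence_vectors <- function(hit_tables, evalue_cutoff = 1e-10,
                             contig_ids = NULL) {
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be > 0")
  if (is.null(names(hit_tables)) || any(!nzchar(names(hit_tables)))) {
    stop("hit_tables must be a named list (one element per taxon)")
  }
  if (is.null(contig_ids)) {
    contig_ids <- sort(unique(unlist(lapply(hit_tables,
                                            function(h) h$query_id))))
  }
  out <- data.frame(contig_id = contig_ids, stringsAsFactors = FALSE)
  for (tax in names(hit_tables)) {
    h <- hit_tables[[tax]]
    hitset <- unique(h$query_id[h$evalue <= evalue_cutoff])
    out[[tax]] <- contig_ids %in% hitset
  }
  out
}

#' @keywords internal
letter_map_default <- function() {
  c("1100" = "B", "0100" = "C", "1110" = "E", "0010" = "G",
    "1111" = "I", "0011" = "K", "0001" = "O", "0000" = "Z")
}

#' Decompose contigs into the 16 presence/absence subsets
#'
#' Groups contigs by their four-taxon presence bitmask (order At, Br,
#' Cp, Pt; the focal taxon is implicitly present everywhere), producing
#' the 15 overlap sets plus the residual focal-taxon-specific set. The
#' eight subsets with conventional single-letter names are labelled
#' (`B` core-Brassicales-shared, `C` Br-shared, `E` Brassicales-shared,
#' `G` Cp-shared, `I` shared by all, `K` lost in Brassicaceae, `O`
#' Pt-shared, `Z` focal-specific); the remaining masks are labelled by
#' their bitmask.
#'
#' @param vectors Presence `data.frame` from [presence_vectors()] with
#'   columns `At`, `Br`, `Cp`, `Pt`.
#' @return A `subset_partition`: list with `assignment` (`data.frame`:
#'   `contig_id`, `bitmask`, `label`) and `sizes` (named count vector
#'   over all 16 bitmasks, zeros included).
#' @export
decompose_sets <- function(vectors) {
  need <- c("At", "Br", "Cp", "Pt")
  if (!all(need %in% names(vectors))) {
    stop("vectors must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(vectors$contig_id)) {
    stop("duplicate contig_id in presence vectors")
  }
  mask <- apply(vectors[, need], 1L, function(x) {
    paste(as.integer(x), collapse = "")
  })
  if (nrow(vectors) == 0L) mask <- character(0)
  lm <- letter_map_default()
  label <- ifelse(mask %in% names(lm), lm[mask], mask)
  all_masks <- apply(expand.grid(rep(list(0:1), 4L))[, 4:1], 1L, paste,
                     collapse = "")
  all_masks <- sort(all_masks)
  sizes <- stats::setNames(integer(length(all_masks)), all_masks)
  tab <- table(mask)
  sizes[names(tab)] <- as.integer(tab)
  structure(
    list(
      assignment = data.frame(contig_id = vectors$contig_id,
                              bitmask = unname(mask), label = unname(label),
                              stringsAsFactors = FALSE),
      sizes = sizes,
      letter_map = lm
    ),
    class = "subset_partition"
  )
}

#' @export
print.subset_partition <- function(x, ...) {
  cat("Presence/absence partition of", nrow(x$assignment), "contigs\n")
  lab <- ifelse(names(x$sizes) %in% names(x$letter_map),
                x$letter_map[names(x$sizes)], names(x$sizes))
  print(stats::setNames(as.integer(x$sizes), lab))
  invisible(x)
}

#' Dollo interpretation of one presence vector
#'
#' Under Dollo parsimony a gene family is gained exactly once and may
#' only be lost thereafter. The birth branch is the edge above the most
#' recent common ancestor of all present leaves (the focal taxon is
#' always present); the losses are the edges leading to the maximal
#' all-absent clades below that ancestor. This loss set is minimal and
#' unique.
#'
#' @param flags Named logical vector of comparator-taxon presence (e.g.
#'   `c(At = TRUE, Br = FALSE, Cp = FALSE, Pt = FALSE)`).
#' @param tree Tree from [taxon_tree()].
#' @param focal Focal taxon leaf name.
#' @return A list with `birth_branch` (edge named after its child node)
#'   and `loss_branches` (character vector, possibly empty).
#' @export
dollo_events <- function(flags, tree = taxon_tree(), focal = "Th") {
  present <- c(focal, names(flags)[as.logical(flags)])
  absentees <- setdiff(tree$tip.label, present)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (length(present) == 1L) {
    mrca <- match(focal, tree$tip.label)
  } else {
    mrca <- ape::getMRCA(tree, present)
  }
  losses <- character(0)
  if (mrca > ntip) {
    rec <- function(node) {
      tips <- tips_below(tree, node)
      if (all(tips %in% absentees)) {
        losses <<- c(losses, node_name(tree, node))
      } else if (node > ntip) {
        for (ch in node_children(tree, node)) rec(ch)
      }
    }
    for (ch in node_children(tree, mrca)) rec(ch)
  }
  list(birth_branch = node_name(tree, mrca), loss_branches = losses)
}

#' Aggregate gene births and losses per branch
#'
#' Applies [dollo_events()] to every contig of a partition and totals
#' the gains and losses on each edge of the tree.
#'
#' @param partition A `subset_partition` from [decompose_sets()].
#' @param tree Tree from [taxon_tree()].
#' @param focal Focal taxon leaf name.
#' @return A `data.frame` with columns `branch`, `gains`, `losses`,
#'   covering every edge (edges named after their child node; the root
#'   stem carries the root's label).
#' @export
summarize_births_losses <- function(partition, tree = taxon_tree(),
                                    focal = "Th") {
  ntip <- length(tree$tip.label)
  branches <- c(node_name(tree, ntip + 1L),
                vapply(tree$edge[, 2L], function(v) node_name(tree, v),
                       character(1L)))
  branches <- unique(branches)
  gains <- stats::setNames(integer(length(branches)), branches)
  losses <- gains
  # one Dollo call per distinct bitmask, weighted by subset size
  sizes <- partition$sizes[partition$sizes > 0]
  for (mask in names(sizes)) {
    flags <- stats::setNames(strsplit(mask, "")[[1L]] == "1",
                             c("At", "Br", "Cp", "Pt"))
    ev <- dollo_events(flags, tree, focal)
    gains[ev$birth_branch] <- gains[ev$birth_branch] + sizes[[mask]]
    for (b in ev$loss_branches) losses[b] <- losses[b] + sizes[[mask]]
  }
  data.frame(branch = branches, gains = as.integer(gains),
             losses = as.integer(losses), stringsAsFactors = FALSE,
             row.names = NULL)
}
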