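#' Read a Newick tree
#'
#' Parses a single Newick string into an [ape::read.tree()] `"phylo"` object
#' and validates it for use in rate-covariation analyses: leaf labels must be
#' unique, branch lengths non-negative and finite.  Missing branch lengths
#' default to 0.  NHX-style square-bracket comments are stripped with a
#' warning (their annotations are not used).
#'
#' @param text a single Newick string (terminal `;` optional).
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:2):0.5,C:3);")
#' write_newick(tr)
#' @seealso [write_newick()], [prune()], [branch_ids()]
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop_domain("`text` must be a single Newick string")
  if (grepl("\\[", text)) {
    warning("square-bracket comments stripped from Newick input")
    text <- gsub("\\[[^][]*\\]", "", text)
  }
  text <- trimws(text)
  if (!nzchar(text)) stop_domain("empty Newick string")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")

  # single-leaf degenerate case: "(A:1);" or "A:1;" — ape cannot represent it
  if (!grepl(",", text)) {
    lab <- sub("^\\(?\\s*([^():;,]+?)\\s*(:[0-9eE.+-]+)?\\)?;$", "\\1", text)
    len <- if (grepl(":", text))
      as.numeric(sub("^.*:([0-9eE.+-]+)\\)?;$", "\\1", text)) else 0
    if (!nzchar(lab) || is.na(len) || len < 0)
      stop_domain("malformed Newick string: ", text)
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = lab, edge.length = len, Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }

  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr) || is.null(tr$tip.label))
    stop_domain("malformed Newick string: ", text)
  if (anyDuplicated(tr$tip.label)) {
    dup <- tr$tip.label[duplicated(tr$tip.label)][1L]
    stop_domain("duplicate leaf label: ", dup)
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length)))
    stop_domain("non-finite branch length in Newick input")
  if (any(tr$edge.length < 0))
    stop_domain("negative branch length in Newick input")
  tr
}

#' Write a tree as Newick
#'
#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string (with terminal `;`).
#' @export
write_newick <- function(tree, digits = 10) {
  check_phylo(tree)
  if (length(tree$tip.label) == 1L)
    return(sprintf("(%s:%s);", tree$tip.label,
                   format(tree$edge.length[1L], digits = digits)))
  ape::write.tree(tree, digits = digits)
}

# Validate the phylo invariants this package relies on.
check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop_domain("not a \"phylo\" object")
  if (length(tree$tip.label) < 1L) stop_domain("tree has no leaves")
  if (anyDuplicated(tree$tip.label))
    stop_domain("duplicate leaf label: ",
                tree$tip.label[duplicated(tree$tip.label)][1L])
  if (!is.null(tree$edge.length) &&
      (anyNA(tree$edge.length) || any(tree$edge.length < 0) ||
       any(!is.finite(tree$edge.length))))
    stop_domain("branch lengths must be finite and >= 0")
  invisible(tree)
}

#' Prune a tree to a species subset
#'
#' Restricts `tree` to the leaves in `keep`, suppressing unary internal nodes
#' and summing their branch lengths onto the merged branch, so that
#' leaf-to-leaf path lengths within `keep` are preserved.
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of leaf labels to retain (at least 2).
#' @return the pruned `"phylo"` object.
#' @examples
#' prune(read_newick("((A:1,B:2):0.5,C:3);"), c("A", "C"))
#' @export
prune <- function(tree, keep) {
  check_phylo(tree)
  keep <- unique(as.character(keep))
  if (!all(keep %in% tree$tip.label))
    stop_domain("species not in tree: ",
                paste(setdiff(keep, tree$tip.label), collapse = ", "))
  if (length(keep) < 2L) stop_domain("need at least 2 species to prune to")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# -------------------------------------------------------------------------
# Bipartition machinery.
#
# A branch of an (effectively unrooted) tree is identified by the set of
# leaves on the side NOT containing the anchor species; the canonical string
# ID is those species sorted and comma-joined.  The two edges incident to a
# degree-2 root describe the same unrooted branch and are merged (lengths
# summed).

# For each edge of `tree` (rows of tree$edge), the set of tips on its child
# side, as a logical matrix n_edge x n_tip with tips in tree$tip.label order.
edge_tip_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  M <- matrix(FALSE, ne, nt)
  post <- ape::reorder.phylo(tree, "postorder")
  # accumulate child-side tip sets bottom-up over the postorder edge list
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  ord <- match(paste(post$edge[, 1], post$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(ne)) {
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    M[ord[k], below[[ch]]] <- TRUE
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  colnames(M) <- tree$tip.label
  M
}

branch_id_string <- function(species) paste(sort(species), collapse = ",")

# Canonical per-unrooted-branch table for a tree: data.frame with columns
# `id` (anchor-free BranchID string) and `length` (root-incident edges
# merged by summing).  `anchor` defaults to the lexicographically smallest
# leaf of the tree.
branch_table_core <- function(tree, anchor = NULL) {
  tips <- tree$tip.label
  if (is.null(anchor)) anchor <- min(tips)
  if (!anchor %in% tips) stop_domain("anchor species not in tree: ", anchor)
  if (length(tips) == 1L)
    stop_domain("cannot identify branches of a single-leaf tree")
  M <- edge_tip_matrix(tree)
  ai <- match(anchor, tips)
  lens <- tree$edge.length %||% rep(0, nrow(M))
  ids <- character(nrow(M))
  for (e in seq_len(nrow(M))) {
    side <- M[e, ]
    if (side[ai]) side <- !side
    ids[e] <- branch_id_string(tips[side])
  }
  agg <- tapply(lens, ids, sum)
  data.frame(id = names(agg), length = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Canonical branch identifiers of a tree
#'
#' Each branch of the unrooted topology is identified by the leaf set on the
#' side not containing the `anchor` species, serialized as the sorted,
#' comma-joined species names.  The two edges incident to a degree-2 root
#' collapse to a single unrooted branch.
#'
#' @param tree a `"phylo"` object with at least 2 leaves.
#' @param anchor anchor species; defaults to the lexicographically smallest
#'   leaf label.
#' @return character vector of BranchID strings, one per unrooted branch.
#' @examples
#' branch_ids(read_newick("((A,B),C);"))  # "B", "C", "B,C"
#' @export
branch_ids <- function(tree, anchor = NULL) {
  check_phylo(tree)
  branch_table_core(tree, anchor)$id
}

#' Branch-length table of one orthogroup
#'
#' Packages an orthogroup gene tree as its canonical branch-length table:
#' lengths keyed by anchor-free bipartition IDs on the tree's own topology.
#'
#' @param tree a `"phylo"` gene tree (topology = species tree pruned to the
#'   orthogroup's species).
#' @param orthogroup_id identifier string for the orthogroup.
#' @param anchor anchor species for branch IDs (default: smallest leaf label).
#' @return an object of class `"branch_table"`: a list with elements
#'   `orthogroup_id`, `species` (sorted character vector) and `lengths`
#'   (named numeric vector, names = BranchIDs).
#' @export
branch_table <- function(tree, orthogroup_id, anchor = NULL) {
  check_phylo(tree)
  if (length(tree$tip.label) < 2L)
    stop_domain("orthogroup tree needs at least 2 species")
  tab <- branch_table_core(tree, anchor)
  lens <- tab$length
  names(lens) <- tab$id
  structure(list(orthogroup_id = as.character(orthogroup_id),
                 species = sort(tree$tip.label),
                 lengths = lens),
            class = "branch_table")
}

#' @export
print.branch_table <- function(x, ...) {
  cat("Orthogroup branch-length table: ", x$orthogroup_id, "\n",
      "  species:  ", length(x$species), "\n",
      "  branches: ", length(x$lengths),
      " (total length ", format(sum(x$lengths), digits = 4), ")\n", sep = "")
  invisible(x)
}

# Precomputed bipartition context for a master tree: tip-membership matrix
# over unrooted branches (degree-2 root edges merged), columns in sorted
# species order and each row canonicalized to exclude the anchor (first
# sorted species).  Restrictions to species subsets are then cheap row
# operations, and can additionally be memoized in an environment.
master_context <- function(master) {
  tips <- master$tip.label
  ord <- order(tips)
  stips <- tips[ord]
  M <- edge_tip_matrix(master)[, ord, drop = FALSE]
  lens <- master$edge.length %||% rep(0, nrow(M))
  flip <- M[, 1L]
  M[flip, ] <- !M[flip, , drop = FALSE]
  mid <- apply(M, 1L, function(s) paste(stips[s], collapse = ","))
  first <- !duplicated(mid)
  merged <- as.numeric(tapply(lens, mid, sum)[mid[first]])
  list(M = M[first, , drop = FALSE], mid = mid[first], length = merged,
       tips = stips)
}

restrict_ctx <- function(ctx, keep, cache = NULL) {
  keep <- sort(as.character(keep))
  key <- paste(keep, collapse = ";")
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ki <- match(keep, ctx$tips)
  if (anyNA(ki))
    stop_domain("species not in master tree: ",
                paste(keep[is.na(ki)], collapse = ", "))
  Msub <- ctx$M[, ki, drop = FALSE]
  flip <- Msub[, 1L]
  Msub[flip, ] <- !Msub[flip, , drop = FALSE]
  n1 <- rowSums(Msub)
  sid <- rep(NA_character_, nrow(Msub))
  nz <- n1 > 0L & n1 < length(ki)
  if (any(nz))
    sid[nz] <- apply(Msub[nz, , drop = FALSE], 1L,
                     function(s) paste(keep[s], collapse = ","))
  out <- data.frame(master_id = ctx$mid, sub_id = sid, length = ctx$length,
                    stringsAsFactors = FALSE)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# Restriction map of master branches onto a species subset.  Returns a
# data.frame with one row per unrooted master branch: `master_id` (canonical
# on the full master leaf set), `sub_id` (canonical restriction to `keep`,
# NA for branches off every within-`keep` path), `length`.
master_restriction <- function(master, keep, ctx = NULL, cache = NULL) {
  if (is.null(ctx)) ctx <- master_context(master)
  restrict_ctx(ctx, keep, cache)
}

#' Map a pruned-tree branch onto its master-tree edge path
#'
#' When a tree is pruned to a species subset, each branch of the pruned tree
#' corresponds to a path of one or more master-tree branches (the edges
#' merged by suppressing unary nodes).  This returns that path as master
#' BranchIDs, so branch lengths can be compared across orthogroups with
#' different species content.
#'
#' @param branch a BranchID string on `prune(master, keep)` (anchored at the
#'   smallest species of `keep`).
#' @param master the master species tree (`"phylo"`).
#' @param keep the species subset.
#' @return character vector of master BranchIDs whose edges merge into
#'   `branch`.
#' @export
map_to_master <- function(branch, master, keep) {
  check_phylo(master)
  res <- master_restriction(master, keep)
  hit <- res$master_id[!is.na(res$sub_id) & res$sub_id == branch]
  if (length(hit) == 0L)
    stop_domain("branch not present in pruned topology: ", branch)
  hit
}

# Full pruned-branch -> master-branch-path map: named list keyed by sub_id.
master_path_map <- function(master, keep, ctx = NULL, cache = NULL) {
  res <- master_restriction(master, keep, ctx, cache)
  res <- res[!is.na(res$sub_id), , drop = FALSE]
  split(res$master_id, res$sub_id)
}

#' Read a file of gene trees
#'
#' One tree per line; the line may be either a bare Newick string or an
#' orthogroup ID, a tab, and the Newick string.
#'
#' @param path file path.
#' @return named list of `"phylo"` objects (names = orthogroup IDs; unnamed
#'   lines are numbered `og1`, `og2`, ...).
#' @export
read_tree_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) {
      ids[i] <- parts[1L]
      out[[i]] <- read_newick(parts[2L])
    } else {
      ids[i] <- paste0("og", i)
      out[[i]] <- read_newick(parts[1L])
    }
  }
  names(out) <- ids
  out
}

#' Export branch tables as TSV
#'
#' Writes columns `orthogroup_id`, `branch_id`, `length`, one row per branch.
#'
#' @param tables list of `"branch_table"` objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_branch_tables <- function(tables, path) {
  rows <- lapply(tables, function(tb)
    data.frame(orthogroup_id = tb$orthogroup_id,
               branch_id = names(tb$lengths),
               length = as.numeric(tb$lengths),
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
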