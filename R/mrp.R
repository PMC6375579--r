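# Matrix-representation-with-parsimony (MRP) supertree assembly:
# Baum-Ragan coding of input gene-tree bipartitions, Fitch small-parsimony
# scoring with missing data as wildcards, and exhaustive or NNI hill-climb
# search over unrooted binary species topologies.

# Unique non-trivial bipartitions of a tree, as logical tip-masks
# (anchor-free side), in tree$tip.label order.
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  if (nt < 4L) return(list())
  M <- edge_tip_matrix(tree)
  ai <- which(tree$tip.label == min(tree$tip.label))[1L]
  seen <- character(0)
  out <- list()
  for (e in seq_len(nrow(M))) {
    clade <- M[e, ]                       # child-side = clade side
    side <- if (clade[ai]) !clade else clade
    k <- sum(side)
    if (k < 2L || k > nt - 2L) next
    key <- paste(which(side), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- clade
  }
  out
}

#' Baum-Ragan matrix representation of a tree set
#'
#' Encodes every non-trivial bipartition of every input tree as a binary
#' character: species on the clade side score 1, the tree's other species 0,
#' and species absent from that tree are missing (`NA`).  Uninformative
#' columns (fewer than 2 ones or 2 zeros among scored species) never arise
#' from internal edges and are dropped by construction.
#'
#' @param trees list of `"phylo"` objects.
#' @param all_species character vector of all species (superset of every
#'   tree's leaves); defaults to the sorted union.
#' @return integer matrix (`0`/`1`/`NA`), rows = species, one column per
#'   encoded bipartition, with class `"mrp_matrix"` prepended.
#' @export
encode_mrp <- function(trees, all_species = NULL) {
  if (length(trees) < 1L) stop_domain("need at least one tree")
  lapply(trees, check_phylo)
  if (is.null(all_species))
    all_species <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  all_species <- sort(unique(as.character(all_species)))
  for (tr in trees)
    if (!all(tr$tip.label %in% all_species))
      stop_domain("tree has leaves outside `all_species`")
  cols <- list()
  for (tr in trees) {
    sp <- tree_splits(tr)
    idx <- match(tr$tip.label, all_species)
    for (side in sp) {
      col <- rep(NA_integer_, length(all_species))
      col[idx] <- 0L
      col[idx[side]] <- 1L
      cols[[length(cols) + 1L]] <- col
    }
  }
  m <- if (length(cols)) do.call(cbind, cols)
       else matrix(NA_integer_, length(all_species), 0L)
  rownames(m) <- all_species
  colnames(m) <- if (ncol(m)) paste0("split", seq_len(ncol(m))) else NULL
  class(m) <- c("mrp_matrix", class(m))
  m
}

# ---- Fitch machinery on a nested-list tree representation ----------------
# A nested tree is either an integer (row index into the state matrix) or a
# list of two nested trees.  States are bitmasks: 1 = state 0, 2 = state 1,
# 3 = missing/wildcard.

state_matrix <- function(species, mrp) {
  S <- matrix(3L, nrow = length(species), ncol = max(1L, ncol(mrp)))
  rownames(S) <- species
  scored <- intersect(species, rownames(mrp))
  if (ncol(mrp)) {
    v <- mrp[scored, , drop = FALSE]
    S[scored, ] <- ifelse(is.na(v), 3L, ifelse(v == 1L, 2L, 1L))
  }
  if (ncol(mrp) == 0L) S <- S[, 0L, drop = FALSE]
  S
}

fitch_eval <- function(node, S) {
  if (!is.list(node))
    return(list(st = S[node, ], ch = 0L))
  a <- fitch_eval(node[[1L]], S)
  res_st <- a$st; res_ch <- a$ch
  for (k in seq_along(node)[-1L]) {
    b <- fitch_eval(node[[k]], S)
    inter <- bitwAnd(res_st, b$st)
    un <- bitwOr(res_st, b$st)
    miss <- inter == 0L
    res_st <- ifelse(miss, un, inter)
    res_ch <- res_ch + b$ch + sum(miss)
  }
  list(st = res_st, ch = res_ch)
}

# Score the unrooted tree formed by joining leaf `top` to nested tree `rest`.
fitch_score_nested <- function(rest, top, S) {
  r <- fitch_eval(rest, S)
  sum(bitwAnd(r$st, S[top, ]) == 0L) + r$ch
}

# phylo -> nested list of tip indices into `species` (fails on polytomies
# other than a root trifurcation, which sequential folding scores exactly).
phylo_to_nested <- function(tree, species) {
  nt <- length(tree$tip.label)
  idx <- match(tree$tip.label, species)
  if (anyNA(idx)) stop_domain("topology has leaves not in the matrix scope")
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  rec <- function(node, at_root) {
    if (node <= nt) return(idx[node])
    ch <- kids[[as.character(node)]]
    if (length(ch) > 3L || (length(ch) == 3L && !at_root))
      stop_domain("topology must be fully resolved (binary)")
    lapply(ch, rec, at_root = FALSE)
  }
  rec(root, TRUE)
}

#' Parsimony score of a topology against an MRP matrix
#'
#' Sum over matrix columns of the Fitch small-parsimony length of the
#' (unrooted, fully resolved) topology, with missing cells and species
#' absent from the matrix treated as wildcards that can take either state.
#'
#' @param topology a `"phylo"` tree whose leaves cover the matrix species.
#' @param mrp an [encode_mrp()] matrix (or any 0/1/NA matrix with species
#'   rownames).
#' @return integer parsimony score.
#' @export
parsimony_score <- function(topology, mrp) {
  check_phylo(topology)
  if (!all(rownames(mrp) %in% topology$tip.label))
    stop_domain("topology is missing scored species: ",
                paste(setdiff(rownames(mrp), topology$tip.label),
                      collapse = ", "))
  if (ncol(mrp) == 0L) return(0L)
  S <- state_matrix(topology$tip.label, mrp)
  nested <- phylo_to_nested(topology, topology$tip.label)
  r <- fitch_eval(nested, S)
  as.integer(r$ch)
}

# ---- canonical Newick (topology-only, deterministic) ---------------------

#' Canonical Newick string of an unrooted topology
#'
#' Topology-only serialization that is identical for all rooted or unrooted
#' representations of the same unrooted tree: rooted next to the
#' lexicographically smallest leaf, subtrees sorted recursively, no branch
#' lengths.  Used for deterministic tie-breaking and tree comparison.
#'
#' @param tree a `"phylo"` object with >= 3 leaves.
#' @return a Newick string.
#' @export
canonical_newick <- function(tree) {
  check_phylo(tree)
  labs <- tree$tip.label
  nt <- length(labs)
  if (nt < 3L) stop_domain("need at least 3 leaves")
  nb <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    nb[[p]] <- c(nb[[p]], c); nb[[c]] <- c(nb[[c]], p)
  }
  a <- which(labs == min(labs))[1L]
  start <- nb[[a]][1]
  canon <- function(node, from) {
    if (node <= nt) return(labs[node])
    subs <- sort(unlist(lapply(setdiff(nb[[node]], from), canon, from = node)))
    if (length(subs) == 1L) return(subs)
    paste0("(", paste(subs, collapse = ","), ")")
  }
  subs <- sort(unlist(lapply(setdiff(nb[[start]], a), canon, from = start)))
  inner <- if (length(subs) == 1L) sub("^\\((.*)\\)$", "\\1", subs)
           else paste(subs, collapse = ",")
  paste0("(", labs[a], ",", inner, ");")
}

# canonical string of a nested tree joined to top leaf `top`
canon_nested <- function(rest, top, species) {
  canon <- function(node) {
    if (!is.list(node)) return(species[node])
    subs <- sort(vapply(node, canon, character(1)))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  if (!is.list(rest))
    return(paste0("(", species[top], ",", species[rest], ");"))
  subs <- sort(vapply(rest, canon, character(1)))
  paste0("(", species[top], ",", paste(subs, collapse = ","), ");")
}

# all ways to insert `leaf` into nested tree `node` (on every edge and
# above the root)
nested_insert <- function(node, leaf) {
  res <- list(list(node, leaf))
  if (is.list(node)) {
    for (i in seq_along(node)) {
      for (sub in nested_insert(node[[i]], leaf)) {
        nn <- node
        nn[[i]] <- sub
        res[[length(res) + 1L]] <- nn
      }
    }
  }
  res
}

nested_to_newick <- function(rest, top, species) {
  fmt <- function(node) {
    if (!is.list(node)) return(species[node])
    paste0("(", paste(vapply(node, fmt, character(1)), collapse = ","), ")")
  }
  if (!is.list(rest))
    return(paste0("(", species[top], ",", species[rest], ");"))
  paste0("(", species[top], ",",
         paste(vapply(rest, fmt, character(1)), collapse = ","), ");")
}

#' MRP supertree
#'
#' Estimates a single species topology from a set of (possibly
#' taxon-incomplete) gene trees by matrix representation with parsimony:
#' the input topologies are Baum-Ragan coded ([encode_mrp()]) and the
#' unrooted binary topology minimizing the total Fitch parsimony score is
#' sought.  Exhaustive mode enumerates all `(2n-5)!!` topologies (capped at
#' 9 taxa); heuristic mode runs NNI hill-climbing from seeded
#' random-addition starts.  Ties are broken by the lexicographically
#' smallest [canonical_newick()] string, so results are reproducible.
#'
#' @param trees list of `"phylo"` gene trees.
#' @param mode `"auto"` (exhaustive up to 9 taxa, else heuristic),
#'   `"exhaustive"`, or `"heuristic"`.
#' @param seed RNG seed for the heuristic starts.
#' @param restarts number of random-addition restarts (heuristic mode).
#' @return a `"phylo"` topology (no branch lengths) with attributes
#'   `score` (its parsimony score) and `mode`.
#' @export
mrp_supertree <- function(trees, mode = c("auto", "exhaustive", "heuristic"),
                          seed = 1, restarts = 10) {
  mode <- match.arg(mode)
  if (length(trees) < 1L) stop_domain("need at least one input tree")
  mrp <- encode_mrp(trees)
  species <- rownames(mrp)
  n <- length(species)
  if (n < 3L) stop_domain("need at least 3 species across input trees")
  if (mode == "auto") mode <- if (n <= 9L) "exhaustive" else "heuristic"
  if (mode == "exhaustive" && n > 9L)
    stop_domain("exhaustive search capped at 9 taxa; use heuristic mode")
  S <- state_matrix(species, mrp)

  best <- new.env(parent = emptyenv())
  best$score <- Inf; best$canon <- NULL; best$newick <- NULL
  consider <- function(rest) {
    sc <- if (ncol(mrp)) fitch_score_nested(rest, 1L, S) else 0L
    if (sc > best$score) return(invisible())
    cn <- canon_nested(rest, 1L, species)
    if (sc < best$score || cn < best$canon) {
      best$score <- sc
      best$canon <- cn
      best$newick <- nested_to_newick(rest, 1L, species)
    }
    invisible()
  }

  if (mode == "exhaustive") {
    rec <- function(rest, next_taxon) {
      if (next_taxon > n) { consider(rest); return(invisible()) }
      for (cand in nested_insert(rest, next_taxon))
        rec(cand, next_taxon + 1L)
      invisible()
    }
    if (n == 3L) consider(list(2L, 3L)) else rec(list(2L, 3L), 4L)
  } else {
    for (r in seq_len(restarts)) {
      # greedy random-addition start: random taxon order, best insertion
      start <- with_seed(child_seed(seed, r), {
        ord <- if (n > 2L) sample(2:n) else 2L
        rest <- ord[1L]
        for (x in ord[-1L]) {
          cands <- nested_insert(rest, x)
          scs <- vapply(cands, fitch_score_nested, numeric(1),
                        top = 1L, S = S)
          k <- which(scs == min(scs))
          if (length(k) > 1L) {
            cns <- vapply(cands[k], canon_nested, character(1),
                          top = 1L, species = species)
            k <- k[order(cns)]
          }
          rest <- cands[[k[1L]]]
        }
        rest
      })
      tr <- read_newick(nested_to_newick(start, 1L, species))
      sc <- parsimony_score(tr, mrp)
      repeat {
        nbrs <- phangorn::nni(tr)
        nsc <- vapply(nbrs, parsimony_score, integer(1), mrp = mrp)
        if (length(nsc) && min(nsc) < sc) {
          k <- which(nsc == min(nsc))
          cns <- vapply(nbrs[k], canonical_newick, character(1))
          tr <- nbrs[k][[order(cns)[1L]]]
          sc <- min(nsc)
        } else break
      }
      cn <- canonical_newick(tr)
      if (sc < best$score || (sc == best$score && cn < best$canon)) {
        best$score <- sc
        best$canon <- cn
        best$newick <- ape::write.tree(tr)
      }
    }
  }
  out <- read_newick(best$canon)
  out$edge.length <- NULL
  attr(out, "score") <- as.integer(best$score)
  attr(out, "mode") <- mode
  out
}
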