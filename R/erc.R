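#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation,
#' `(C - D) / sqrt((n0 - n1) * (n0 - n2))` with `n0 = n(n-1)/2` and `n1`,
#' `n2` the tied-pair counts of each vector.  Delegates to
#' [stats::cor()] `method = "kendall"` (which implements tau-b); a constant
#' vector makes the correlation undefined and returns `NA` rather than 0.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return tau-b in `[-1, 1]`, or `NA_real_` when either vector is constant.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop_domain("vectors must have equal length")
  if (length(x) < 2L) stop_domain("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop_domain("missing values not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  as.numeric(stats::cor(x, y, method = "kendall"))
}

# Restrict a gene's branch-length table to a species subset by path-summing
# its own branch lengths onto the pruned topology.
restrict_table <- function(table, master, keep, ctx = NULL, cache = NULL) {
  keep <- sort(as.character(keep))
  if (identical(keep, table$species)) return(table)
  if (!all(keep %in% table$species))
    stop_domain("subset species missing from orthogroup ",
                table$orthogroup_id)
  if (is.null(ctx)) ctx <- master_context(master)
  res_g <- restrict_ctx(ctx, table$species, cache)
  res_s <- restrict_ctx(ctx, keep, cache)
  sub <- data.frame(gid = res_g$sub_id, sid = res_s$sub_id,
                    stringsAsFactors = FALSE)
  sub <- sub[!is.na(sub$sid), , drop = FALSE]
  # each pruned-to-keep branch is a union of whole gene-tree branches
  sub <- unique(sub)
  if (anyNA(sub$gid))
    stop_domain("inconsistent restriction for orthogroup ",
                table$orthogroup_id)
  lens <- tapply(as.numeric(table$lengths[sub$gid]), sub$sid, sum)
  structure(list(orthogroup_id = table$orthogroup_id,
                 species = keep,
                 lengths = stats::setNames(as.numeric(lens), names(lens))),
            class = "branch_table")
}

erc_undefined <- function(ga, gb, n_shared, status) {
  structure(list(gene_a = ga, gene_b = gb, tau = NA_real_,
                 n_branches = 0L, n_shared_species = as.integer(n_shared),
                 status = status),
            class = "erc_entry")
}

#' Evolutionary rate covariation of one gene pair
#'
#' Computes ERC between two orthogroups as Kendall's tau-b between their
#' relative evolutionary rates, evaluated on the tree containing exactly the
#' species the pair shares: both genes' branch lengths are path-summed onto
#' the master tree pruned to the shared species, expected lengths are
#' rebuilt there from the dataset-average tree, RERs are recomputed for both
#' genes on that common topology, and tau is taken over the branches both
#' retain.
#'
#' Pairs sharing fewer than `min_species` species, with fewer than 2 common
#' retained branches, or with a constant RER vector are undefined
#' (`tau = NA`) with a reason code in `status`.
#'
#' @param a,b [branch_table()] objects.
#' @param avg the dataset [build_average_tree()].
#' @param master the master species tree.
#' @param min_species minimum shared species for a defined pair (default 6).
#' @param floor expected-length floor passed to [compute_rer()].
#' @return an object of class `"erc_entry"`: list with `gene_a`, `gene_b`,
#'   `tau`, `n_branches`, `n_shared_species`, `status` (`"ok"` or a reason
#'   code).  Symmetric: the entry is identical whichever order the genes are
#'   given in.
#' @export
erc_pair <- function(a, b, avg, master, min_species = 6, floor = 1e-9,
                     .ctx = NULL, .cache = NULL) {
  if (!inherits(a, "branch_table") || !inherits(b, "branch_table"))
    stop_domain("`a` and `b` must be branch_table objects")
  if (a$orthogroup_id > b$orthogroup_id) { tmp <- a; a <- b; b <- tmp }
  shared <- intersect(a$species, b$species)
  if (length(shared) < min_species)
    return(erc_undefined(a$orthogroup_id, b$orthogroup_id, length(shared),
                         "insufficient shared species"))
  if (is.null(.ctx)) .ctx <- master_context(master)
  exp_s <- expected_lengths(avg, master, shared, .ctx, .cache)
  ra <- tryCatch(compute_rer(restrict_table(a, master, shared, .ctx, .cache),
                             exp_s, floor),
                 ratecov_degenerate_error = function(e) NULL)
  rb <- tryCatch(compute_rer(restrict_table(b, master, shared, .ctx, .cache),
                             exp_s, floor),
                 ratecov_degenerate_error = function(e) NULL)
  if (is.null(ra) || is.null(rb))
    return(erc_undefined(a$orthogroup_id, b$orthogroup_id, length(shared),
                         "degenerate gene"))
  common <- intersect(ra$branch_ids, rb$branch_ids)
  if (length(common) < 2L)
    return(erc_undefined(a$orthogroup_id, b$orthogroup_id, length(shared),
                         "too few branches"))
  x <- ra$residual[match(common, ra$branch_ids)]
  y <- rb$residual[match(common, rb$branch_ids)]
  tau <- kendall_tau(x, y)
  status <- if (is.na(tau)) "constant RER vector" else "ok"
  structure(list(gene_a = a$orthogroup_id, gene_b = b$orthogroup_id,
                 tau = tau, n_branches = length(common),
                 n_shared_species = length(shared), status = status),
            class = "erc_entry")
}

#' @export
print.erc_entry <- function(x, ...) {
  cat("ERC ", x$gene_a, " ~ ", x$gene_b, ": tau = ",
      ifelse(is.na(x$tau), "NA", format(x$tau, digits = 4)),
      "  (", x$n_branches, " branches, ", x$n_shared_species,
      " shared species, ", x$status, ")\n", sep = "")
  invisible(x)
}

#' All-pairs ERC matrix
#'
#' Evaluates [erc_pair()] for every unordered pair of orthogroups.  The
#' diagonal is 1 by convention and excluded from percentile pools.
#'
#' @inheritParams erc_pair
#' @param tables list of [branch_table()] objects (length >= 2), uniquely
#'   named by orthogroup.
#' @return an object of class `"erc_matrix"`: list with symmetric numeric
#'   matrix `tau` (NA = undefined), integer matrices `n_branches` and
#'   `n_shared_species`, character matrix `status`, and `genes`.
#' @export
erc_matrix <- function(tables, avg, master, min_species = 6, floor = 1e-9) {
  if (length(tables) < 2L) stop_domain("need at least 2 orthogroups")
  ids <- unname(vapply(tables, function(tb) tb$orthogroup_id, character(1)))
  if (anyDuplicated(ids)) stop_domain("duplicate orthogroup IDs")
  g <- length(ids)
  tau <- matrix(NA_real_, g, g, dimnames = list(ids, ids))
  nb <- matrix(0L, g, g, dimnames = list(ids, ids))
  ns <- matrix(0L, g, g, dimnames = list(ids, ids))
  st <- matrix("diagonal", g, g, dimnames = list(ids, ids))
  diag(tau) <- 1
  ctx <- master_context(master)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(g - 1L)) for (j in seq(i + 1L, g)) {
    e <- erc_pair(tables[[i]], tables[[j]], avg, master, min_species, floor,
                  .ctx = ctx, .cache = cache)
    tau[i, j] <- tau[j, i] <- e$tau
    nb[i, j] <- nb[j, i] <- e$n_branches
    ns[i, j] <- ns[j, i] <- e$n_shared_species
    st[i, j] <- st[j, i] <- e$status
  }
  structure(list(tau = tau, n_branches = nb, n_shared_species = ns,
                 status = st, genes = ids),
            class = "erc_matrix")
}

#' @export
print.erc_matrix <- function(x, ...) {
  off <- x$tau[upper.tri(x$tau)]
  cat("ERC matrix: ", length(x$genes), " genes, ",
      length(off), " pairs (", sum(!is.na(off)), " defined)\n", sep = "")
  if (any(!is.na(off)))
    cat("  tau range [", format(min(off, na.rm = TRUE), digits = 3), ", ",
        format(max(off, na.rm = TRUE), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Rank ERC partners of a focal gene
#'
#' Orders all partners of a focal gene by ERC value and annotates each tau
#' with the fraction of defined tau values strictly greater than it — 0.013
#' reads "top 1.3%".  The pool is either every defined off-diagonal pair in
#' the matrix (`percentile = "all_pairs"`) or the focal gene's own row
#' (`"focal_row"`); published percentile claims are ambiguous between the
#' two, so both are exposed.  The hit set collects partners at or above
#' `threshold`.
#'
#' @param m an [erc_matrix()].
#' @param focal focal orthogroup ID.
#' @param threshold ERC threshold for the hit set (default 0.4).
#' @param percentile percentile pool, `"all_pairs"` (default) or
#'   `"focal_row"`.
#' @return an object of class `"erc_ranking"`: data.frame with columns
#'   `partner`, `tau`, `top_fraction`, `hit`, sorted by decreasing tau
#'   (undefined last); attributes `focal`, `threshold`, `n_hits`, `pool`.
#' @export
focal_ranking <- function(m, focal, threshold = 0.4,
                          percentile = c("all_pairs", "focal_row")) {
  if (!inherits(m, "erc_matrix")) stop_domain("`m` must be an erc_matrix")
  percentile <- match.arg(percentile)
  if (!focal %in% m$genes) stop_domain("unknown focal gene: ", focal)
  if (threshold < -1 || threshold > 1)
    stop_domain("threshold must be in [-1, 1]")
  taus <- m$tau[focal, setdiff(m$genes, focal)]
  pool <- if (percentile == "all_pairs") m$tau[upper.tri(m$tau)] else taus
  pool <- pool[!is.na(pool)]
  top_frac <- vapply(taus, function(t)
    if (is.na(t)) NA_real_ else mean(pool > t), numeric(1))
  ord <- order(taus, decreasing = TRUE, na.last = TRUE)
  out <- data.frame(partner = names(taus)[ord], tau = as.numeric(taus[ord]),
                    top_fraction = as.numeric(top_frac[ord]),
                    hit = !is.na(taus[ord]) & taus[ord] >= threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, focal = focal, threshold = threshold,
            n_hits = sum(out$hit), pool = percentile,
            class = c("erc_ranking", "data.frame"))
}

#' @export
print.erc_ranking <- function(x, n = 10, ...) {
  cat("ERC ranking for focal gene ", attr(x, "focal"),
      " (threshold ", attr(x, "threshold"), ", ",
      attr(x, "n_hits"), " hits; percentile pool: ", attr(x, "pool"),
      ")\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more partners\n", sep = "")
  invisible(x)
}

#' Wilcoxon rank-sum contrast between two gene groups
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test on a per-gene score
#' (e.g. mean migration fraction), comparing a hit group against controls.
#' With combined group size at most 12 the p-value is computed by exact
#' enumeration of all label assignments (tie-aware: extremeness is distance
#' of the rank sum from its null expectation); larger samples use the
#' normal approximation with tie and continuity corrections.
#'
#' @param score named numeric vector of per-gene scores.
#' @param group_hits,group_controls disjoint, non-empty character vectors of
#'   gene IDs, all present in `names(score)`.
#' @return list with `statistic` (rank sum of the hit group), `p.value`,
#'   `method` (`"exact"` or `"normal"`), `n_hits`, `n_controls`.
#' @examples
#' group_contrast(c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6),
#'                c("a", "b", "c"), c("d", "e", "f"))$p.value  # 0.1
#' @export
group_contrast <- function(score, group_hits, group_controls) {
  if (length(group_hits) == 0L || length(group_controls) == 0L)
    stop_domain("both groups must be non-empty")
  if (length(intersect(group_hits, group_controls)) > 0L)
    stop_domain("groups must be disjoint")
  g <- c(group_hits, group_controls)
  if (!all(g %in% names(score)))
    stop_domain("score missing for: ",
                paste(setdiff(g, names(score)), collapse = ", "))
  x <- as.numeric(score[group_hits])
  y <- as.numeric(score[group_controls])
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= 12L) {
    combos <- utils::combn(n, n1)
    Wall <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    d <- W - mu
    z <- if (sigma2 <= 0) 0 else (d - sign(d) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p.value = p, method = method,
       n_hits = n1, n_controls = n2)
}

#' Export an ERC matrix as TSV
#'
#' Long format: `gene_a`, `gene_b`, `tau`, `n_branches`,
#' `n_shared_species`, `status`, one row per unordered pair.
#'
#' @param m an [erc_matrix()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_erc_matrix <- function(m, path) {
  ut <- which(upper.tri(m$tau), arr.ind = TRUE)
  df <- data.frame(gene_a = m$genes[ut[, 1]], gene_b = m$genes[ut[, 2]],
                   tau = m$tau[ut], n_branches = m$n_branches[ut],
                   n_shared_species = m$n_shared_species[ut],
                   status = m$status[ut], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
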