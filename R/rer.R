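#' Filter orthogroups by species representation
#'
#' Retains only orthogroups whose trees cover at least `min_species` species.
#' Orthogroups below the threshold carry too few branches for a stable rate
#' residual; the default of 6 matches the standard ERC practice for
#' 22-species Drosophila panels.
#'
#' @param tables list of [branch_table()] objects.
#' @param min_species minimum species count (default 6).
#' @return the retained subset of `tables`, input order preserved.
#' @export
filter_orthogroups <- function(tables, min_species = 6) {
  if (min_species < 2) stop_domain("min_species must be >= 2")
  keep <- vapply(tables, function(tb) length(tb$species) >= min_species,
                 logical(1))
  tables[keep]
}

#' Dataset-average branch lengths on the master topology
#'
#' For every branch of the master species tree, the arithmetic mean of the
#' branch lengths attributed to it across orthogroups.  An orthogroup
#' contributes to a master branch only when that branch maps one-to-one onto
#' a branch of the orthogroup's pruned topology (a merged multi-edge path
#' cannot be decomposed into per-edge lengths and would bias the mean).
#' Branches with no contributors get mean 0 and are flagged by a zero count.
#'
#' @param tables list of [branch_table()] objects (all consistent with
#'   `master`).
#' @param master the master species tree (`"phylo"`).
#' @return an object of class `"avg_tree"`: list with `mean` and `count`
#'   (named numeric/integer vectors over master BranchIDs) and `master_ids`.
#' @export
build_average_tree <- function(tables, master, .ctx = NULL, .cache = NULL) {
  check_phylo(master)
  if (length(tables) < 1L) stop_domain("need at least one orthogroup table")
  if (is.null(.ctx)) .ctx <- master_context(master)
  all_ids <- branch_ids(master)
  sums <- stats::setNames(numeric(length(all_ids)), all_ids)
  cnts <- stats::setNames(integer(length(all_ids)), all_ids)
  for (tb in tables) {
    res <- restrict_ctx(.ctx, tb$species, .cache)
    res <- res[!is.na(res$sub_id), , drop = FALSE]
    expect_ids <- sort(unique(res$sub_id))
    have_ids <- sort(names(tb$lengths))
    if (!identical(expect_ids, have_ids))
      stop_domain("branch IDs of orthogroup ", tb$orthogroup_id,
                  " are inconsistent with the master topology")
    path_sizes <- table(res$sub_id)
    solo <- res$sub_id %in% names(path_sizes)[path_sizes == 1L]
    mids <- res$master_id[solo]
    sums[mids] <- sums[mids] + as.numeric(tb$lengths[res$sub_id[solo]])
    cnts[mids] <- cnts[mids] + 1L
  }
  means <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), 0)
  structure(list(mean = stats::setNames(as.numeric(means), all_ids),
                 count = cnts, master_ids = all_ids),
            class = "avg_tree")
}

#' @export
print.avg_tree <- function(x, ...) {
  cat("Dataset-average tree: ", length(x$master_ids), " branches, ",
      sum(x$count > 0), " resolved (count > 0)\n", sep = "")
  invisible(x)
}

#' Expected branch lengths on a species subset
#'
#' For each branch of `prune(master, keep)`, the sum of dataset-average
#' branch lengths over the master-edge path that merges into it.  This is
#' the regression covariate for the RER residuals of an orthogroup covering
#' exactly the species in `keep`.
#'
#' @param avg an `"avg_tree"` from [build_average_tree()].
#' @param master the master species tree.
#' @param keep species subset (>= 2).
#' @return named numeric vector: BranchID (on the pruned topology) ->
#'   expected length.
#' @export
expected_lengths <- function(avg, master, keep, .ctx = NULL, .cache = NULL) {
  if (!inherits(avg, "avg_tree")) stop_domain("`avg` must be an avg_tree")
  if (length(keep) < 2L) stop_domain("need at least 2 species")
  paths <- master_path_map(master, keep, .ctx, .cache)
  vapply(paths, function(mids) sum(avg$mean[mids]), numeric(1))
}

#' Relative evolutionary rates of one orthogroup
#'
#' Regresses an orthogroup's observed branch lengths against the expected
#' lengths from the dataset-average tree, by through-origin ordinary least
#' squares (model `observed = rate * expected`), and returns the residuals
#' as relative evolutionary rates: a branch where the gene accumulated more
#' change than expected for its overall rate gets a positive RER, less
#' change a negative RER.
#'
#' Branches whose expected length falls below `floor` are dropped before the
#' fit (an unresolvable or zero-mean branch would otherwise have unbounded
#' leverage).  A gene with all-zero branch lengths gets rate 0 and all-zero
#' residuals; downstream correlation treats such constant vectors as
#' undefined.
#'
#' @param table a [branch_table()].
#' @param expected named numeric vector of expected lengths covering the
#'   table's branches (from [expected_lengths()]).
#' @param floor minimum usable expected length (default `1e-9`).
#' @return an object of class `"rer"`: list with `orthogroup_id`, `species`,
#'   `branch_ids`, `observed`, `expected`, `residual` (the RERs) and `rate`
#'   (the fitted through-origin slope).
#' @export
compute_rer <- function(table, expected, floor = 1e-9) {
  if (!inherits(table, "branch_table"))
    stop_domain("`table` must be a branch_table")
  if (floor <= 0) stop_domain("`floor` must be > 0")
  ids <- names(table$lengths)
  if (!all(ids %in% names(expected)))
    stop_domain("`expected` does not cover branches of orthogroup ",
                table$orthogroup_id)
  a <- as.numeric(expected[ids])
  b <- as.numeric(table$lengths)
  use <- a >= floor
  if (sum(use) < 2L)
    stop_degenerate("fewer than 2 usable branches for orthogroup ",
                    table$orthogroup_id)
  a <- a[use]; b <- b[use]; ids <- ids[use]
  denom <- sum(a * a)
  r <- if (denom > 0) sum(a * b) / denom else 0
  resid <- b - r * a
  # residuals at machine-precision scale carry no rank information and
  # would otherwise feed spurious rank correlations; snap them to zero
  eps <- 1e-12 * max(abs(b), 1e-300)
  resid[abs(resid) < eps] <- 0
  structure(list(orthogroup_id = table$orthogroup_id,
                 species = table$species,
                 branch_ids = ids,
                 observed = stats::setNames(b, ids),
                 expected = stats::setNames(a, ids),
                 residual = stats::setNames(resid, ids),
                 rate = r),
            class = "rer")
}

#' @export
print.rer <- function(x, ...) {
  cat("RER vector: ", x$orthogroup_id, "\n",
      "  rate (through-origin slope): ", format(x$rate, digits = 4), "\n",
      "  branches: ", length(x$residual),
      ", residual range [", format(min(x$residual), digits = 3), ", ",
      format(max(x$residual), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Export an average tree or RER set as TSV
#'
#' @param avg an `"avg_tree"`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_average_tree <- function(avg, path) {
  df <- data.frame(branch_id = avg$master_ids,
                   mean = as.numeric(avg$mean),
                   count = as.integer(avg$count), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_average_tree
#' @param rers list of `"rer"` objects.
#' @export
write_rer_table <- function(rers, path) {
  rows <- lapply(rers, function(r)
    data.frame(orthogroup_id = r$orthogroup_id, branch_id = r$branch_ids,
               expected = r$expected, observed = r$observed,
               residual = r$residual, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
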