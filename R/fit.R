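#' Fit an evolutionary rate covariation model
#'
#' The one-stop estimator: filters orthogroups by species representation,
#' builds the dataset-average tree on the master topology, computes each
#' orthogroup's relative evolutionary rates, and (optionally) the full
#' pairwise ERC matrix.
#'
#' @param tables list of [branch_table()] objects, one per orthogroup.
#' @param master master species tree (`"phylo"`).
#' @param min_species minimum species representation, applied both as the
#'   orthogroup filter and pairwise to shared species (default 6).
#' @param floor expected-length floor for the RER regression (default 1e-9).
#' @param compute_matrix compute the all-pairs ERC matrix (default `TRUE`;
#'   cost grows quadratically in the number of orthogroups).
#' @return an object of class `"erc_fit"`: list with `tables` (retained),
#'   `master`, `avg` (the average tree), `rers` (per-orthogroup RERs on each
#'   gene's own species set; `NULL` entries for degenerate genes), `matrix`
#'   (an [erc_matrix()] or `NULL`), `min_species`, `floor`, `n_dropped`.
#' @seealso [focal_ranking()], [erc_pair()]
#' @export
erc_fit <- function(tables, master, min_species = 6, floor = 1e-9,
                    compute_matrix = TRUE) {
  check_phylo(master)
  kept <- filter_orthogroups(tables, min_species)
  if (length(kept) < 2L)
    stop_domain("fewer than 2 orthogroups pass the species filter")
  ctx <- master_context(master)
  cache <- new.env(parent = emptyenv())
  avg <- build_average_tree(kept, master, .ctx = ctx, .cache = cache)
  rers <- lapply(kept, function(tb) {
    exp_s <- expected_lengths(avg, master, tb$species, ctx, cache)
    tryCatch(compute_rer(tb, exp_s, floor),
             ratecov_degenerate_error = function(e) NULL)
  })
  names(rers) <- vapply(kept, function(tb) tb$orthogroup_id, character(1))
  ndeg <- sum(vapply(rers, is.null, logical(1)))
  if (ndeg > 0)
    warning(ndeg, " degenerate orthogroup(s) excluded from RER output")
  m <- if (compute_matrix) erc_matrix(kept, avg, master, min_species, floor)
       else NULL
  structure(list(tables = kept, master = master, avg = avg, rers = rers,
                 matrix = m, min_species = min_species, floor = floor,
                 n_dropped = length(tables) - length(kept)),
            class = "erc_fit")
}

#' @export
print.erc_fit <- function(x, ...) {
  cat("Evolutionary rate covariation fit\n",
      "  orthogroups: ", length(x$tables), " retained (",
      x$n_dropped, " below ", x$min_species, " species)\n",
      "  master tree: ", length(x$master$tip.label), " species\n", sep = "")
  if (!is.null(x$matrix)) {
    off <- x$matrix$tau[upper.tri(x$matrix$tau)]
    cat("  ERC pairs:   ", length(off), " (", sum(!is.na(off)),
        " defined)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.erc_fit <- function(object, threshold = 0.4, ...) {
  rates <- vapply(object$rers, function(r)
    if (is.null(r)) NA_real_ else r$rate, numeric(1))
  out <- list(n_orthogroups = length(object$tables),
              n_dropped = object$n_dropped,
              min_species = object$min_species,
              rate_summary = summary(rates[!is.na(rates)]),
              threshold = threshold)
  if (!is.null(object$matrix)) {
    off <- object$matrix$tau[upper.tri(object$matrix$tau)]
    out$n_pairs <- length(off)
    out$n_defined <- sum(!is.na(off))
    out$tau_summary <- summary(off[!is.na(off)])
    out$n_above_threshold <- sum(off >= threshold, na.rm = TRUE)
  }
  class(out) <- "summary.erc_fit"
  out
}

#' @export
print.summary.erc_fit <- function(x, ...) {
  cat("ERC fit: ", x$n_orthogroups, " orthogroups (",
      x$n_dropped, " dropped below ", x$min_species, " species)\n", sep = "")
  cat("Through-origin rates:\n"); print(x$rate_summary)
  if (!is.null(x$tau_summary)) {
    cat("Pairwise tau (", x$n_defined, "/", x$n_pairs, " defined):\n",
        sep = "")
    print(x$tau_summary)
    cat("Pairs with tau >= ", x$threshold, ": ", x$n_above_threshold,
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.erc_fit <- function(object, ...) {
  if (is.null(object$matrix))
    stop_domain("fit was computed with compute_matrix = FALSE")
  object$matrix$tau
}

#' Plot an ERC fit
#'
#' Histogram of the defined pairwise tau values, with an optional focal
#' gene's partner values overlaid as a rug and the threshold marked.
#'
#' @param x an `"erc_fit"`.
#' @param focal optional focal gene ID to highlight.
#' @param threshold ERC threshold line (default 0.4).
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.erc_fit <- function(x, focal = NULL, threshold = 0.4, ...) {
  if (is.null(x$matrix))
    stop_domain("fit was computed with compute_matrix = FALSE")
  off <- x$matrix$tau[upper.tri(x$matrix$tau)]
  off <- off[!is.na(off)]
  graphics::hist(off, breaks = 30, main = "Pairwise ERC (Kendall's tau-b)",
                 xlab = "tau", col = "grey85", border = "grey40", ...)
  graphics::abline(v = threshold, col = "firebrick", lty = 2)
  if (!is.null(focal)) {
    taus <- x$matrix$tau[focal, setdiff(x$matrix$genes, focal)]
    graphics::rug(taus[!is.na(taus)], col = "steelblue", lwd = 1.5)
  }
  invisible(x)
}
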