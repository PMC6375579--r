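# Quantification statistics for the border-cell migration screen layer:
# migration classing, cluster disassociation rates, junctional-intensity
# normalization, protrusion-angle sectors, and gene-set over-representation.
# All operations consume tabular records (real or from simulate_screen()).

MIGRATION_CLASSES <- c("no_migration", "delayed", "completed")

#' Classify migration completeness
#'
#' Assigns border-cell cluster positions (fraction of the anterior-posterior
#' migratory path traversed) to the standard scoring classes: 0-25% no
#' migration, 25-75% delayed, 75-100% completed.  Boundaries are half-open
#' with the top class closed at 1 (`0.25` is delayed, `0.75` completed).
#'
#' @param f numeric vector of migration fractions in `[0, 1]`.
#' @return factor with levels `no_migration`, `delayed`, `completed`.
#' @examples
#' classify_migration(c(0.1, 0.5, 1.0))
#' @export
classify_migration <- function(f) {
  if (anyNA(f) || any(f < 0 | f > 1))
    stop_domain("migration fractions must be in [0, 1]")
  # right = FALSE + include.lowest makes bins [0,.25), [.25,.75), [.75,1]
  cut(f, breaks = c(0, 0.25, 0.75, 1), labels = MIGRATION_CLASSES,
      right = FALSE, include.lowest = TRUE)
}

#' Per-gene migration class proportions
#'
#' @param records data.frame with columns `genotype` and
#'   `migration_fraction` (e.g. from [simulate_screen()]).
#' @param gene genotype to summarize.
#' @return list with `fractions` (named proportions over the three classes,
#'   summing to 1), `counts`, and `n`.
#' @export
class_fractions <- function(records, gene) {
  rec <- records[records$genotype == gene, , drop = FALSE]
  if (nrow(rec) == 0L) stop_domain("no records for genotype ", gene)
  cl <- classify_migration(rec$migration_fraction)
  counts <- table(cl)
  list(fractions = stats::setNames(as.numeric(counts) / nrow(rec),
                                   MIGRATION_CLASSES),
       counts = stats::setNames(as.integer(counts), MIGRATION_CLASSES),
       n = nrow(rec))
}

#' Per-gene cluster disassociation rate
#'
#' Proportion of egg chambers in which one or more border cells detached
#' from the migrating cluster.
#'
#' @param records data.frame with columns `genotype` and `disassociated`.
#' @param gene genotype to summarize.
#' @return list with `rate`, `n_disassociated`, `n`.
#' @export
disassociation_rate <- function(records, gene) {
  rec <- records[records$genotype == gene, , drop = FALSE]
  if (nrow(rec) == 0L) stop_domain("no records for genotype ", gene)
  list(rate = mean(rec$disassociated),
       n_disassociated = sum(rec$disassociated), n = nrow(rec))
}

#' Normalized junctional intensity from linescan profiles
#'
#' For each border-cell (BC-BC) contact linescan, the peak intensity divided
#' by the aggregate of nurse-cell (NC-NC) contact peaks of the same egg
#' chamber, so junctional protein levels are comparable across chambers.
#'
#' @param profiles data.frame with columns `profile_id`, `chamber`, `class`
#'   (`"BC"` or `"NC"`), `position`, `intensity`; at least 3 samples per
#'   profile, at least one profile of each class per chamber.
#' @param aggregate how to pool NC peaks within a chamber: `"mean"`
#'   (default) or `"median"`.
#' @return data.frame with one row per BC profile: `profile_id`, `chamber`,
#'   `peak`, `nc_reference`, `normalized`.
#' @export
contact_intensity <- function(profiles, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  need <- c("profile_id", "chamber", "class", "position", "intensity")
  if (!all(need %in% names(profiles)))
    stop_domain("profiles must have columns: ", paste(need, collapse = ", "))
  if (any(profiles$intensity < 0))
    stop_domain("intensities must be >= 0")
  ns <- table(profiles$profile_id)
  if (any(ns < 3L)) stop_domain("each linescan needs at least 3 samples")
  peaks <- tapply(profiles$intensity, profiles$profile_id, max)
  meta <- unique(profiles[, c("profile_id", "chamber", "class")])
  if (anyDuplicated(meta$profile_id))
    stop_domain("a profile_id maps to more than one chamber/class")
  meta$peak <- as.numeric(peaks[as.character(meta$profile_id)])
  agg_fun <- if (aggregate == "mean") mean else stats::median
  out <- list()
  for (ch in unique(meta$chamber)) {
    sub <- meta[meta$chamber == ch, , drop = FALSE]
    bc <- sub[sub$class == "BC", , drop = FALSE]
    nc <- sub[sub$class == "NC", , drop = FALSE]
    if (nrow(bc) == 0L || nrow(nc) == 0L)
      stop_domain("chamber ", ch, " needs >= 1 BC and >= 1 NC profile")
    ref <- agg_fun(nc$peak)
    if (ref <= 0) stop_degenerate("zero NC reference peak in chamber ", ch)
    out[[length(out) + 1L]] <-
      data.frame(profile_id = bc$profile_id, chamber = ch, peak = bc$peak,
                 nc_reference = ref, normalized = bc$peak / ref,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Protrusion-angle sectors and histogram
#'
#' Bins protrusion angles (degrees, 0 = direction of migration) into eight
#' 45-degree bins and the three standard sectors: front `[315, 360) U
#' [0, 45)`, middle `[45, 135) U [225, 315)`, rear `[135, 225)`.  Boundary
#' angles belong to the clockwise-starting sector (45 is middle, 135 rear,
#' 225 middle, 315 front).
#'
#' @param angles numeric vector of angles in `[0, 360)`.
#' @return list with `sectors` (named counts front/middle/rear), `histogram`
#'   (8 named 45-degree bins), `n`.
#' @export
protrusion_sectors <- function(angles) {
  if (anyNA(angles) || any(angles < 0 | angles >= 360))
    stop_domain("angles must be in [0, 360)")
  bins <- findInterval(angles, seq(0, 315, by = 45))
  hist <- stats::setNames(tabulate(bins, nbins = 8L),
                          paste0("[", seq(0, 315, 45), ",",
                                 seq(45, 360, 45), ")"))
  sector_of <- c("front", "middle", "middle", "rear",
                 "rear", "middle", "middle", "front")
  sectors <- c(front = sum(hist[sector_of == "front"]),
               middle = sum(hist[sector_of == "middle"]),
               rear = sum(hist[sector_of == "rear"]))
  list(sectors = sectors, histogram = hist, n = length(angles))
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric upper-tail test of whether a hit list is
#' enriched for each annotation term, with Benjamini-Hochberg adjustment
#' across terms.
#'
#' @param hits character vector of hit genes (subset of `universe`).
#' @param universe character vector of all testable genes.
#' @param annotation named list: term -> character vector of member genes
#'   (each a subset of `universe`).
#' @return data.frame with one row per term: `term`, `n_term`, `n_overlap`,
#'   `fold` (observed/expected overlap; 0 when no overlap), `p`
#'   (hypergeometric), `q` (BH-adjusted).
#' @export
enrichment_test <- function(hits, universe, annotation) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!all(hits %in% universe))
    stop_domain("hits outside the universe: ",
                paste(setdiff(hits, universe), collapse = ", "))
  if (length(annotation) == 0L) stop_domain("no annotation terms")
  N <- length(universe); h <- length(hits)
  rows <- lapply(names(annotation), function(term) {
    genes <- unique(as.character(annotation[[term]]))
    if (!all(genes %in% universe))
      stop_domain("term ", term, " has genes outside the universe")
    K <- length(genes)
    k <- length(intersect(genes, hits))
    fold <- if (k == 0L) 0 else (k / h) / (K / N)
    p <- stats::phyper(k - 1L, K, N - K, h, lower.tail = FALSE)
    data.frame(term = term, n_term = K, n_overlap = k, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Read screen records / protrusion angles / linescan profiles from TSV
#'
#' Thin readers for the documented one-header-line TSV schemas:
#' `read_screen_records()` expects columns `genotype`, `migration_fraction`,
#' `disassociated` (0/1 or TRUE/FALSE); `read_protrusion_angles()` a column
#' `angle`; `read_linescans()` the [contact_intensity()] columns.
#'
#' @param path TSV file path.
#' @return a data.frame (or numeric vector of angles).
#' @export
read_screen_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "migration_fraction", "disassociated")
  if (!all(need %in% names(df)))
    stop_domain("screen TSV must have columns: ",
                paste(need, collapse = ", "))
  df$disassociated <- if (is.numeric(df$disassociated))
    df$disassociated != 0 else as.logical(df$disassociated)
  df
}

#' @rdname read_screen_records
#' @export
read_protrusion_angles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"angle" %in% names(df))
    stop_domain("protrusion TSV must have an `angle` column")
  df$angle
}

#' @rdname read_screen_records
#' @export
read_linescans <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
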