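# Synthetic-data generator: master species trees and orthogroup
# branch-length tables with planted co-functional modules, plus a
# phenotype-screen record simulator.  Everything is deterministic under the
# configured seed, with one derived RNG substream per module and per gene so
# that generated objects do not depend on evaluation order.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the orthogroup generator.  The
#' generative model for gene `g` on master branch `e` is
#' `b[g,e] = r[g] * a[e] * exp(sigma_shared * z[m(g),e] + sigma_noise *
#' eps[g,e])` with `a` the master branch lengths, `r[g]` the gene's base
#' rate, `z` a latent per-module, per-branch deviation shared by all module
#' members, and `eps` independent gene-level noise (all standard normal).
#' Genes outside any module have no `z` term.  Multiplicative log-normal
#' deviations keep branch lengths positive without truncation.
#'
#' @param n_species number of species on the master tree (default 22, the
#'   size of the Drosophila panel this generator emulates).
#' @param n_orthogroups number of orthogroup tables to generate.
#' @param module_spec named list of character vectors: module ID -> member
#'   gene IDs (gene IDs are `"g001"`, `"g002"`, ...).  Members must be
#'   disjoint across modules.
#' @param sigma_shared log-scale SD of the shared module deviation
#'   (default 0.5).
#' @param sigma_noise log-scale SD of gene-level noise (default 0.1).
#' @param rate_range range of per-gene base rates, drawn uniformly
#'   (default `c(0.5, 2)`).
#' @param dropout_prob per-species, per-gene dropout probability
#'   (default 0.1); species sets are redrawn until at least `min_species`
#'   remain, so every generated table passes the orthogroup filter.
#' @param min_species minimum species per orthogroup (default 6).
#' @param seed RNG seed.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 22, n_orthogroups = 200,
                       module_spec = list(), sigma_shared = 0.5,
                       sigma_noise = 0.1, rate_range = c(0.5, 2),
                       dropout_prob = 0.1, min_species = 6, seed = 1) {
  if (n_species < 3) stop_domain("n_species must be >= 3")
  if (n_orthogroups < 1) stop_domain("n_orthogroups must be >= 1")
  if (sigma_shared < 0 || sigma_noise < 0)
    stop_domain("sigma parameters must be >= 0")
  if (length(rate_range) != 2L || rate_range[1] <= 0 ||
      rate_range[2] < rate_range[1])
    stop_domain("rate_range must be (lo, hi) with lo > 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop_domain("dropout_prob must be in [0, 1)")
  if (min_species < 2 || min_species > n_species)
    stop_domain("min_species must be in [2, n_species]")
  gene_ids <- sprintf("g%03d", seq_len(n_orthogroups))
  members <- unlist(module_spec, use.names = FALSE)
  if (anyDuplicated(members))
    stop_domain("module members must be disjoint")
  if (!all(members %in% gene_ids))
    stop_domain("module members outside the generated gene IDs: ",
                paste(setdiff(members, gene_ids), collapse = ", "))
  structure(list(n_species = as.integer(n_species),
                 n_orthogroups = as.integer(n_orthogroups),
                 module_spec = module_spec,
                 sigma_shared = sigma_shared, sigma_noise = sigma_noise,
                 rate_range = rate_range, dropout_prob = dropout_prob,
                 min_species = as.integer(min_species),
                 seed = as.integer(seed), gene_ids = gene_ids),
            class = "sim_config")
}

#' Simulate a master species tree
#'
#' Random unrooted binary topology drawn uniformly over labeled topologies
#' (sequential random attachment of each leaf to a uniformly chosen existing
#' branch) with branch lengths drawn from an exponential with mean
#' `mean_length` substitutions per site.  Deterministic given `seed`.
#'
#' @param n_species number of species (>= 3); leaves are labeled `"s01"`,
#'   `"s02"`, ...
#' @param seed RNG seed.
#' @param mean_length mean branch length (default 0.1).
#' @return a `"phylo"` tree with `2 * n_species - 3` unrooted branches.
#' @export
simulate_species_tree <- function(n_species, seed = 1, mean_length = 0.1) {
  if (n_species < 3) stop_domain("n_species must be >= 3")
  labels <- sprintf("s%02d", seq_len(n_species))
  with_seed(seed, {
    rest <- 2L
    for (x in seq(3L, n_species)) {
      cands <- nested_insert(rest, x)
      rest <- cands[[sample.int(length(cands), 1L)]]
    }
    tr <- read_newick(nested_to_newick(rest, 1L, labels))
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_length)
    tr
  })
}

#' Simulate orthogroup branch-length tables with planted modules
#'
#' Generates one [branch_table()] per gene under the model documented in
#' [sim_config()]: gene-specific base rates, shared log-normal rate
#' deviations within planted co-functional modules, independent gene-level
#' noise, and random species dropout.  Pruned-tree branch lengths are
#' obtained by path-summing the per-master-branch values, exactly as real
#' orthogroup trees relate to the species tree.
#'
#' @param cfg a [sim_config()].
#' @param master master species tree; defaults to
#'   `simulate_species_tree(cfg$n_species, cfg$seed)`.
#' @return an object of class `"erc_sim"`: list with `master`, `tables`
#'   (named list of branch tables), `modules` (named character vector gene
#'   -> module ID, `NA` for singletons), `deviations` (matrix of latent
#'   module deviations, modules x master branches), `rates` (per-gene base
#'   rates) and `config`.
#' @export
simulate_orthogroups <- function(cfg, master = NULL) {
  if (!inherits(cfg, "sim_config")) stop_domain("`cfg` must be a sim_config")
  if (is.null(master))
    master <- simulate_species_tree(cfg$n_species, cfg$seed)
  check_phylo(master)
  species <- sort(master$tip.label)
  a <- branch_table_core(master)        # master branch lengths by BranchID
  master_ids <- a$id
  a_len <- stats::setNames(a$length, master_ids)

  mod_names <- names(cfg$module_spec) %||% character(0)
  if (length(cfg$module_spec) && is.null(names(cfg$module_spec)))
    mod_names <- paste0("module", seq_along(cfg$module_spec))
  Z <- matrix(0, nrow = length(cfg$module_spec), ncol = length(master_ids),
              dimnames = list(mod_names, master_ids))
  for (m in seq_along(cfg$module_spec))
    Z[m, ] <- with_seed(child_seed(cfg$seed, m, salt = 1L),
                        stats::rnorm(length(master_ids)))
  gene2mod <- stats::setNames(rep(NA_character_, cfg$n_orthogroups),
                              cfg$gene_ids)
  for (m in seq_along(cfg$module_spec))
    gene2mod[cfg$module_spec[[m]]] <- mod_names[m]

  ctx <- master_context(master)
  rates <- stats::setNames(numeric(cfg$n_orthogroups), cfg$gene_ids)
  tables <- vector("list", cfg$n_orthogroups)
  names(tables) <- cfg$gene_ids
  for (g in seq_len(cfg$n_orthogroups)) {
    gid <- cfg$gene_ids[g]
    tables[[g]] <- with_seed(child_seed(cfg$seed, g, salt = 2L), {
      r_g <- stats::runif(1, cfg$rate_range[1], cfg$rate_range[2])
      rates[gid] <- r_g
      repeat {
        keep <- species[stats::runif(length(species)) >= cfg$dropout_prob]
        if (length(keep) >= cfg$min_species) break
      }
      dev <- if (!is.na(gene2mod[gid]))
        cfg$sigma_shared * Z[gene2mod[gid], ] else 0
      eps <- stats::rnorm(length(master_ids))
      b <- r_g * a_len * exp(dev + cfg$sigma_noise * eps)
      res_k <- restrict_ctx(ctx, keep)
      res_k <- res_k[!is.na(res_k$sub_id), , drop = FALSE]
      lens <- tapply(as.numeric(b[res_k$master_id]), res_k$sub_id, sum)
      structure(list(orthogroup_id = gid, species = sort(keep),
                     lengths = stats::setNames(as.numeric(lens),
                                               names(lens))),
                class = "branch_table")
    })
  }
  structure(list(master = master, tables = tables, modules = gene2mod,
                 deviations = Z, rates = rates, config = cfg),
            class = "erc_sim")
}

#' @export
print.erc_sim <- function(x, ...) {
  nmod <- sum(!is.na(x$modules))
  cat("Simulated ERC dataset: ", length(x$tables), " orthogroups on ",
      length(x$master$tip.label), " species (",
      length(x$config$module_spec), " planted module(s), ",
      nmod, " member genes)\n", sep = "")
  invisible(x)
}

#' Simulate genetic-screen records
#'
#' Per-gene egg-chamber records for the screen-statistics layer: migration
#' fractions drawn from a beta distribution whose mean is the control
#' baseline shifted by the gene's effect, and cluster-disassociation flags
#' drawn Bernoulli.  Deterministic given `seed` (one substream per gene).
#'
#' @param genes character vector of genotype IDs.
#' @param effect_map named list (or data.frame with rownames) giving, per
#'   gene, `c(migration_shift, disassociation_prob)`; genes absent from the
#'   map get `c(0, 0)`.
#' @param n_chambers egg chambers scored per gene (default 30).
#' @param seed RNG seed.
#' @param baseline_mean control-mean migration fraction (default 0.85:
#'   control clusters usually complete migration).
#' @param concentration beta concentration parameter `alpha + beta`
#'   (default 10).
#' @return data.frame with columns `genotype`, `chamber`,
#'   `migration_fraction` (in `[0, 1]`), `disassociated` (logical).
#' @export
simulate_screen <- function(genes, effect_map = list(), n_chambers = 30,
                            seed = 1, baseline_mean = 0.85,
                            concentration = 10) {
  if (n_chambers < 1) stop_domain("n_chambers must be >= 1")
  rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    eff <- effect_map[[genes[g]]] %||% c(0, 0)
    if (length(eff) != 2L || is.na(eff[1]) || is.na(eff[2]) ||
        eff[2] < 0 || eff[2] > 1)
      stop_domain("invalid effect for gene ", genes[g],
                  ": need c(migration_shift, disassociation_prob in [0,1])")
    rows[[g]] <- with_seed(child_seed(seed, g, salt = 3L), {
      mu <- min(max(baseline_mean + eff[1], 0.01), 0.99)
      f <- stats::rbeta(n_chambers, mu * concentration,
                        (1 - mu) * concentration)
      f <- pmin(pmax(f, 0), 1)
      d <- if (eff[2] == 0) rep(FALSE, n_chambers)
           else stats::rbinom(n_chambers, 1, eff[2]) == 1
      data.frame(genotype = genes[g], chamber = seq_len(n_chambers),
                 migration_fraction = f, disassociated = d,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the master tree (`master.nwk`), one Newick gene tree per line with
#' the orthogroup ID (`gene_trees.nwk`), and the ground-truth module map
#' (`modules.tsv`) under `dir`.
#'
#' @param sim an `"erc_sim"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(sim$master), file.path(dir, "master.nwk"))
  lines <- vapply(sim$tables, function(tb) {
    tr <- table_to_tree(tb, sim$master)
    paste0(tb$orthogroup_id, "\t", write_newick(tr))
  }, character(1))
  writeLines(lines, file.path(dir, "gene_trees.nwk"))
  df <- data.frame(gene = names(sim$modules),
                   module = ifelse(is.na(sim$modules), "", sim$modules),
                   rate = as.numeric(sim$rates), stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Rebuild a phylo gene tree from a branch table by grafting the table's
# lengths onto the master topology pruned to the table's species.
table_to_tree <- function(table, master) {
  tr <- prune(master, table$species)
  M <- edge_tip_matrix(tr)
  tips <- tr$tip.label
  ai <- which(tips == min(tips))[1L]
  ids <- character(nrow(M))
  for (e in seq_len(nrow(M))) {
    side <- M[e, ]
    if (side[ai]) side <- !side
    ids[e] <- branch_id_string(tips[side])
  }
  # a degree-2 root splits one unrooted branch across two edges: put the
  # full length on the first and zero on the second
  lens <- as.numeric(table$lengths[ids])
  dup <- duplicated(ids)
  lens[dup] <- 0
  tr$edge.length <- lens
  tr
}
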