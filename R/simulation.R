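#' @title Forest simulation
#' @description Trees live on a circular island and advance through a
#'   yearly cycle: light interception, stress sensing, secondary growth
#'   and maintenance, storm pruning, death, primary growth, and seed
#'   dispersal. A single session RNG stream drives every stochastic step
#'   in a documented order (storm sampling, then per-tree fracture draws,
#'   then per-tree growth placement and dispersal, in tree list order), so
#'   a fixed seed reproduces a run exactly.
#' @name forest-simulation
NULL

#' Initialise a forest
#'
#' Seedlings (single vertical segments of twig diameter, reserve
#' `initial_reserve * V0`) are sown at uniform random positions in the
#' island disc. Genomes are uniform random unless a pool is supplied, in
#' which case rows are drawn from it with replacement.
#'
#' @param n number of trees.
#' @param params a [wt_params()] object.
#' @param genomes optional genome pool (matrix, one genome per row).
#' @return A `wt_forest` object.
#' @export
init_forest <- function(n, params = wt_params(), genomes = NULL) {
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    r <- params$R * sqrt(runif(1))
    phi <- runif(1, 0, 2 * pi)
    g <- if (is.null(genomes)) random_genome() else
      genomes[sample.int(nrow(genomes), 1), ]
    tr <- new_tree(g, r * c(cos(phi), sin(phi)), params,
                   lineage = i, id = i)
    tr$decoded <- decode_genome(g)
    trees[[i]] <- tr
  }
  fo <- list(params = params, year = 0L, trees = trees,
             next_id = n + 1L, sky = sky_directions(params$n_sky_angles),
             storms = data.frame())
  class(fo) <- "wt_forest"
  fo
}

#' @export
print.wt_forest <- function(x, ...) {
  cat(sprintf("<forest> year %d: %d trees, %d species, island R = %g L\n",
              x$year, length(x$trees), count_species(x), x$params$R))
  invisible(x)
}

#' Number of species in a forest
#'
#' Species are identified with founding lineages: every tree inherits its
#' founder's lineage marker unchanged.
#'
#' @param forest a `wt_forest`.
#' @return Number of distinct lineages among living trees.
#' @export
count_species <- function(forest) {
  length(unique(vapply(forest$trees, function(tr) tr$lineage,
                       integer(1))))
}

#' Remove dead trees
#'
#' A tree dies when its age exceeds `max_age`, when it is older than
#' `juvenile_age` with fewer than `min_segments` segments, or when it has
#' lost its trunk.
#'
#' @param forest a `wt_forest`.
#' @return The forest without the dead trees.
#' @export
apply_death <- function(forest) {
  p <- forest$params
  keep <- vapply(forest$trees, function(tr) {
    tr$alive && tr$age <= p$max_age &&
      !(tr$age > p$juvenile_age && n_segments(tr) < p$min_segments)
  }, logical(1))
  forest$trees <- forest$trees[keep]
  forest
}

#' Advance a forest by one year
#'
#' Executes the yearly cycle in order: light, sensed stress, secondary
#' allocation and weakening, storm pruning, death, primary growth,
#' reproduction.
#'
#' @param forest a `wt_forest`.
#' @param record_budget keep the per-tree carbon budgets of the secondary
#'   phase in the result (used by the conservation tests).
#' @return The advanced forest; with `record_budget`, the budgets are in
#'   `forest$budgets`.
#' @export
yearly_cycle <- function(forest, record_budget = FALSE) {
  p <- forest$params
  nt <- length(forest$trees)
  forest$budgets <- NULL
  if (nt == 0) {
    forest$year <- forest$year + 1L
    return(forest)
  }
  # -- step 1: light interception, forest-wide
  fol <- lapply(forest$trees, foliage_centers, params = p)
  counts <- vapply(fol, function(f) length(f$twig), integer(1))
  light <- intercept_light(do.call(rbind, lapply(fol, `[[`, "center")),
                           p, forest$sky)
  off <- cumsum(c(0, counts))
  budgets <- if (record_budget) vector("list", nt)
  for (i in seq_len(nt)) {
    tr <- forest$trees[[i]]
    li <- numeric(n_segments(tr))
    li[fol[[i]]$twig] <- light[(off[i] + 1):off[i + 1]]
    tr$light <- li
    # -- step 2: sensed stress at reference wind
    tr <- max_stress(tr, p)
    # -- step 3: secondary growth and maintenance
    twig_ind <- matrix(as.numeric(is_twig(tr)), n_segments(tr), 1)
    n_above <- cpp_acc_to_root(tr$parent, twig_ind)[, 1]
    S <- secondary_policy(tr$sigma_rel, n_above, tr$decoded$secondary, p)
    al <- allocate_secondary(tr, production(tr$light[fol[[i]]$twig], p),
                             S, p)
    if (record_budget) budgets[[i]] <- al$budget
    forest$trees[[i]] <- al$tree
  }
  if (record_budget) forest$budgets <- budgets
  # -- step 4: storm pruning
  storm <- sample_wind(p)
  pruned <- 0
  for (i in seq_len(nt)) {
    st <- apply_storm_tree(forest$trees[[i]], storm$U, storm$azimuth, p)
    pruned <- pruned + st$volume
    forest$trees[[i]] <- st$tree
  }
  forest$storms <- rbind(forest$storms,
                         data.frame(year = forest$year + 1L, U = storm$U,
                                    azimuth = storm$azimuth,
                                    pruned_volume = pruned))
  # -- step 5: death
  forest <- apply_death(forest)
  # -- steps 6 and 7: primary growth and reproduction
  seeds <- list()
  for (i in seq_along(forest$trees)) {
    tr <- forest$trees[[i]]
    pol <- primary_policy(tr$reserve, sum(is_twig(tr)),
                          tr$decoded$primary, p)
    gr <- primary_growth(tr, pol, p)
    if (gr$n_seed > 0) {
      ends <- distal_ends(tr, p)
      for (tw in gr$seed_twigs)
        seeds[[length(seeds) + 1]] <- list(origin = ends[tw, ],
                                           genome = tr$genome,
                                           lineage = tr$lineage)
    }
    forest$trees[[i]] <- gr$tree
  }
  for (tr_i in seq_along(forest$trees))
    forest$trees[[tr_i]]$age <- forest$trees[[tr_i]]$age + 1L
  for (s in seeds) {
    pos <- disperse_seed(s$origin, p)
    if (is.null(pos)) next
    g <- mutate_genome(s$genome, p)
    tr <- new_tree(g, pos, p, lineage = s$lineage, id = forest$next_id)
    tr$decoded <- decode_genome(g)
    forest$trees[[length(forest$trees) + 1]] <- tr
    forest$next_id <- forest$next_id + 1L
  }
  forest$year <- forest$year + 1L
  forest
}

#' One summary row for a forest
#' @param forest a `wt_forest`.
#' @return A one-row `data.frame` with the year, tree and species counts,
#'   total biomass, effective number and biomass, and segment count.
#' @export
forest_summary_row <- function(forest) {
  B <- vapply(forest$trees, tree_volume, numeric(1),
              params = forest$params)
  eff <- if (length(B)) effective_numbers(B) else c(N_eff = NA, M_eff = NA)
  data.frame(year = forest$year, n_trees = length(forest$trees),
             n_species = count_species(forest), biomass = sum(B),
             N_eff = eff[[1]], M_eff = eff[[2]],
             n_segments = sum(vapply(forest$trees, n_segments,
                                     integer(1))))
}

#' Run a forest for a number of years
#'
#' @param forest a `wt_forest` (see [init_forest()]).
#' @param years number of yearly cycles.
#' @param snapshot_every write a snapshot every so many years (0 = none;
#'   requires `out_dir`).
#' @param out_dir optional directory for snapshots and the run logs.
#' @param verbose print a progress line every 50 years.
#' @return An object of class `wt_run`: list with the final `forest` and
#'   the per-year `summary` data frame (one row per simulated year).
#' @export
run_forest <- function(forest, years, snapshot_every = 0, out_dir = NULL,
                       verbose = FALSE) {
  if (years < 1) stop("years must be >= 1")
  if (snapshot_every > 0 && is.null(out_dir))
    stop("snapshots need an out_dir")
  rows <- vector("list", years)
  for (y in seq_len(years)) {
    forest <- yearly_cycle(forest)
    rows[[y]] <- forest_summary_row(forest)
    if (snapshot_every > 0 && y %% snapshot_every == 0)
      write_forest_snapshot(forest, file.path(
        out_dir, sprintf("snapshot_%06d", forest$year)))
    if (verbose && y %% 50 == 0)
      message(sprintf("year %d: %d trees", forest$year,
                      length(forest$trees)))
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(forest$storms, file.path(out_dir, "storms.csv"),
              row.names = FALSE)
  }
  out <- list(forest = forest, summary = summary)
  class(out) <- "wt_run"
  out
}

#' @export
print.wt_run <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("<run> %d years; final: %d trees, %d species, biomass %.3g L^3\n",
              n, x$summary$n_trees[n], x$summary$n_species[n],
              x$summary$biomass[n]))
  invisible(x)
}

#' Plot the self-thinning trajectory of a run
#' @param x a `wt_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wt_run <- function(x, ...) {
  ok <- x$summary$N_eff > 0 & x$summary$M_eff > 0
  graphics::plot(x$summary$N_eff[ok], x$summary$M_eff[ok], log = "xy",
                 xlab = "effective number of trees",
                 ylab = "effective biomass (L^3)", type = "l", ...)
  invisible(x)
}

#' Write a forest snapshot
#'
#' Two plain-text tables: `<prefix>_segments.csv` (the segment schema of
#' [tree_to_table()] plus a `tree` column) and `<prefix>_trees.csv`
#' (tree id, lineage, age, reserve, position and the 34 genes).
#'
#' @param forest a `wt_forest`.
#' @param prefix file path prefix.
#' @return `prefix`, invisibly.
#' @export
write_forest_snapshot <- function(forest, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  segs <- do.call(rbind, lapply(forest$trees, function(tr)
    cbind(tree = tr$id, tree_to_table(tr))))
  meta <- do.call(rbind, lapply(forest$trees, function(tr) {
    df <- data.frame(tree = tr$id, lineage = tr$lineage, age = tr$age,
                     reserve = tr$reserve, x = tr$pos[1], y = tr$pos[2])
    df[paste0("g", seq_along(tr$genome))] <- as.list(tr$genome)
    df
  }))
  write.csv(segs, paste0(prefix, "_segments.csv"), row.names = FALSE)
  write.csv(meta, paste0(prefix, "_trees.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Single-elimination tournament of forests
#'
#' Round 1 simulates `n_forests` independent forests sown with random
#' genomes; after each round the genomes of the `n_winners` oldest living
#' trees of every forest are collected, and each next-round forest is
#' sown from the merged winner pools of two previous-round forests, until
#' a single final forest remains.
#'
#' @param params a [wt_params()] object.
#' @param n_forests forests in round 1 (a power of 2).
#' @param n_init trees sown per forest.
#' @param years simulated years per round (scalar, or one value per
#'   round).
#' @param n_winners genomes collected per forest and round.
#' @param out_dir optional directory for `winners_round<k>.txt` pools.
#' @return List with `pools` (per round, a list of winner-genome
#'   matrices) and `final` (the winner pool of the final forest).
#' @export
tournament <- function(params = wt_params(), n_forests = 4, n_init = 100,
                       years = 25, n_winners = 20, out_dir = NULL) {
  if (bitwAnd(n_forests, n_forests - 1L) != 0)
    stop("n_forests must be a power of 2")
  n_rounds <- as.integer(log2(n_forests)) + 1L
  years <- rep_len(years, n_rounds)
  pools <- vector("list", n_rounds)
  prev <- NULL
  for (r in seq_len(n_rounds)) {
    nf <- n_forests %/% 2^(r - 1)
    pools[[r]] <- vector("list", nf)
    for (f in seq_len(nf)) {
      pool <- if (r == 1) NULL else rbind(prev[[2 * f - 1]], prev[[2 * f]])
      fo <- init_forest(n_init, params, genomes = pool)
      fo <- run_forest(fo, years[r])$forest
      pools[[r]][[f]] <- collect_winners(fo, n_winners)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_genomes(pools[[r]][[f]], file.path(
          out_dir, sprintf("winners_round%d_forest%d.txt", r, f)))
      }
    }
    prev <- pools[[r]]
  }
  list(pools = pools, final = pools[[n_rounds]][[1]])
}

#' Winner genomes of a forest
#'
#' The genomes of the `n` oldest living trees, ties broken by tree id.
#'
#' @param forest a `wt_forest`.
#' @param n number of winners.
#' @return Matrix with one genome per row.
#' @export
collect_winners <- function(forest, n) {
  if (length(forest$trees) == 0) stop("forest has no living trees")
  ages <- vapply(forest$trees, function(tr) tr$age, integer(1))
  ids <- vapply(forest$trees, function(tr) tr$id, integer(1))
  if (length(ages) < n) {
    warning("fewer living trees than requested winners; taking all")
    n <- length(ages)
  }
  o <- order(-ages, ids)[seq_len(n)]
  do.call(rbind, lapply(forest$trees[o], function(tr) tr$genome))
}
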