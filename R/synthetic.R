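# Seeded generator for toy pathway databases and multi-plant community
# profiles with planted ground truth. The study design emulated: several
# treatment plants, two compartments (activated sludge AS, incoming
# wastewater IW), monthly sampling dates, technical replicates taken
# minutes apart. Counts follow a Dirichlet-multinomial: a per-plant,
# per-compartment mean composition; monthly redraws at a
# compartment-specific concentration (AS temporally tighter than IW);
# replicates as high-concentration redraws of the month's composition.

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {
    # all shapes zero or numerically underflowed; fall back to point mass
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Simulation design for the synthetic study
#'
#' Defaults emulate the field design: 3 plants, AS and IW compartments, 3
#' monthly dates, duplicate sampling, a few thousand reads per sample.
#' Temporal Dirichlet concentrations are compartment-specific
#' (`conc_time`), chosen so that replicate distances sit near 0.02, AS
#' month-to-month distances in the few-percent range and IW ones several
#' times larger, matching the magnitudes such studies report; the planted
#' effect multiplies a designated set of taxa in the last plant.
#'
#' @param seed Mandatory integer seed; every downstream draw derives from
#'   it.
#' @param n_taxa Number of genera in the toy taxonomy.
#' @param n_pathways Number of random pathways (plus one planted target).
#' @param stage_range,p_parallel,branch_range,branch_len_range Shape of the
#'   random series-parallel pathways: serial stage count range, probability
#'   a stage is a parallel block, branch count range, branch length range.
#' @param orgs_per_reaction Range of capable organisms per reaction.
#' @param n_plants,compartments,n_dates,n_replicates Study layout.
#' @param reads_per_sample Multinomial read depth.
#' @param base_meanlog,base_sdlog Log-normal law of the base composition.
#' @param plant_sdlog Log-sd of the per-plant tilt on taxon abundances
#'   (shared by both compartments of a plant).
#' @param compartment_sdlog Log-sd of a compartment-specific composition
#'   tilt; the default 0 makes AS and IW differ only through their temporal
#'   dispersion, which is what the stability test probes.
#' @param conc_time Named Dirichlet concentrations (`AS`, `IW`) for monthly
#'   redraws; larger = temporally tighter.
#' @param conc_replicate Concentration for replicate redraws.
#' @param effect Multiplier applied to the target taxa in the last plant
#'   (1 = no planted effect).
#' @param n_target_taxa Number of planted target taxa.
#' @param cfu_mean Named mean CFU/mL per compartment; noised log-normally
#'   (`cfu_sdlog`).
#' @param cfu_sdlog Log-sd of CFU noise.
#' @return A `sim_design` list, validated.
#' @export
sim_design <- function(seed,
                       n_taxa = 40L,
                       n_pathways = 20L,
                       stage_range = c(2L, 5L),
                       p_parallel = 0.25,
                       branch_range = c(2L, 3L),
                       branch_len_range = c(1L, 2L),
                       orgs_per_reaction = c(2L, 5L),
                       n_plants = 3L,
                       compartments = c("AS", "IW"),
                       n_dates = 3L,
                       n_replicates = 2L,
                       reads_per_sample = 3000L,
                       base_meanlog = 0,
                       base_sdlog = 1.5,
                       plant_sdlog = 0.25,
                       compartment_sdlog = 0,
                       conc_time = c(AS = 150, IW = 25),
                       conc_replicate = 200,
                       effect = 4,
                       n_target_taxa = 3L,
                       cfu_mean = c(AS = 1.2e7, IW = 1.5e6),
                       cfu_sdlog = 0.15) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  d <- list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
            n_pathways = as.integer(n_pathways),
            stage_range = as.integer(stage_range),
            p_parallel = p_parallel,
            branch_range = as.integer(branch_range),
            branch_len_range = as.integer(branch_len_range),
            orgs_per_reaction = as.integer(orgs_per_reaction),
            n_plants = as.integer(n_plants),
            compartments = compartments,
            n_dates = as.integer(n_dates),
            n_replicates = as.integer(n_replicates),
            reads_per_sample = as.integer(reads_per_sample),
            base_meanlog = base_meanlog, base_sdlog = base_sdlog,
            plant_sdlog = plant_sdlog, compartment_sdlog = compartment_sdlog,
            conc_time = conc_time,
            conc_replicate = conc_replicate, effect = effect,
            n_target_taxa = as.integer(n_target_taxa),
            cfu_mean = cfu_mean, cfu_sdlog = cfu_sdlog)
  stopifnot(d$n_taxa > 0, d$n_pathways > 0, d$n_plants > 0, d$n_dates > 0,
            d$n_replicates > 0, d$reads_per_sample > 0,
            all(d$stage_range >= 1L), d$stage_range[1] <= d$stage_range[2],
            d$p_parallel >= 0, d$p_parallel <= 1,
            all(d$branch_range >= 1L), all(d$branch_len_range >= 1L),
            all(d$conc_time > 0), d$conc_replicate > 0, d$effect > 0,
            d$n_target_taxa >= 1L, d$n_target_taxa <= d$n_taxa,
            all(d$compartments %in% c("AS", "IW")))
  if (!all(d$compartments %in% names(d$conc_time))) {
    abort("conc_time must name every compartment in the design")
  }
  structure(d, class = "sim_design")
}

# deterministic toy taxonomy: genera spread over a handful of phyla
toy_taxonomy <- function(design) {
  n <- design$n_taxa
  n_phyla <- max(1L, min(5L, n %/% 8L + 1L))
  phyla <- sprintf("Phy%02d", seq_len(n_phyla))
  phy_of <- phyla[(seq_len(n) - 1L) %% n_phyla + 1L]
  sprintf("domain:Bacteria;phylum:%s;genus:Gen%03d", phy_of, seq_len(n))
}

#' Generate a toy pathway database with a planted target pathway
#'
#' Random series-parallel pathways over a toy genus-level taxonomy. One
#' extra pathway (`PWY-TARGET`) draws its capable organisms exclusively
#' from the designated target taxa, and those taxa are excluded from every
#' other reaction, so a planted abundance shift on them moves exactly one
#' pathway's score. Some capable organisms are emitted at species level
#' below their genus to exercise ancestor matching. Deterministic given the
#' design seed.
#'
#' @param design A [sim_design()].
#' @return List with `db` (a `pathway_db`) and `truth` (target pathway id,
#'   target taxa, effect multiplier per plant, grouping variable).
#' @export
make_toy_db <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_local_seed(design$seed, {
    taxa <- toy_taxonomy(design)
    target_taxa <- sample(taxa, design$n_target_taxa)
    free_taxa <- setdiff(taxa, target_taxa)
    if (!length(free_taxa)) abort("infeasible design: no non-target taxa")

    rxn_counter <- 0L
    reactions <- list()
    new_reaction <- function(pool) {
      rxn_counter <<- rxn_counter + 1L
      id <- sprintf("RXN-%04d", rxn_counter)
      k <- sample(seq(design$orgs_per_reaction[1],
                      design$orgs_per_reaction[2]), 1L)
      orgs <- sample(pool, min(k, length(pool)))
      # a third of the organisms are species below the sampled genus
      sp <- stats::runif(length(orgs)) < 1 / 3
      orgs[sp] <- paste0(orgs[sp], ";species:",
                         lineage_taxon_at(orgs[sp], "genus"), " sp")
      reactions[[id]] <<- list(name = id, organisms = orgs)
      id
    }
    random_stages <- function(pool) {
      n_stages <- sample(seq(design$stage_range[1], design$stage_range[2]),
                         1L)
      lapply(seq_len(n_stages), function(i) {
        if (stats::runif(1) < design$p_parallel) {
          nb <- sample(seq(design$branch_range[1], design$branch_range[2]),
                       1L)
          branches <- lapply(seq_len(nb), function(b) {
            len <- sample(seq(design$branch_len_range[1],
                              design$branch_len_range[2]), 1L)
            lapply(seq_len(len), function(j) stage_reaction(
              new_reaction(pool)))
          })
          list(parallel = branches)
        } else {
          stage_reaction(new_reaction(pool))
        }
      })
    }

    pathways <- list()
    for (p in seq_len(design$n_pathways)) {
      pid <- sprintf("PWY-%04d", p)
      pathways[[pid]] <- list(
        name = paste0("random pathway ", p),
        keywords = if (p %% 2L == 0L) "degradation" else character(),
        stages = random_stages(free_taxa))
    }
    pathways[["PWY-TARGET"]] <- list(
      name = "planted target degradation pathway",
      keywords = "degradation",
      stages = random_stages(target_taxa))

    db <- pathway_db(reactions = reactions, pathways = pathways,
                     source_note = paste0("synthetic toy database (seed ",
                                          design$seed, ")"))
    plants <- sprintf("P%d", seq_len(design$n_plants))
    truth <- list(
      target_pathway = "PWY-TARGET",
      target_taxa = target_taxa,
      effect = setNames(c(rep(1, design$n_plants - 1L), design$effect),
                        plants),
      group_by = "plant",
      taxa = taxa)
    list(db = db, truth = truth)
  })
}

#' Simulate multi-plant community profiles with planted truth
#'
#' Per (plant, compartment): a mean composition = one shared log-normal
#' base (planted target taxa pinned to its upper quartile so they behave
#' like the abundant families real plant contrasts act on), tilted per
#' compartment and per plant, with the planted effect multiplied onto the
#' target taxa and renormalised. Per date a Dirichlet redraw at the compartment's
#' temporal concentration; per replicate a high-concentration redraw of the
#' date composition; reads multinomial at the design depth. All taxa appear
#' in every sample (zero counts included) so lineage universes align.
#' Deterministic given the design seed.
#'
#' @param design A [sim_design()].
#' @param truth Optional truth from [make_toy_db()]; when absent, no effect
#'   is planted (taxonomy is regenerated deterministically).
#' @return A non-normalized profiles tibble covering every plant,
#'   compartment, date and replicate of the design.
#' @export
simulate_profiles <- function(design, truth = NULL) {
  stopifnot(inherits(design, "sim_design"))
  taxa <- if (!is.null(truth)) truth$taxa else
    with_local_seed(design$seed, toy_taxonomy(design))
  n <- length(taxa)
  plants <- sprintf("P%d", seq_len(design$n_plants))
  dates <- seq(as.Date("2013-10-15"), by = "month",
               length.out = design$n_dates)
  effect <- if (!is.null(truth)) truth$effect else
    setNames(rep(1, design$n_plants), plants)
  target <- if (!is.null(truth)) match(truth$target_taxa, taxa) else
    integer()

  with_local_seed(design$seed + 1L, {
    base <- rlnorm(n, design$base_meanlog, design$base_sdlog)
    if (length(target)) {
      # planted taxa are mid-to-high abundance organisms, like the abundant
      # families whose shifts drive pathway differences in real plants
      base[target] <- stats::quantile(base, 0.75)
    }
    comp_tilt <- lapply(setNames(design$compartments, design$compartments),
                        function(cc) exp(rnorm(n, 0,
                                               design$compartment_sdlog)))
    plant_tilt <- lapply(setNames(plants, plants),
                         function(pl) exp(rnorm(n, 0, design$plant_sdlog)))
    rows <- list()
    for (pl in plants) {
      for (cc in design$compartments) {
        mean_comp <- base * comp_tilt[[cc]] * plant_tilt[[pl]]
        if (length(target) && effect[[pl]] != 1) {
          mean_comp[target] <- mean_comp[target] * effect[[pl]]
        }
        mean_comp <- mean_comp / sum(mean_comp)
        for (di in seq_along(dates)) {
          theta_date <- rdirichlet1(design$conc_time[[cc]] * mean_comp)
          for (rep_i in seq_len(design$n_replicates)) {
            theta <- rdirichlet1(design$conc_replicate * theta_date)
            counts <- as.numeric(rmultinom(1L, design$reads_per_sample,
                                           theta))
            cfu <- rlnorm(1L, log(design$cfu_mean[[cc]]), design$cfu_sdlog)
            rows[[length(rows) + 1L]] <- tibble(
              sample_id = sprintf("%s_%s_%s_r%d", pl, cc,
                                  format(dates[di], "%Y-%m"), rep_i),
              plant = pl, compartment = cc, date = dates[di],
              replicate = rep_i, cfu_per_ml = cfu,
              lineage = taxa, count = counts, normalized = FALSE)
          }
        }
      }
    }
    out <- bind_rows(rows) %>% arrange(.data$sample_id, .data$lineage)
    check_profiles(out)
    out
  })
}
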