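# The availability score S_A of a pathway in a community: each serial stage
# i has capacity n_i = total reads of profile taxa able to perform it, and
# S_A = 1 / sum_i(1 / n_i) (harmonic composition; any empty stage makes the
# pathway unavailable, S_A = 0). A parallel stage's capacity is the sum of
# its branch scores, each branch scored by the same rule recursively --
# alternative routes add capacity the way additional organisms do.

# deepest profile lineage that is an ancestor of (or equal to) `organism`,
# NA_character_ when none is; depth = canonical rank of the lineage's
# deepest entry (nchar breaks ties)
match_organism <- function(organism, profile_lineages) {
  hits <- profile_lineages[lineage_is_ancestor(profile_lineages, organism)]
  if (!length(hits)) return(NA_character_)
  depth <- match(lineage_deepest_rank(hits), LINEAGE_RANKS)
  hits[[order(depth, nchar(hits), decreasing = TRUE)[[1]]]]
}

# per-sample lineage -> count lookup tables
sample_count_tables <- function(profiles) {
  samples <- sort(unique(profiles$sample_id))
  lapply(setNames(samples, samples), function(s) {
    sub <- profiles[profiles$sample_id == s, ]
    setNames(sub$count, sub$lineage)
  })
}

# capacities of every reaction in every sample: matrix reactions x samples.
# Samples sharing a lineage set share one organism-matching pass.
reaction_capacity_matrix <- function(db, profiles, dedup = TRUE) {
  tabs <- sample_count_tables(profiles)
  rids <- names(db$reactions)
  out <- matrix(0, nrow = length(rids), ncol = length(tabs),
                dimnames = list(rids, names(tabs)))
  sig <- vapply(tabs, function(tb) paste(sort(names(tb)), collapse = "\r"),
                character(1))
  for (s in unique(sig)) {
    cols <- which(sig == s)
    lins <- names(tabs[[cols[[1]]]])
    for (rid in rids) {
      orgs <- db$reactions[[rid]]$organisms
      if (!length(orgs)) next
      matched <- vapply(orgs, match_organism, character(1),
                        profile_lineages = lins)
      matched <- matched[!is.na(matched)]
      if (dedup) matched <- unique(matched)
      if (!length(matched)) next
      for (j in cols) {
        out[rid, j] <- sum(tabs[[j]][matched])
      }
    }
  }
  out
}

#' Capacity of one reaction in each sample, with the matching taxa
#'
#' A reaction's capacity in a community is the summed read count of the
#' profile taxa matched to its capable organisms. Each capable organism is
#' matched to the deepest profile lineage that is an ancestor of it or equal
#' to it (a species-level organism matches the profile's genus entry when
#' classification stops at genus). Ancestry is tested on rank entries, so a
#' profile chain spelling out every rank still matches a database organism
#' that records only genus and species; the rare genus-name homonym across
#' higher clades would match generously. By default a matched profile taxon
#' contributes once per reaction even when several capable organisms
#' collapse onto it, so congeneric database species do not double-count the
#' genus reads.
#'
#' @param profiles A profiles tibble.
#' @param db A `pathway_db`.
#' @param reaction_id Reaction identifier present in `db`.
#' @param dedup Count each matched profile taxon once per reaction
#'   (default) or once per capable organism.
#' @return Tibble with one row per sample and matched taxon: `sample_id`,
#'   `reaction_id`, `lineage`, `count`, and the per-sample `total`.
#' @export
reaction_capacity <- function(profiles, db, reaction_id, dedup = TRUE) {
  if (is.null(db$reactions[[reaction_id]])) {
    abort(paste0("unknown reaction '", reaction_id, "'"))
  }
  orgs <- db$reactions[[reaction_id]]$organisms
  tabs <- sample_count_tables(profiles)
  rows <- purrr::map_dfr(names(tabs), function(s) {
    tb <- tabs[[s]]
    matched <- vapply(orgs, match_organism, character(1),
                      profile_lineages = names(tb))
    matched <- matched[!is.na(matched)]
    if (dedup) matched <- unique(matched)
    if (!length(matched)) {
      return(tibble(sample_id = s, reaction_id = reaction_id,
                    lineage = character(), count = numeric()))
    }
    tibble(sample_id = s, reaction_id = reaction_id,
           lineage = unname(matched), count = unname(tb[matched]))
  })
  totals <- tibble(sample_id = names(tabs)) %>%
    left_join(rows %>% group_by(.data$sample_id) %>%
                summarise(total = sum(.data$count), .groups = "drop"),
              by = "sample_id") %>%
    mutate(total = ifelse(is.na(.data$total), 0, .data$total))
  rows %>%
    dplyr::right_join(totals, by = "sample_id") %>%
    mutate(reaction_id = reaction_id) %>%
    arrange(.data$sample_id, .data$lineage)
}

# vector over samples of the capacity of one stage, given the reaction
# capacity matrix
stage_capacity_vec <- function(stage, capmat) {
  if (!is.null(stage$reaction)) {
    if (!stage$reaction %in% rownames(capmat)) {
      abort(paste0("dangling reaction ref '", stage$reaction, "'"))
    }
    return(capmat[stage$reaction, ])
  }
  Reduce(`+`, lapply(stage$parallel, score_stages_vec, capmat = capmat))
}

# serial harmonic composition over a stage list, vectorised over samples
score_stages_vec <- function(stages, capmat) {
  caps <- lapply(stages, stage_capacity_vec, capmat = capmat)
  inv <- Reduce(`+`, lapply(caps, function(v) ifelse(v > 0, 1 / v, Inf)))
  ifelse(is.finite(inv), 1 / inv, 0)
}

#' Capacity of a single stage in each sample
#'
#' A reaction stage passes through its reaction's capacity; a parallel
#' stage sums the availability scores of its branches, which then enter the
#' serial composition like organism counts.
#'
#' @param profiles A profiles tibble.
#' @param db A `pathway_db`.
#' @param stage A stage node ([stage_reaction()] / [stage_parallel()]).
#' @param dedup See [reaction_capacity()].
#' @return Named numeric vector, one entry per sample.
#' @export
stage_capacity <- function(profiles, db, stage, dedup = TRUE) {
  capmat <- reaction_capacity_matrix(db, profiles, dedup = dedup)
  stage_capacity_vec(stage, capmat)
}

#' Availability score of one pathway in each sample
#'
#' With serial stage capacities `n_i`, the score is
#' `S_A = 1 / sum_i (1 / n_i)`; it is 0 as soon as any serial stage has no
#' capable taxon, and equals the single stage's capacity for one-stage
#' pathways. Parallel blocks are scored recursively and their branch scores
#' summed into the enclosing stage's capacity. Scores are relative
#' estimates for comparing the same pathway across communities, not
#' absolute rates.
#'
#' @param profiles A profiles tibble (normalized counts recommended so
#'   scores are comparable across sequencing depths).
#' @param db A `pathway_db`.
#' @param pathway_id Pathway identifier present in `db`.
#' @param dedup See [reaction_capacity()].
#' @return Named numeric vector of scores, one entry per sample.
#' @export
score_pathway <- function(profiles, db, pathway_id, dedup = TRUE) {
  pw <- db$pathways[[pathway_id]]
  if (is.null(pw)) abort(paste0("unknown pathway '", pathway_id, "'"))
  capmat <- reaction_capacity_matrix(db, profiles, dedup = dedup)
  score_stages_vec(pw$stages, capmat)
}

#' Availability scores for every pathway in every sample
#'
#' @param profiles A profiles tibble.
#' @param db A `pathway_db`.
#' @param dedup See [reaction_capacity()].
#' @return A long tibble of class `avail_tbl` with columns `pathway_id`,
#'   `sample_id`, `s_a`, rows ordered by pathway then sample. Attributes
#'   record the database `source_note`, the dedup setting and whether the
#'   input counts were normalized.
#' @seealso [avail_wide()], [differential_pathways()]
#' @export
score_matrix <- function(profiles, db, dedup = TRUE) {
  check_profiles(profiles)
  if (!length(unique(profiles$sample_id))) abort("no samples in profiles")
  capmat <- reaction_capacity_matrix(db, profiles, dedup = dedup)
  pids <- sort(names(db$pathways))
  samples <- colnames(capmat)
  rows <- purrr::map_dfr(pids, function(pid) {
    s <- score_stages_vec(db$pathways[[pid]]$stages, capmat)
    tibble(pathway_id = pid, sample_id = samples, s_a = unname(s))
  })
  structure(rows,
            class = c("avail_tbl", class(rows)),
            source_note = db$source_note,
            dedup = dedup,
            normalized = all(profiles$normalized))
}

#' Pivot an availability table to a pathways-by-samples matrix
#'
#' @param avail An `avail_tbl` from [score_matrix()].
#' @param transform `"none"` or `"sqrt"` (display convention for heatmaps).
#' @return Numeric matrix, pathways (rows) by samples (columns).
#' @export
avail_wide <- function(avail, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  pids <- sort(unique(avail$pathway_id))
  sids <- sort(unique(avail$sample_id))
  mat <- matrix(0, length(pids), length(sids), dimnames = list(pids, sids))
  mat[cbind(match(avail$pathway_id, pids), match(avail$sample_id, sids))] <-
    avail$s_a
  if (transform == "sqrt") sqrt(mat) else mat
}

#' Heatmap of square-root availability scores
#'
#' @param object An `avail_tbl`.
#' @param ... Unused.
#' @return A ggplot object: pathways by samples, fill = sqrt(S_A).
#' @export
autoplot.avail_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id, y = .data$pathway_id,
                               fill = sqrt(.data$s_a))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(sqrt(S[A]))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
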