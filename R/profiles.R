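# Taxonomic profiles live in one long tibble: one row per sample x lineage,
# with per-sample metadata repeated on each row. Columns:
#   sample_id, plant, compartment ("AS"/"IW"), date (Date), replicate (int),
#   cfu_per_ml (dbl, may be NA), lineage (canonical string), count (dbl),
#   normalized (lgl, constant within a sample).

PROFILE_COLS <- c("sample_id", "plant", "compartment", "date", "replicate",
                  "cfu_per_ml", "lineage", "count", "normalized")

#' Read taxonomic profiles from a classifier export TSV
#'
#' Expected columns: `sample_id`, `plant`, `compartment` (`AS` or `IW`),
#' `date` (ISO), `replicate`, `lineage` (semicolon-separated `rank:name`
#' pairs), `count`, and optionally `cfu_per_ml`. Rows repeating a lineage
#' within a sample are aggregated by summing counts.
#'
#' @param file Path to a tab-separated file.
#' @return A profiles tibble (see package overview); `normalized` is `FALSE`.
#' @export
read_profiles <- function(file) {
  raw <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("sample_id", "plant", "compartment", "date", "replicate",
            "lineage", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("profile TSV is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"cfu_per_ml" %in% names(raw)) raw$cfu_per_ml <- NA_real_
  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$count[i]) || raw$count[i] < 0) {
      abort(paste0("row ", i, ": negative or missing count"))
    }
    raw$lineage[i] <- tryCatch(parse_lineage(raw$lineage[i]),
                               error = function(e) {
                                 abort(paste0("row ", i, ": ",
                                              conditionMessage(e)))
                               })
    if (!raw$compartment[i] %in% c("AS", "IW")) {
      abort(paste0("row ", i, ": compartment must be 'AS' or 'IW', got '",
                   raw$compartment[i], "'"))
    }
  }
  out <- as_tibble(raw) %>%
    mutate(date = as.Date(.data$date),
           replicate = as.integer(.data$replicate),
           count = as.numeric(.data$count),
           cfu_per_ml = as.numeric(.data$cfu_per_ml)) %>%
    group_by(.data$sample_id, .data$plant, .data$compartment, .data$date,
             .data$replicate, .data$cfu_per_ml, .data$lineage) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(normalized = FALSE) %>%
    select(all_of(PROFILE_COLS)) %>%
    arrange(.data$sample_id, .data$lineage)
  check_profiles(out)
  out
}

# shared structural checks; errors on violation
check_profiles <- function(profiles, need_normalized = NA) {
  miss <- setdiff(PROFILE_COLS, names(profiles))
  if (length(miss)) {
    abort(paste0("profiles tibble is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(profiles$count < 0)) abort("negative counts in profiles")
  meta <- profile_meta(profiles)
  if (anyDuplicated(meta$sample_id)) {
    abort("inconsistent per-sample metadata (sample_id maps to >1 row)")
  }
  key <- paste(meta$plant, meta$compartment, meta$date, meta$replicate)
  if (anyDuplicated(key)) {
    abort("duplicate (plant, compartment, date, replicate) combination")
  }
  if (!is.na(need_normalized)) {
    if (need_normalized && !all(profiles$normalized)) {
      abort("profiles must be normalized for this operation")
    }
    if (!need_normalized && any(profiles$normalized)) {
      abort("profiles must not be normalized for this operation")
    }
  }
  invisible(profiles)
}

#' Write a profiles tibble back to the classifier-export TSV layout
#'
#' @param profiles A profiles tibble.
#' @param file Output path.
#' @return `profiles`, invisibly. [read_profiles()] on the written file
#'   restores the same content (the `normalized` flag is not persisted, so
#'   write raw counts).
#' @export
write_profiles <- function(profiles, file) {
  check_profiles(profiles)
  out <- profiles %>%
    select(all_of(setdiff(PROFILE_COLS, "normalized"))) %>%
    arrange(.data$sample_id, .data$lineage)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(profiles)
}

#' Per-sample metadata of a profiles tibble
#'
#' @param profiles A profiles tibble.
#' @return One row per sample: sample_id, plant, compartment, date,
#'   replicate, cfu_per_ml, normalized.
#' @export
profile_meta <- function(profiles) {
  profiles %>%
    select(all_of(setdiff(PROFILE_COLS, c("lineage", "count")))) %>%
    distinct() %>%
    arrange(.data$sample_id)
}

#' Read a 16S gene copy-number table
#'
#' @param file TSV with columns `lineage` and `copies` (mean 16S rRNA gene
#'   copies per genome, all at least 1).
#' @return Tibble with canonical `lineage` and numeric `copies`.
#' @export
read_copy_numbers <- function(file) {
  raw <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("lineage", "copies") %in% names(raw))) {
    abort("copy-number TSV needs columns 'lineage' and 'copies'")
  }
  tb <- tibble(lineage = parse_lineage(raw$lineage),
               copies = as.numeric(raw$copies))
  if (any(is.na(tb$copies)) || any(tb$copies < 1)) {
    abort("copy numbers must all be >= 1")
  }
  tb
}

#' Divide counts by 16S gene copy numbers
#'
#' Multi-copy genomes are over-represented in amplicon read counts; dividing
#' each taxon's reads by its mean gene copy number corrects this before
#' proportions are computed. Lookup falls back to the nearest ancestor
#' present in the table, and to 1 when no ancestor is listed.
#'
#' @param profiles A non-normalized profiles tibble.
#' @param copy_numbers Tibble with columns `lineage`, `copies`
#'   (see [read_copy_numbers()]).
#' @return The profiles tibble with adjusted (possibly fractional) counts.
#' @export
adjust_copy_numbers <- function(profiles, copy_numbers) {
  check_profiles(profiles, need_normalized = FALSE)
  cn <- setNames(copy_numbers$copies, copy_numbers$lineage)
  lookup <- vapply(unique(profiles$lineage), function(lin) {
    for (pre in rev(lineage_prefixes(lin))) {
      if (!is.na(cn[pre])) return(unname(cn[pre]))
    }
    1
  }, numeric(1))
  profiles %>%
    mutate(count = .data$count / unname(lookup[.data$lineage]))
}

#' Convert counts to within-sample proportions
#'
#' Each sample's counts are divided by that sample's total. Truncated
#' lineages (reads unclassified below some rank) count toward the total like
#' any other entry, so proportions are over the deepest classification of
#' every read.
#'
#' @param profiles A profiles tibble; normalizing an already-normalized
#'   tibble is the identity.
#' @return The profiles tibble with `count` summing to 1 per sample and
#'   `normalized = TRUE`.
#' @export
normalize_profiles <- function(profiles) {
  check_profiles(profiles)
  totals <- profiles %>%
    group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total <= 0]
  if (length(zero)) {
    abort(paste0("cannot normalize all-zero sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  profiles %>%
    left_join(totals, by = "sample_id") %>%
    mutate(count = .data$count / .data$total, normalized = TRUE) %>%
    select(-"total")
}

#' Merge technical replicates taken at the same location and time
#'
#' Within each (plant, compartment, date) group, read counts are summed
#' lineage-wise, the replicate id is set to 0 and `cfu_per_ml` is the mean
#' of the available replicate values.
#'
#' @param profiles A non-normalized profiles tibble.
#' @return Profiles tibble with one sample per (plant, compartment, date);
#'   sample ids become `"<plant>_<compartment>_<date>"`.
#' @export
merge_replicates <- function(profiles) {
  check_profiles(profiles, need_normalized = FALSE)
  meta <- profile_meta(profiles)
  cfu <- meta %>%
    group_by(.data$plant, .data$compartment, .data$date) %>%
    summarise(cfu_per_ml = if (all(is.na(.data$cfu_per_ml))) NA_real_ else
      mean(.data$cfu_per_ml, na.rm = TRUE), .groups = "drop")
  profiles %>%
    group_by(.data$plant, .data$compartment, .data$date, .data$lineage) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    left_join(cfu, by = c("plant", "compartment", "date")) %>%
    mutate(sample_id = paste(.data$plant, .data$compartment, .data$date,
                             sep = "_"),
           replicate = 0L, normalized = FALSE) %>%
    select(all_of(PROFILE_COLS)) %>%
    arrange(.data$sample_id, .data$lineage)
}

#' Universe of (rank, taxon) entries across a study set
#'
#' Every taxon at every rank touched by any lineage of any sample, in a
#' deterministic order (rank-major in canonical rank order, then by name).
#'
#' @param profiles A profiles tibble.
#' @return Tibble with columns `rank`, `taxon` and a `key`
#'   (`"rank:taxon"`) used to label vector entries.
#' @export
taxon_universe <- function(profiles) {
  keys <- unique(unlist(lapply(unique(profiles$lineage), lineage_prefixes)))
  entries <- unique(unlist(strsplit(keys, ";", fixed = TRUE)))
  rk <- sub(":.*$", "", entries)
  nm <- sub("^[^:]*:", "", entries)
  ord <- order(match(rk, LINEAGE_RANKS), nm)
  tibble(rank = rk[ord], taxon = nm[ord],
         key = paste0(rk[ord], ":", nm[ord]))
}

#' All-rank abundance vectors for a set of samples
#'
#' Each read contributes to every taxon on its classification path: a read
#' classified to family adds to that family, its order, class, phylum and
#' domain, but to no genus. The result concatenates every rank, which is
#' what the beta-diversity distance and PCA operate on.
#'
#' @param profiles A normalized profiles tibble.
#' @param universe Ordered universe from [taxon_universe()]; defaults to the
#'   universe of `profiles` itself. Pass the study-wide universe when
#'   vectorising subsets.
#' @return Numeric matrix, samples (rows, named by sample_id) by universe
#'   entries (columns, named by `key`).
#' @export
all_rank_matrix <- function(profiles, universe = taxon_universe(profiles)) {
  check_profiles(profiles, need_normalized = TRUE)
  if (!nrow(universe)) abort("empty taxon universe")
  samples <- sort(unique(profiles$sample_id))
  mat <- matrix(0, nrow = length(samples), ncol = nrow(universe),
                dimnames = list(samples, universe$key))
  # map each distinct lineage to the universe entries it passes through
  lin_entries <- lapply(unique(profiles$lineage), function(lin) {
    entries <- strsplit(lin, ";", fixed = TRUE)[[1]]
    idx <- match(entries, universe$key)
    idx[!is.na(idx)]
  })
  names(lin_entries) <- unique(profiles$lineage)
  for (i in seq_len(nrow(profiles))) {
    cols <- lin_entries[[profiles$lineage[i]]]
    row <- match(profiles$sample_id[i], samples)
    mat[row, cols] <- mat[row, cols] + profiles$count[i]
  }
  mat
}

#' @rdname all_rank_matrix
#' @return `all_rank_vector()` returns the single row as a named vector and
#'   requires `profiles` to hold exactly one sample.
#' @export
all_rank_vector <- function(profiles, universe = taxon_universe(profiles)) {
  if (length(unique(profiles$sample_id)) != 1L) {
    abort("all_rank_vector expects exactly one sample; see all_rank_matrix")
  }
  drop(all_rank_matrix(profiles, universe))
}

#' Absolute fold change between two samples scaled by plate counts
#'
#' 16S proportions only give relative abundances; multiplying by a
#' per-sample CFU/mL estimate gives a rough absolute scale, so that a taxon
#' whose share shrinks in activated sludge may still have grown in absolute
#' numbers. Taxa present in exactly one sample get an infinite sentinel
#' rather than a pseudocounted ratio (a pseudocount is available but off by
#' default). Estimates inherit the cultivation bias of CFU counts; treat
#' them as indicative only.
#'
#' @param profiles Normalized profiles tibble carrying `cfu_per_ml` for the
#'   two samples compared.
#' @param numerator,denominator Sample ids (conventionally AS and IW).
#' @param rank Rank label at which taxa are compared (default `"family"`).
#' @param pseudocount Relative-abundance pseudocount added to both sides;
#'   0 keeps the infinite sentinels.
#' @return Tibble: `taxon`, absolute scale in each sample (`abs_num`,
#'   `abs_den`), `log2_fc`, and `status` (`both`, `numerator_only`,
#'   `denominator_only`).
#' @export
absolute_fold_change <- function(profiles, numerator, denominator,
                                 rank = "family", pseudocount = 0) {
  check_profiles(profiles, need_normalized = TRUE)
  pair <- profiles %>% filter(.data$sample_id %in% c(numerator, denominator))
  meta <- profile_meta(pair)
  if (nrow(meta) != 2L) abort("numerator/denominator samples not found")
  if (any(is.na(meta$cfu_per_ml))) {
    abort("both samples need a cfu_per_ml value")
  }
  cfu <- setNames(meta$cfu_per_ml, meta$sample_id)
  uni <- taxon_universe(pair) %>% filter(.data$rank == !!rank)
  if (!nrow(uni)) abort(paste0("no taxa at rank '", rank, "'"))
  mat <- all_rank_matrix(pair, uni)
  rel_num <- mat[numerator, ] + pseudocount
  rel_den <- mat[denominator, ] + pseudocount
  abs_num <- rel_num * cfu[[numerator]]
  abs_den <- rel_den * cfu[[denominator]]
  keep <- rel_num > 0 | rel_den > 0
  tibble(taxon = uni$taxon[keep],
         abs_num = unname(abs_num[keep]),
         abs_den = unname(abs_den[keep]),
         log2_fc = unname(log2(abs_num[keep] / abs_den[keep])),
         status = dplyr::case_when(
           rel_num[keep] > 0 & rel_den[keep] > 0 ~ "both",
           rel_num[keep] > 0 ~ "numerator_only",
           TRUE ~ "denominator_only")) %>%
    arrange(.data$taxon)
}
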