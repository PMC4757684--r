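# Lineages are canonical strings "rank:name;rank:name;..." running from
# domain downwards. Ranks must appear in strictly descending canonical order
# but may skip levels (a read classified to family has no genus entry).

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

#' Taxonomic rank labels in canonical order
#'
#' @return Character vector of the seven rank labels from domain to species.
#' @export
lineage_ranks <- function() LINEAGE_RANKS

#' Parse and canonicalise lineage strings
#'
#' A lineage is written `"rank:name;rank:name;..."`, e.g.
#' `"domain:Bacteria;phylum:Proteobacteria;genus:Pseudomonas"`. Ranks must
#' descend strictly in the order domain, phylum, class, order, family, genus,
#' species; levels may be skipped. Whitespace around separators is ignored.
#'
#' @param x Character vector of lineage strings.
#' @return Character vector of canonical lineage strings (no padding
#'   whitespace), same length as `x`.
#' @examples
#' parse_lineage("domain:Bacteria; genus:Pseudomonas")
#' @export
parse_lineage <- function(x) {
  vapply(x, function(one) {
    if (is.na(one) || !nzchar(trimws(one))) {
      abort("empty lineage string")
    }
    parts <- strsplit(one, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (!length(parts)) abort(paste0("empty lineage string: '", one, "'"))
    ranks <- character(length(parts))
    names_ <- character(length(parts))
    for (i in seq_along(parts)) {
      pos <- regexpr(":", parts[[i]], fixed = TRUE)
      if (pos < 0) {
        abort(paste0("malformed lineage entry '", parts[[i]],
                     "' (expected 'rank:name')"))
      }
      ranks[i] <- trimws(substr(parts[[i]], 1L, pos - 1L))
      names_[i] <- trimws(substr(parts[[i]], pos + 1L, nchar(parts[[i]])))
    }
    idx <- match(ranks, LINEAGE_RANKS)
    if (anyNA(idx)) {
      abort(paste0("unknown rank label '", ranks[which(is.na(idx))[1]],
                   "' in lineage '", one, "'"))
    }
    if (any(diff(idx) <= 0)) {
      abort(paste0("ranks do not strictly descend in lineage '", one, "'"))
    }
    if (any(!nzchar(names_))) {
      abort(paste0("empty taxon name in lineage '", one, "'"))
    }
    paste(paste0(ranks, ":", names_), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Split a canonical lineage into a rank/name table
#'
#' @param x A single canonical lineage string (see [parse_lineage()]).
#' @return A tibble with columns `rank` and `name`, one row per level.
#' @export
lineage_table <- function(x) {
  stopifnot(length(x) == 1L)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble(rank = vapply(kv, `[[`, "", 1L),
         name = vapply(kv, `[[`, "", 2L))
}

# All ancestor strings of a canonical lineage, shallowest first, self last.
lineage_prefixes <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  vapply(seq_along(parts), function(k) paste(parts[seq_len(k)], collapse = ";"),
         character(1))
}

# TRUE if canonical lineage `a` is an ancestor of, or equal to, `b`.
# Real inputs mix rank coverage (profiles carry full domain..genus chains,
# databases often just genus/species), so the test is entry-based: `a` is
# an ancestor-or-equal of `b` when a's deepest (rank, name) entry occurs
# anywhere in b's chain. Vectorised over `a` for a single `b`.
lineage_is_ancestor <- function(a, b) {
  b_entries <- strsplit(b, ";", fixed = TRUE)[[1]]
  a_last <- sub("^.*;", "", a)
  a_last %in% b_entries
}

# Deepest rank label present in a canonical lineage (vectorised).
lineage_deepest_rank <- function(x) {
  vapply(strsplit(x, ";", fixed = TRUE), function(parts) {
    sub(":.*$", "", parts[[length(parts)]])
  }, character(1))
}

# Name of the taxon at `rank` in each canonical lineage, NA where the
# lineage has no entry at that rank (vectorised).
lineage_taxon_at <- function(x, rank) {
  pre <- paste0(rank, ":")
  vapply(strsplit(x, ";", fixed = TRUE), function(parts) {
    hit <- parts[startsWith(parts, pre)]
    if (length(hit)) sub("^[^:]*:", "", hit[[1]]) else NA_character_
  }, character(1))
}
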