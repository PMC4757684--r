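# A pathway_db holds a reaction catalogue (reaction id -> capable-organism
# lineages) and a pathway catalogue (pathway id -> ordered series-parallel
# stage tree). Stages are plain lists: either list(reaction = "id") or
# list(parallel = list(branch, ...)) where each branch is a list of stages.

#' Construct a pathway database
#'
#' @param reactions Named list; each element `list(name =, organisms =)`
#'   where `organisms` is a character vector of canonical lineages
#'   (see [parse_lineage()]), possibly empty.
#' @param pathways Named list; each element
#'   `list(name =, keywords =, stages =)` where `stages` is a non-empty list
#'   of stage nodes built with [stage_reaction()] / [stage_parallel()].
#' @param source_note Free-text provenance of the database.
#' @return A `pathway_db` object.
#' @seealso [load_db()], [validate_db()], [stage_reaction()]
#' @export
pathway_db <- function(reactions = list(), pathways = list(),
                       source_note = "") {
  db <- structure(list(reactions = reactions, pathways = pathways,
                       source_note = source_note),
                  class = "pathway_db")
  findings <- validate_db(db)
  if (length(findings)) {
    abort(c("invalid pathway database", findings))
  }
  db
}

#' Stage constructors for series-parallel pathways
#'
#' A pathway is an ordered chain of stages. A stage is either a single
#' reaction or a parallel block of alternative sub-pathways, each itself an
#' ordered list of stages.
#'
#' @param reaction_id Reaction identifier (must exist in the owning db).
#' @param ... For `stage_parallel()`: two or more branches, each a list of
#'   stage nodes (a single stage node is promoted to a one-stage branch).
#' @return A stage node (plain list).
#' @examples
#' stage_parallel(stage_reaction("RXN-1"),
#'                list(stage_reaction("RXN-2"), stage_reaction("RXN-3")))
#' @export
stage_reaction <- function(reaction_id) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L)
  list(reaction = reaction_id)
}

#' @rdname stage_reaction
#' @export
stage_parallel <- function(...) {
  branches <- lapply(list(...), function(b) {
    if (is_stage(b)) list(b) else b
  })
  if (!length(branches)) abort("parallel stage needs at least one branch")
  list(parallel = branches)
}

is_stage <- function(x) {
  is.list(x) && length(x) == 1L && names(x) %in% c("reaction", "parallel")
}

#' Validate a pathway database
#'
#' Checks referential integrity (every reaction reference resolves), that
#' every pathway has at least one stage, that no branch is empty, that ids
#' are unique, and that organism lineages parse. Violations are returned as
#' findings, not raised.
#'
#' @param db A `pathway_db` (or structurally similar list).
#' @return Character vector of findings; empty when the database is valid.
#' @export
validate_db <- function(db) {
  findings <- character()
  note <- function(msg) findings <<- c(findings, msg)

  rids <- names(db$reactions) %||% character()
  pids <- names(db$pathways) %||% character()
  for (dup in unique(rids[duplicated(rids)])) {
    note(paste0("duplicate reaction id '", dup, "'"))
  }
  for (dup in unique(pids[duplicated(pids)])) {
    note(paste0("duplicate pathway id '", dup, "'"))
  }
  for (rid in rids) {
    orgs <- db$reactions[[rid]]$organisms
    for (o in orgs) {
      ok <- tryCatch({ parse_lineage(o); TRUE }, error = function(e) FALSE)
      if (!ok) note(paste0("reaction '", rid, "': invalid lineage '", o, "'"))
    }
  }

  check_stages <- function(stages, pid, where) {
    if (!length(stages)) {
      note(paste0("pathway '", pid, "': empty stage list", where))
      return(invisible())
    }
    for (st in stages) {
      if (!is_stage(st)) {
        note(paste0("pathway '", pid, "': malformed stage node", where))
      } else if (!is.null(st$reaction)) {
        if (!st$reaction %in% rids) {
          note(paste0("pathway '", pid, "': dangling reaction ref '",
                      st$reaction, "'"))
        }
      } else {
        if (!length(st$parallel)) {
          note(paste0("pathway '", pid, "': parallel stage with no branches",
                      where))
        }
        for (br in st$parallel) {
          check_stages(br, pid, " (in parallel branch)")
        }
      }
    }
  }
  for (pid in pids) check_stages(db$pathways[[pid]]$stages, pid, "")
  findings
}

#' Read a pathway database from its JSON interchange format
#'
#' The document has the shape
#' `{"reactions": {id: {"name", "organisms": [[["genus","Pseudomonas"]], ...]}},`
#' `"pathways": {id: {"name", "keywords": [...], "stages": [stage]}}}` with
#' `stage = {"reaction": id}` or `{"parallel": [[stage, ...], ...]}`.
#' Organisms are lists of `[rank, name]` pairs.
#'
#' @param text Path to a JSON file, or a JSON string.
#' @return A validated `pathway_db`.
#' @seealso [save_db()]
#' @export
load_db <- function(text) {
  raw <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(raw)) abort("pathway db JSON must be an object")
  reactions <- lapply(raw$reactions %||% list(), function(r) {
    orgs <- vapply(r$organisms %||% list(), function(org) {
      parse_lineage(paste(vapply(org, function(p) {
        paste0(p[[1]], ":", p[[2]])
      }, character(1)), collapse = ";"))
    }, character(1))
    list(name = r$name %||% "", organisms = orgs)
  })
  pathways <- lapply(raw$pathways %||% list(), function(p) {
    list(name = p$name %||% "",
         keywords = vapply(p$keywords %||% list(), as.character, ""),
         stages = lapply(p$stages %||% list(), stage_from_json))
  })
  db <- structure(list(reactions = reactions, pathways = pathways,
                       source_note = raw$source_note %||% ""),
                  class = "pathway_db")
  findings <- validate_db(db)
  if (length(findings)) abort(c("invalid pathway database", findings))
  db
}

stage_from_json <- function(node) {
  if (!is.null(node$reaction)) {
    stage_reaction(as.character(node$reaction))
  } else if (!is.null(node$parallel)) {
    list(parallel = lapply(node$parallel, function(branch) {
      lapply(branch, stage_from_json)
    }))
  } else {
    abort("stage node must have a 'reaction' or a 'parallel' field")
  }
}

#' Write a pathway database as canonical JSON
#'
#' Keys are emitted sorted and lists in stable order, so two saves of the
#' same database are byte-identical and diffs are meaningful.
#'
#' @param db A `pathway_db`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
save_db <- function(db, path = NULL) {
  org_to_json <- function(lin) {
    tb <- lineage_table(lin)
    lapply(seq_len(nrow(tb)), function(i) list(tb$rank[i], tb$name[i]))
  }
  rid_sorted <- sort(names(db$reactions) %||% character())
  pid_sorted <- sort(names(db$pathways) %||% character())
  reactions <- lapply(db$reactions[rid_sorted], function(r) {
    list(name = r$name,
         organisms = lapply(sort(unname(r$organisms)), org_to_json))
  })
  pathways <- lapply(db$pathways[pid_sorted], function(p) {
    list(name = p$name,
         keywords = as.list(sort(unname(p$keywords))),
         stages = lapply(p$stages, stage_to_json))
  })
  doc <- list(reactions = reactions, pathways = pathways,
              source_note = db$source_note)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

stage_to_json <- function(st) {
  if (!is.null(st$reaction)) {
    list(reaction = st$reaction)
  } else {
    list(parallel = lapply(st$parallel, function(branch) {
      lapply(branch, stage_to_json)
    }))
  }
}

#' Pathway ids matching a keyword
#'
#' Case-insensitive substring match against the pathway name and each
#' keyword entry; the empty string matches every pathway.
#'
#' @param db A `pathway_db`.
#' @param keyword Single string.
#' @return Sorted character vector of matching pathway ids.
#' @examples
#' # filter_by_keyword(db, "degradation")
#' @export
filter_by_keyword <- function(db, keyword) {
  stopifnot(is.character(keyword), length(keyword) == 1L)
  kw <- tolower(keyword)
  hits <- vapply(db$pathways, function(p) {
    hay <- tolower(c(p$name, p$keywords))
    any(grepl(kw, hay, fixed = TRUE)) || kw == ""
  }, logical(1))
  sort(names(db$pathways)[hits])
}

#' Summarise the pathways of a database as a tibble
#'
#' @param db A `pathway_db`.
#' @return A tibble with one row per pathway: id, name, number of top-level
#'   stages, total reaction references, and keywords collapsed with "; ".
#' @export
db_pathway_summary <- function(db) {
  count_refs <- function(stages) {
    sum(vapply(stages, function(st) {
      if (!is.null(st$reaction)) 1L
      else sum(vapply(st$parallel, count_refs, integer(1)))
    }, integer(1)))
  }
  ids <- sort(names(db$pathways))
  tibble(
    pathway_id = ids,
    name = vapply(ids, function(i) db$pathways[[i]]$name, ""),
    n_stages = vapply(ids, function(i) length(db$pathways[[i]]$stages), 0L),
    n_reactions = vapply(ids, function(i) count_refs(db$pathways[[i]]$stages),
                         0L),
    keywords = vapply(ids, function(i) {
      paste(db$pathways[[i]]$keywords, collapse = "; ")
    }, "")
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", length(x$reactions), " reactions, ",
      length(x$pathways), " pathways\n", sep = "")
  if (nzchar(x$source_note)) cat("  source: ", x$source_note, "\n", sep = "")
  invisible(x)
}
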