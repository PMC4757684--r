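# Parser for MetaCyc-style attribute-value flat files: records are separated
# by "//" lines, attributes are "ATTR - VALUE" lines, comments start with
# "#", continuation lines start with "/". Pathway records carry a
# predecessor relation over their reactions; we attempt a two-terminal
# series-parallel reduction of that DAG and fall back to the plain
# REACTION-LIST order (flagged) when the topology is not series-parallel.

read_text_arg <- function(x) {
  if (length(x) > 1L) return(x)
  if (grepl("\n", x, fixed = TRUE)) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  if (file.exists(x)) return(readLines(x, warn = FALSE))
  x
}

# -> list of records; each record is a named list of character vectors
parse_attr_records <- function(lines) {
  records <- list()
  current <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    if (trimws(line) == "//") {
      if (length(current)) records[[length(records) + 1L]] <- current
      current <- list()
      next
    }
    if (startsWith(line, "/")) next  # continuation of the previous value
    pos <- regexpr(" - ", line, fixed = TRUE)
    if (pos < 0) {
      abort(paste0("unreadable attribute-value line ", i, ": '", line, "'"))
    }
    attr <- substr(line, 1L, pos - 1L)
    value <- trimws(substr(line, pos + 3L, nchar(line)))
    current[[attr]] <- c(current[[attr]] %||% character(), value)
  }
  if (length(current)) records[[length(records) + 1L]] <- current
  records
}

#' Build a pathway database from MetaCyc-style flat files
#'
#' Three attribute-value files are consumed. `pathways` records use
#' `UNIQUE-ID`, `COMMON-NAME`, repeated `REACTION-LIST` lines (one reaction
#' id each) and optional repeated `PREDECESSORS - (SUCC PRED)` lines giving
#' the ordering DAG. `reactions` records use `UNIQUE-ID`, `COMMON-NAME` and
#' repeated `SPECIES` (or `ORGANISM`) lines holding organism ids.
#' `organisms` records map `UNIQUE-ID` to a `LINEAGE` written as
#' `"rank:name;rank:name;..."` (see [parse_lineage()]).
#'
#' Pathways whose predecessor DAG admits a series-parallel reduction get the
#' corresponding stage tree; others are linearised in `REACTION-LIST` order
#' and flagged in the database `source_note` (serialising extra ordering
#' constraints can only lower availability scores, so the fallback is
#' conservative). Pathways referencing unknown reactions are skipped with a
#' warning.
#'
#' @param pathways,reactions,organisms File paths or character content.
#' @return A validated `pathway_db`.
#' @export
parse_metacyc_dat <- function(pathways, reactions, organisms) {
  org_recs <- parse_attr_records(read_text_arg(organisms))
  org_map <- list()
  for (rec in org_recs) {
    id <- rec[["UNIQUE-ID"]][1] %||% NULL
    lin <- rec[["LINEAGE"]][1] %||% NULL
    if (is.null(id) || is.null(lin)) next
    org_map[[id]] <- parse_lineage(lin)
  }

  rxn_recs <- parse_attr_records(read_text_arg(reactions))
  rxns <- list()
  for (rec in rxn_recs) {
    id <- rec[["UNIQUE-ID"]][1] %||% NULL
    if (is.null(id)) next
    org_ids <- c(rec[["SPECIES"]] %||% character(),
                 rec[["ORGANISM"]] %||% character())
    lineages <- character()
    for (oid in org_ids) {
      if (is.null(org_map[[oid]])) {
        warn(paste0("reaction '", id, "': unknown organism '", oid,
                    "' dropped"))
      } else {
        lineages <- c(lineages, org_map[[oid]])
      }
    }
    rxns[[id]] <- list(name = rec[["COMMON-NAME"]][1] %||% id,
                       organisms = unique(lineages))
  }

  pwy_recs <- parse_attr_records(read_text_arg(pathways))
  pwys <- list()
  linearized <- character()
  for (rec in pwy_recs) {
    id <- rec[["UNIQUE-ID"]][1] %||% NULL
    if (is.null(id)) next
    rlist <- rec[["REACTION-LIST"]] %||% character()
    if (!length(rlist)) next
    missing <- setdiff(rlist, names(rxns))
    if (length(missing)) {
      warn(paste0("pathway '", id, "' skipped: unknown reaction(s) ",
                  paste0("'", missing, "'", collapse = ", ")))
      next
    }
    preds <- parse_predecessors(rec[["PREDECESSORS"]] %||% character(), rlist)
    stages <- NULL
    if (!is.null(preds)) {
      stages <- sp_reduce_dag(rlist, preds)
    }
    if (is.null(stages)) {
      if (!is.null(preds) && nrow(preds)) linearized <- c(linearized, id)
      stages <- lapply(rlist, stage_reaction)
    }
    pwys[[id]] <- list(name = rec[["COMMON-NAME"]][1] %||% id,
                       keywords = character(),
                       stages = stages)
  }

  note <- "parsed from MetaCyc-style flat files"
  if (length(linearized)) {
    note <- paste0(note, "; linearized (non-series-parallel): ",
                   paste(sort(linearized), collapse = ", "))
  }
  pathway_db(reactions = rxns, pathways = pwys, source_note = note)
}

# "(SUCC PRED1 PRED2)" lines -> data.frame(from = pred, to = succ);
# NULL when no usable predecessor lines are present.
parse_predecessors <- function(lines, rlist) {
  if (!length(lines)) return(NULL)
  from <- character(); to <- character()
  for (ln in lines) {
    inner <- gsub("^\\(|\\)$", "", trimws(ln))
    toks <- strsplit(trimws(inner), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2L) next
    for (p in toks[-1]) {
      from <- c(from, p); to <- c(to, toks[[1]])
    }
  }
  keep <- from %in% rlist & to %in% rlist
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

# Two-terminal series-parallel reduction of a reaction DAG. Returns a stage
# list on success, NULL when the graph is not series-parallel (or cyclic).
sp_reduce_dag <- function(nodes, edges) {
  # split each reaction node r into r.in -> r.out carrying the reaction term;
  # DAG edges become epsilon edges between the split halves.
  ef <- c(paste0(nodes, ".in"), paste0(edges$from, ".out"),
          rep("S", 0L))
  term_rxn <- function(id) list(type = "rxn", id = id)
  e_from <- paste0(nodes, ".in")
  e_to <- paste0(nodes, ".out")
  e_term <- lapply(nodes, term_rxn)
  if (nrow(edges)) {
    e_from <- c(e_from, paste0(edges$from, ".out"))
    e_to <- c(e_to, paste0(edges$to, ".in"))
    e_term <- c(e_term, rep(list(NULL), nrow(edges)))
  }
  roots <- setdiff(nodes, edges$to)
  leaves <- setdiff(nodes, edges$from)
  if (!length(roots) || !length(leaves)) return(NULL)  # cyclic
  e_from <- c(e_from, rep("S", length(roots)), paste0(leaves, ".out"))
  e_to <- c(e_to, paste0(roots, ".in"), rep("T", length(leaves)))
  e_term <- c(e_term, rep(list(NULL), length(roots) + length(leaves)))

  combine_series <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    parts <- list()
    for (t in list(a, b)) {
      if (t$type == "series") parts <- c(parts, t$parts) else
        parts <- c(parts, list(t))
    }
    list(type = "series", parts = parts)
  }
  combine_parallel <- function(a, b) {
    if (is.null(a) && is.null(b)) return(NULL)
    parts <- list()
    for (t in list(a, b)) {
      if (is.null(t)) next
      if (t$type == "parallel") parts <- c(parts, t$parts) else
        parts <- c(parts, list(t))
    }
    if (length(parts) == 1L) parts[[1]] else list(type = "parallel",
                                                  parts = parts)
  }

  repeat {
    changed <- FALSE
    # parallel rule: merge a duplicated (from, to) edge pair
    key <- paste(e_from, e_to, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      j <- dup[[1]]
      i <- which(key == key[[j]])[[1]]
      e_term[[i]] <- combine_parallel(e_term[[i]], e_term[[j]])
      e_from <- e_from[-j]; e_to <- e_to[-j]; e_term <- e_term[-j]
      changed <- TRUE
    } else {
      # series rule: contract an internal vertex of degree (1, 1)
      verts <- setdiff(unique(c(e_from, e_to)), c("S", "T"))
      for (v in verts) {
        ins <- which(e_to == v); outs <- which(e_from == v)
        if (length(ins) == 1L && length(outs) == 1L) {
          i <- ins; j <- outs
          e_term[[i]] <- combine_series(e_term[[i]], e_term[[j]])
          e_to[[i]] <- e_to[[j]]
          e_from <- e_from[-j]; e_to <- e_to[-j]; e_term <- e_term[-j]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  if (length(e_from) != 1L || e_from[[1]] != "S" || e_to[[1]] != "T") {
    return(NULL)
  }
  term_to_stages(e_term[[1]])
}

term_to_stages <- function(term) {
  if (is.null(term)) return(list())
  if (term$type == "rxn") return(list(stage_reaction(term$id)))
  if (term$type == "series") {
    return(do.call(c, lapply(term$parts, term_to_stages)))
  }
  # parallel term -> one parallel stage whose branches are stage lists
  list(list(parallel = lapply(term$parts, term_to_stages)))
}
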