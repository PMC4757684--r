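# Shared in-code fixtures: tiny databases, tiny profiles, and independent
# oracles (brute-force series-parallel reducer, textbook Lance-Williams
# Ward clustering, exhaustive Mann-Whitney null enumeration).

lin <- function(...) paste(c(...), collapse = ";")

# one-sample profiles tibble from a named count vector (names = lineages)
toy_profile <- function(counts, sample_id = "s1", plant = "P1",
                        compartment = "AS", date = as.Date("2013-10-15"),
                        replicate = 1L, cfu_per_ml = NA_real_,
                        normalized = FALSE) {
  tibble::tibble(sample_id = sample_id, plant = plant,
                 compartment = compartment, date = date,
                 replicate = replicate, cfu_per_ml = cfu_per_ml,
                 lineage = names(counts), count = unname(counts),
                 normalized = normalized)
}

# three-pathway fixture database exercising parallel blocks and
# species-level organisms
fixture_db <- function() {
  pathway_db(
    reactions = list(
      "RXN-A" = list(name = "step A", organisms = c(
        "domain:Bacteria;genus:Pseudomonas;species:Pseudomonas putida",
        "domain:Bacteria;genus:Pseudomonas;species:Pseudomonas fluorescens",
        "domain:Bacteria;genus:Flavobacterium")),
      "RXN-B" = list(name = "step B",
                     organisms = "domain:Bacteria;genus:Flavobacterium"),
      "RXN-C" = list(name = "step C",
                     organisms = "domain:Bacteria;genus:Nitrospira"),
      "RXN-D" = list(name = "step D", organisms = character())),
    pathways = list(
      "PWY-1" = list(name = "leucine degradation I",
                     keywords = c("degradation", "amino acid"),
                     stages = list(stage_reaction("RXN-A"),
                                   stage_reaction("RXN-B"))),
      "PWY-2" = list(name = "TCA cycle", keywords = character(),
                     stages = list(stage_reaction("RXN-C"))),
      "PWY-3" = list(name = "branched route", keywords = "degradation",
                     stages = list(
                       stage_reaction("RXN-A"),
                       stage_parallel(stage_reaction("RXN-B"),
                                      stage_reaction("RXN-C"))))),
    source_note = "hand-built fixture")
}

# ---- independent series-parallel oracle --------------------------------

# term tree: list(op = "leaf", value =) | list(op = "serial"/"parallel",
# kids = list(term, ...)). Built from a stage list plus per-reaction
# capacities, then reduced by repeatedly collapsing, in random order, any
# node whose children are all leaves: serial -> harmonic sum (0 if any
# child is 0), parallel -> plain sum. The reduction is confluent, so any
# collapse order must give the recursive evaluator's answer.
oracle_term_from_stages <- function(stages, caps) {
  kids <- lapply(stages, function(st) {
    if (!is.null(st$reaction)) {
      list(op = "leaf", value = caps[[st$reaction]])
    } else {
      list(op = "parallel",
           kids = lapply(st$parallel, oracle_term_from_stages, caps = caps))
    }
  })
  list(op = "serial", kids = kids)
}

oracle_collapse <- function(op, values) {
  if (op == "serial") {
    if (any(values == 0)) 0 else 1 / sum(1 / values)
  } else {
    sum(values)
  }
}

oracle_reduce <- function(term) {
  if (term$op == "leaf") return(term$value)
  repeat {
    # indices (paths) of reducible internal nodes
    paths <- list()
    walk <- function(node, path) {
      if (node$op == "leaf") return(invisible())
      if (all(vapply(node$kids, function(k) k$op == "leaf", logical(1)))) {
        paths[[length(paths) + 1L]] <<- path
      }
      for (i in seq_along(node$kids)) walk(node$kids[[i]], c(path, i))
    }
    walk(term, integer())
    if (!length(paths)) stop("irreducible term")  # cannot happen on trees
    p <- paths[[sample.int(length(paths), 1L)]]
    node <- term
    for (i in p) node <- node$kids[[i]]
    leaf <- list(op = "leaf",
                 value = oracle_collapse(node$op, vapply(node$kids,
                                                         `[[`, 0, "value")))
    if (!length(p)) {
      term <- leaf
    } else {
      expr <- "term"
      for (i in p) expr <- paste0(expr, "$kids[[", i, "]]")
      eval(parse(text = paste0(expr, " <- leaf")))
    }
    if (term$op == "leaf") return(term$value)
  }
}

# random series-parallel stage list over reactions RXN-1..RXN-n (n <= 12);
# returns list(stages =, n_reactions =)
random_sp_stages <- function(max_reactions = 12L, depth = 0L) {
  counter <- 0L
  new_rxn <- function() {
    counter <<- counter + 1L
    stage_reaction(sprintf("RXN-%d", counter))
  }
  gen_stages <- function(budget, depth) {
    n <- sample.int(min(3L, budget), 1L)
    left <- budget
    out <- list()
    for (i in seq_len(n)) {
      if (left <= 0L) break
      if (depth < 2L && left >= 2L && stats::runif(1) < 0.35) {
        nb <- sample(2:min(3L, left), 1L)
        per <- max(1L, (left %/% nb) %/% 2L)
        branches <- lapply(seq_len(nb), function(b) {
          gen_stages(max(1L, per), depth + 1L)
        })
        out[[length(out) + 1L]] <- list(parallel = branches)
        left <- left - sum(vapply(branches, count_stage_rxns, 0L))
      } else {
        out[[length(out) + 1L]] <- new_rxn()
        left <- left - 1L
      }
    }
    if (!length(out)) out <- list(new_rxn())
    out
  }
  count_stage_rxns <- function(stages) {
    sum(vapply(stages, function(st) {
      if (!is.null(st$reaction)) 1L else
        sum(vapply(st$parallel, count_stage_rxns, 0L))
    }, 0L))
  }
  stages <- gen_stages(max_reactions, depth)
  list(stages = stages, n_reactions = counter)
}

# random db/profile pair around a random SP pathway; capacities are the
# per-reaction totals implied by the profile
random_sp_case <- function(max_reactions = 12L, allow_zero = TRUE) {
  sp <- random_sp_stages(max_reactions)
  n <- sp$n_reactions
  genera <- sprintf("domain:Bacteria;genus:Gen%02d", seq_len(n))
  reactions <- lapply(seq_len(n), function(i) {
    list(name = "", organisms = genera[[i]])
  })
  names(reactions) <- sprintf("RXN-%d", seq_len(n))
  db <- pathway_db(reactions = reactions,
                   pathways = list("PWY" = list(name = "rand",
                                                keywords = character(),
                                                stages = sp$stages)))
  counts <- stats::rpois(n, 40) + (!allow_zero)
  if (allow_zero) counts[stats::runif(n) < 0.1] <- 0
  prof <- toy_profile(stats::setNames(as.numeric(counts), genera))
  caps <- stats::setNames(as.numeric(counts), names(reactions))
  list(db = db, profile = prof, caps = caps, stages = sp$stages)
}

# ---- textbook Lance-Williams Ward oracle -------------------------------

# Agglomerative Ward on a distance matrix: operates on squared distances,
# merges the minimum pair, Lance-Williams update
#   d2(k, i+j) = [(n_i+n_k) d2(k,i) + (n_j+n_k) d2(k,j) - n_k d2(i,j)] / N.
# Returns the cophenetic matrix with heights on the distance scale.
ward_oracle_cophenetic <- function(dm) {
  n <- nrow(dm)
  labels <- rownames(dm)
  d2 <- dm^2
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  cur <- d2
  for (step in seq_len(n - 1L)) {
    best <- NULL; bestval <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a < b && cur[a, b] < bestval) { bestval <- cur[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    h <- sqrt(bestval)
    for (x in members[[i]]) for (y in members[[j]]) {
      coph[x, y] <- coph[y, x] <- h
    }
    for (k in idx) {
      if (k == i || k == j) next
      cur[i, k] <- cur[k, i] <-
        ((sizes[i] + sizes[k]) * cur[i, k] +
           (sizes[j] + sizes[k]) * cur[j, k] -
           sizes[k] * cur[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  coph
}

# ---- exhaustive Mann-Whitney two-sided null ----------------------------

# exact two-sided p for U by enumerating every assignment of the pooled
# values to the two groups (no ties assumed)
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), nx)
  u_null <- apply(combos, 2L, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(u_null <= u_obs + 1e-9)
  p_ge <- mean(u_null >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
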