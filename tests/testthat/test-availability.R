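test_that("reaction capacity matches organisms to deepest ancestor, deduped", {
  db <- fixture_db()
  prof <- toy_profile(c("domain:Bacteria;genus:Pseudomonas" = 40,
                        "domain:Bacteria;genus:Flavobacterium" = 10))
  # two Pseudomonas species collapse onto the genus entry: counted once
  cap <- reaction_capacity(prof, db, "RXN-A")
  expect_equal(unique(cap$total), 50)
  expect_setequal(stats::na.omit(cap$lineage),
                  c("domain:Bacteria;genus:Pseudomonas",
                    "domain:Bacteria;genus:Flavobacterium"))
  # without dedup the genus reads are counted once per capable species
  cap2 <- reaction_capacity(prof, db, "RXN-A", dedup = FALSE)
  expect_equal(unique(cap2$total), 90)
  # no capable organism present / empty organism set -> 0
  expect_equal(unique(reaction_capacity(prof, db, "RXN-C")$total), 0)
  expect_equal(unique(reaction_capacity(prof, db, "RXN-D")$total), 0)
})

test_that("deepest-match prefers the species entry over its genus", {
  db <- fixture_db()
  prof <- toy_profile(c(
    "domain:Bacteria;genus:Pseudomonas" = 40,
    "domain:Bacteria;genus:Pseudomonas;species:Pseudomonas putida" = 7))
  cap <- reaction_capacity(prof, db, "RXN-A")
  # P. putida matches its own species row; P. fluorescens the genus row
  expect_equal(unique(cap$total), 47)
})

test_that("matching bridges different rank coverage of profile and database", {
  # classifier output spells out every rank; database organisms often
  # record only genus (and species)
  db <- fixture_db()
  prof <- toy_profile(c(
    "domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Pseudomonadaceae;genus:Pseudomonas" = 40,
    "domain:Bacteria;phylum:Bacteroidetes;class:Flavobacteriia;order:Flavobacteriales;family:Flavobacteriaceae;genus:Flavobacterium" = 10))
  expect_equal(unique(reaction_capacity(prof, db, "RXN-A")$total), 50)
  expect_equal(unname(score_pathway(prof, db, "PWY-1")),
               1 / (1 / 50 + 1 / 10))
})

test_that("stage capacities and pathway scores follow the printed rules", {
  db <- fixture_db()
  prof <- toy_profile(c("domain:Bacteria;genus:Pseudomonas" = 20,
                        "domain:Bacteria;genus:Flavobacterium" = 10,
                        "domain:Bacteria;genus:Nitrospira" = 20))
  # parallel stage: sum of branch scores (single-step branches = capacity)
  par <- stage_parallel(stage_reaction("RXN-B"), stage_reaction("RXN-C"))
  expect_equal(unname(stage_capacity(prof, db, par)), 30)
  # zero branch contributes nothing, the other survives
  prof0 <- toy_profile(c("domain:Bacteria;genus:Nitrospira" = 30))
  expect_equal(unname(stage_capacity(prof0, db, par)), 30)
  # reaction stage = its capacity
  expect_equal(unname(stage_capacity(prof, db, stage_reaction("RXN-A"))), 30)

  # serial harmonic: PWY-1 = 1/(1/30 + 1/10)
  expect_equal(unname(score_pathway(prof, db, "PWY-1")), 7.5)
  # single stage = capacity
  expect_equal(unname(score_pathway(prof, db, "PWY-2")), 20)
  # serial then parallel {10, 20}: 1/(1/30 + 1/30) = 15
  expect_equal(unname(score_pathway(prof, db, "PWY-3")), 15)
  # zero-capacity serial stage zeroes the pathway
  expect_equal(unname(score_pathway(prof0, db, "PWY-1")), 0)
})

test_that("score matrix equals element-wise pathway scoring", {
  db <- fixture_db()
  profs <- dplyr::bind_rows(
    toy_profile(c("domain:Bacteria;genus:Pseudomonas" = 20,
                  "domain:Bacteria;genus:Flavobacterium" = 10),
                sample_id = "s1", replicate = 1L),
    toy_profile(c("domain:Bacteria;genus:Flavobacterium" = 5,
                  "domain:Bacteria;genus:Nitrospira" = 80),
                sample_id = "s2", replicate = 2L),
    toy_profile(c("domain:Bacteria;genus:Pseudomonas" = 1),
                sample_id = "s3", replicate = 3L))
  av <- score_matrix(profs, db)
  for (pid in names(db$pathways)) {
    for (sid in c("s1", "s2", "s3")) {
      one <- profs[profs$sample_id == sid, ]
      expect_equal(av$s_a[av$pathway_id == pid & av$sample_id == sid],
                   unname(score_pathway(one, db, pid)),
                   label = paste(pid, sid))
    }
  }
  # identical profiles give identical rows
  dup <- dplyr::bind_rows(
    toy_profile(c("domain:Bacteria;genus:Flavobacterium" = 10),
                sample_id = "a", replicate = 1L),
    toy_profile(c("domain:Bacteria;genus:Flavobacterium" = 10),
                sample_id = "b", replicate = 2L))
  av2 <- score_matrix(dup, db)
  w <- avail_wide(av2)
  expect_equal(w[, "a"], w[, "b"])
  # pathway with no capable organisms anywhere -> zero row
  expect_true(all(w["PWY-2", ] == 0))
})

test_that("scores agree with the independent brute-force reducer", {
  set.seed(401)
  for (i in 1:200) {
    case <- random_sp_case(12L)
    got <- unname(score_pathway(case$profile, case$db, "PWY"))
    want <- oracle_reduce(oracle_term_from_stages(case$stages, case$caps))
    expect_equal(got, want, tolerance = 1e-12, label = paste("case", i))
  }
})

test_that("analytic properties hold on random instances", {
  set.seed(402)
  for (i in 1:120) {
    case <- random_sp_case(10L, allow_zero = FALSE)
    s <- unname(score_pathway(case$profile, case$db, "PWY"))
    # serial bound: never above the smallest top-level serial capacity
    capmat <- commpath:::reaction_capacity_matrix(case$db, case$profile)
    top <- vapply(case$stages, function(st) {
      commpath:::stage_capacity_vec(st, capmat)
    }, numeric(1))
    expect_lte(s, min(top) + 1e-9)
    # scale equivariance
    c_ <- stats::runif(1, 0.5, 3)
    scaled <- dplyr::mutate(case$profile, count = count * c_)
    expect_equal(unname(score_pathway(scaled, case$db, "PWY")), c_ * s,
                 tolerance = 1e-12)
    # monotonicity under a count increase
    bump <- case$profile
    j <- sample.int(nrow(bump), 1L)
    bump$count[j] <- bump$count[j] + 5
    expect_gte(unname(score_pathway(bump, case$db, "PWY")), s - 1e-12)
  }
})

test_that("adding a capable organism never decreases a score", {
  set.seed(403)
  for (i in 1:40) {
    case <- random_sp_case(8L, allow_zero = FALSE)
    s <- unname(score_pathway(case$profile, case$db, "PWY"))
    db2 <- case$db
    rid <- sample(names(db2$reactions), 1L)
    extra <- "domain:Bacteria;genus:Extra"
    db2$reactions[[rid]]$organisms <-
      c(db2$reactions[[rid]]$organisms, extra)
    prof2 <- dplyr::bind_rows(case$profile,
                              toy_profile(c("domain:Bacteria;genus:Extra" = 3)))
    prof2 <- prof2[!duplicated(prof2$lineage), ]
    expect_gte(unname(score_pathway(prof2, db2, "PWY")), s - 1e-12)
  }
})

test_that("a one-reaction pathway scores its reaction capacity", {
  set.seed(404)
  db <- fixture_db()
  for (i in 1:20) {
    counts <- stats::rpois(3, 30)
    prof <- toy_profile(c("domain:Bacteria;genus:Nitrospira" = counts[1],
                          "domain:Bacteria;genus:Pseudomonas" = counts[2],
                          "domain:Bacteria;genus:Flavobacterium" = counts[3]))
    expect_equal(unname(score_pathway(prof, db, "PWY-2")), counts[1])
  }
})
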