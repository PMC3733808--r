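pdb_prof <- function() default_profiles()[["Default (PDB)"]]
redo_prof <- function() default_profiles()[["Default (PDB_REDO)"]]

test_that("label_from_score follows the score/tolerance rule", {
  expect_equal(label_from_score(0, 1), "Good")
  expect_equal(label_from_score(2, 1), "Bad")
  expect_equal(label_from_score(1, 1), "Dubious")
  expect_equal(label_from_score(0, 0), "Good")
  expect_equal(label_from_score(1, 0), "Bad")
  expect_equal(label_from_score(3, 5), "Dubious")
})

test_that("evaluate_component reproduces the worked example", {
  # ligand as re-refined: all three default conditions met
  r1 <- evaluate_component(residue_stats(rsr = 0.065, rscc = 0.97,
                                         avg_occupancy = 1.0),
                           profile = redo_prof())
  expect_equal(r1$score, 0L)
  expect_equal(r1$label, "Good")
  # ligand as originally deposited: only RSCC fails
  r2 <- evaluate_component(residue_stats(rsr = 0.154, rscc = 0.86,
                                         avg_occupancy = 1.0),
                           profile = pdb_prof())
  expect_equal(r2$score, 1L)
  expect_equal(r2$failed_conditions, "rscc")
  expect_equal(r2$label, "Dubious")
})

test_that("threshold comparisons are inclusive at the printed values", {
  r <- evaluate_component(residue_stats(rsr = 0.24, rscc = 0.90,
                                        avg_occupancy = 1.0),
                          profile = pdb_prof())
  expect_equal(r$score, 0L)
  r2 <- evaluate_component(residue_stats(rsr = 0.165, rscc = 0.90,
                                         avg_occupancy = 1.0),
                           profile = redo_prof())
  expect_equal(r2$score, 0L)
})

test_that("rsr above the hard cap forces Bad regardless of the rest", {
  for (p in default_profiles()) {
    r <- evaluate_component(residue_stats(rsr = 0.45, rscc = 0.99,
                                          avg_occupancy = 1.0), profile = p)
    expect_equal(r$label, "Bad")
    expect_true("rsr_max" %in% r$failed_conditions)
    expect_true(r$score > p$tolerance)
  }
})

test_that("missing enabled statistics count as unmet and are reported", {
  r <- evaluate_component(residue_stats(rscc = 0.95), profile = pdb_prof())
  expect_equal(sort(r$failed_conditions), c("avg_occupancy", "rsr"))
  expect_equal(sort(r$missing_conditions), c("avg_occupancy", "rsr"))
  expect_equal(r$label, "Bad")  # 2 > tolerance 1
})

test_that("model-level conditions contribute to every component", {
  p <- profile("res", source = "PDB", resolution_max = 2.0,
               r_free_max = 0.25)
  good <- residue_stats(rsr = 0.1, rscc = 0.95, avg_occupancy = 1.0)
  r <- evaluate_component(good, list(resolution = 2.5, r_free = 0.3),
                          profile = p)
  expect_equal(sort(r$failed_conditions), c("r_free", "resolution"))
  r2 <- evaluate_component(good, list(resolution = 1.8, r_free = 0.2),
                           profile = p)
  expect_equal(r2$score, 0L)
})

test_that("evaluate_component agrees with the brute-force counter", {
  set.seed(123)
  for (rep in 1:200) {
    p <- profile("rnd", source = "PDB",
                 rscc_min = runif(1, 0.7, 0.95),
                 occupancy_min = runif(1, 0.8, 1),
                 rsr_good_max = runif(1, 0.1, 0.3),
                 rsr_max = runif(1, 0.3, 0.5),
                 owab_max = if (runif(1) < 0.5) runif(1, 20, 60) else NA,
                 r_free_max = if (runif(1) < 0.5) runif(1, 0.2, 0.3) else NA,
                 tolerance = sample(0:3, 1))
    s <- residue_stats(
      rsr = if (runif(1) < 0.9) runif(1, 0, 0.6) else NA,
      rscc = if (runif(1) < 0.9) runif(1, 0.4, 1) else NA,
      avg_occupancy = if (runif(1) < 0.9) runif(1, 0.4, 1) else NA,
      owab = if (runif(1) < 0.9) runif(1, 5, 80) else NA)
    ms <- list(resolution = NA_real_,
               r_free = if (runif(1) < 0.9) runif(1, 0.15, 0.35) else NA)
    r <- evaluate_component(s, ms, p)
    expect_equal(r$score,
                 brute_score(s$rsr, s$rscc, s$avg_occupancy, s$owab,
                             ms$r_free, ms$resolution, p))
    expect_equal(r$label, label_from_score(r$score, p$tolerance))
  }
})

test_that("relaxing thresholds never worsens a label", {
  set.seed(7)
  rank <- function(l) match(l, c("Good", "Dubious", "Bad"))
  for (rep in 1:100) {
    s <- residue_stats(rsr = runif(1, 0, 0.5), rscc = runif(1, 0.5, 1),
                       avg_occupancy = runif(1, 0.5, 1))
    p <- profile("tight", source = "PDB",
                 rscc_min = runif(1, 0.85, 0.95),
                 occupancy_min = runif(1, 0.9, 1),
                 rsr_good_max = runif(1, 0.15, 0.25),
                 rsr_max = runif(1, 0.35, 0.45))
    relaxed <- profile("loose", source = "PDB",
                       rscc_min = p$rscc_min - runif(1, 0, 0.2),
                       occupancy_min = p$occupancy_min - runif(1, 0, 0.3),
                       rsr_good_max = p$rsr_good_max + runif(1, 0, 0.1),
                       rsr_max = p$rsr_max + runif(1, 0, 0.2))
    l1 <- evaluate_component(s, profile = p)$label
    l2 <- evaluate_component(s, profile = relaxed)$label
    expect_lte(rank(l2), rank(l1))
  }
})

test_that("worst-of aggregation is a bounded semilattice", {
  expect_equal(worst_label(c("Good", "Good", "Dubious")), "Dubious")
  expect_equal(worst_label(c(rep("Good", 10), "Bad")), "Bad")
  expect_equal(worst_label(c("Good", "Good")), "Good")
  expect_equal(worst_label(character()), "Good")
  labs <- c("Good", "Dubious", "Bad")
  for (a in labs) {
    expect_equal(worst_label(c(a, a)), a)                      # idempotent
    expect_equal(worst_label(c(a, "Good")), a)                 # Good neutral
    for (b in labs) {
      expect_equal(worst_label(c(a, b)), worst_label(c(b, a))) # commutative
      for (c_ in labs) {
        expect_equal(worst_label(c(worst_label(c(a, b)), c_)),
                     worst_label(c(a, worst_label(c(b, c_))))) # associative
      }
    }
  }
})

test_that("classify_pair aggregates worst-of and warns on empty sites", {
  m <- point_model(data.frame(comp = c("LIG", "GLY", "GLY"),
                              chain = c("L", "A", "A"),
                              seq = c(101, 1, 2),
                              het = c(TRUE, FALSE, FALSE),
                              x = c(0, 3, 4), y = 0, z = 0))
  lig <- extract_ligands(m)$ligands[[1]]
  site <- find_binding_site(m, lig)
  p <- redo_prof()
  st <- data.frame(res_key = c("LIG:L:101", "GLY:A:1", "GLY:A:2"),
                   rsr = c(0.06, 0.06, 0.2), rscc = c(0.97, 0.97, 0.97),
                   avg_occupancy = 1, owab = NA_real_)
  pr <- classify_pair(lig, site, st, profile = p)
  expect_equal(pr$ligand_label, "Good")
  expect_equal(pr$site_label, "Dubious")  # GLY:A:2 fails good-RSR only
  st$rscc[3] <- 0.5                        # now 2 conditions fail -> Bad
  pr2 <- classify_pair(lig, site, st, profile = p)
  expect_equal(pr2$site_label, "Bad")
  # empty site: label Good with a warning
  far <- point_model(data.frame(comp = c("LIG", "GLY"), chain = c("L", "A"),
                                seq = c(101, 1), het = c(TRUE, FALSE),
                                x = c(0, 40), y = 0, z = 0))
  flig <- extract_ligands(far)$ligands[[1]]
  fsite <- find_binding_site(far, flig)
  expect_warning(fpr <- classify_pair(flig, fsite,
                                      st[1, , drop = FALSE], profile = p),
                 "empty binding site")
  expect_equal(fpr$site_label, "Good")
})

test_that("profile files round-trip and enforce invariants", {
  tmp <- withr::local_tempfile(fileext = ".profile")
  for (p in default_profiles()) {
    save_profile(p, tmp)
    expect_equal(load_profile(tmp), p)
  }
  # disabled threshold encoded as 'off'
  p <- pdb_prof()
  p$owab_max <- NA_real_
  save_profile(p, tmp)
  expect_true(is.na(load_profile(tmp)$owab_max))
  writeLines(c("name=x", "source=PDB", "rscc_min=0.9", "occupancy_min=1",
               "rsr_good_max=0.5", "rsr_max=0.4", "tolerance=1",
               "site_cutoff=4.5", "bond_cutoff=2.1"), tmp)
  expect_error(load_profile(tmp), "rsr_good_max > rsr_max")
  writeLines(c("name=x", "source=PDB", "wibble=1"), tmp)
  expect_error(load_profile(tmp), "unknown profile key")
  # shipped template for literature-derived thresholds loads
  tpl <- system.file("extdata", "profiles", "iridium_template.profile",
                     package = "ligqc")
  expect_s3_class(load_profile(tpl), "ligqc_profile")
})
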