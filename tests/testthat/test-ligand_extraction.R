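test_that("default exclusion lists ship the expected members, disjoint", {
  lists <- default_exclusion_lists()
  expect_true(all(c("HOH", "SO4", "GOL", "EDO", "PEG", "PO4", "ACT", "DMS",
                    "CL", "BR", "NO3", "FMT", "MPD", "TRS", "EPE", "CIT")
                  %in% lists$blacklist))
  expect_true(all(c("NA", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
                    "CO", "CD", "HG") %in% lists$non_propagating))
  expect_length(intersect(lists$blacklist, lists$non_propagating), 0L)
  expect_error(exclusion_lists(c("SO4", "ZN"), "ZN"), "both lists")
})

test_that("exclusion list files accept comments and are user-extendable", {
  f <- withr::local_tempfile(lines = c("# custom", "xyz  ", "", "ABC # tail"))
  expect_setequal(read_exclusion_list(f), c("XYZ", "ABC"))
})

test_that("covalent_pairs uses a strict < cutoff on minimum atom distance", {
  # AAA-BBB at 1.8 (in); CCC at x=0 on a far y-row with DDD exactly 2.1
  # away (out: strict <, and 2.1 - 0 is the exact double of the cutoff)
  m <- point_model(data.frame(comp = c("AAA", "BBB", "CCC", "DDD"),
                              chain = "L", seq = 1:4, het = TRUE,
                              x = c(0, 1.8, 0, 2.1), y = c(0, 0, 50, 50),
                              z = 0))
  pairs <- covalent_pairs(m, 2.1)
  expect_equal(nrow(pairs), 1L)
  expect_equal(sort(unname(unlist(pairs[1, ]))), c("AAA:L:1", "BBB:L:2"))
  m1 <- point_model(data.frame(comp = "AAA", chain = "L", seq = 1, het = TRUE,
                               x = 0, y = 0, z = 0))
  expect_equal(nrow(covalent_pairs(m1, 2.1)), 0L)
})

test_that("isolated ligand is extracted; covalent contacts reject", {
  lists <- default_exclusion_lists()
  # inhibitor far from everything
  m <- point_model(data.frame(comp = c("GLY", "INH"), chain = c("A", "L"),
                              seq = c(1, 101), het = c(FALSE, TRUE),
                              x = c(0, 12), y = 0, z = 0))
  ext <- extract_ligands(m, lists)
  expect_length(ext$ligands, 1L)
  expect_equal(ext$ligands[[1]]$group_id, "INH:L:101")
  expect_equal(nrow(ext$rejections), 0L)
  # hetero residue 1.8 A from a polymer atom -> covalent_to_polymer
  m2 <- point_model(data.frame(comp = c("CYS", "INH"), chain = c("A", "L"),
                               seq = c(1, 101), het = c(FALSE, TRUE),
                               x = c(0, 1.8), y = 0, z = 0))
  ext2 <- extract_ligands(m2, lists)
  expect_length(ext2$ligands, 0L)
  expect_equal(ext2$rejections$reason, "covalent_to_polymer")
  # 1.8 A from a sulfate -> covalent_to_blacklisted
  m3 <- point_model(data.frame(comp = c("SO4", "INH"), chain = "L",
                               seq = c(100, 101), het = TRUE,
                               x = c(0, 1.8), y = 0, z = 0))
  ext3 <- extract_ligands(m3, lists)
  expect_length(ext3$ligands, 0L)
  expect_equal(ext3$rejections$reason, "covalent_to_blacklisted")
})

test_that("non-propagating metals neither reject nor bridge nor emit", {
  lists <- default_exclusion_lists()
  # ligand 2.0 A from ZN, everything else far -> retained, ZN not a component
  m <- point_model(data.frame(comp = c("INH", "ZN"), chain = c("L", "D"),
                              seq = c(101, 201), het = TRUE,
                              x = c(0, 2.0), y = 0, z = 0))
  ext <- extract_ligands(m, lists)
  expect_length(ext$ligands, 1L)
  expect_equal(ext$ligands[[1]]$components, "INH:L:101")
  expect_equal(nrow(ext$rejections), 0L)
  # two ligands bridged by a metal stay two ligands
  m2 <- point_model(data.frame(comp = c("AAA", "ZN", "BBB"),
                               chain = c("L", "D", "L"),
                               seq = c(101, 201, 102), het = TRUE,
                               x = c(0, 1.9, 3.8), y = 0, z = 0))
  ext2 <- extract_ligands(m2, lists)
  expect_length(ext2$ligands, 2L)
  # a ligand-metal-polymer bridge does not reject the ligand either
  m3 <- point_model(data.frame(comp = c("GLY", "ZN", "INH"),
                               chain = c("A", "D", "L"),
                               seq = c(1, 201, 101),
                               het = c(FALSE, TRUE, TRUE),
                               x = c(0, 1.9, 3.8), y = 0, z = 0))
  ext3 <- extract_ligands(m3, lists)
  expect_length(ext3$ligands, 1L)
  expect_equal(nrow(ext3$rejections), 0L)
})

test_that("covalently linked hetero residues group into one ligand", {
  m <- point_model(data.frame(comp = c("NAG", "NAG"), chain = "L",
                              seq = c(101, 102), het = TRUE,
                              x = c(0, 1.45), y = 0, z = 0))
  ext <- extract_ligands(m)
  expect_length(ext$ligands, 1L)
  expect_equal(ext$ligands[[1]]$components, c("NAG:L:101", "NAG:L:102"))
  expect_equal(ext$ligands[[1]]$group_id, "NAG:L:101+NAG:L:102")
})

test_that("blacklisted and water residues are never emitted as ligands", {
  m <- point_model(data.frame(comp = c("SO4", "HOH", "GOL"), chain = "S",
                              seq = 1:3, het = TRUE,
                              x = c(0, 10, 20), y = 0, z = 0))
  ext <- extract_ligands(m)
  expect_length(ext$ligands, 0L)
  expect_equal(nrow(ext$rejections), 0L)  # solvents are skipped, not rejected
})

test_that("grouping equals brute-force union of covalent pairs (seeded)", {
  lists <- default_exclusion_lists()
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:10, 1)
    df <- data.frame(comp = sprintf("L%02d", seq_len(n)), chain = "L",
                     seq = 100 + seq_len(n), het = TRUE,
                     x = runif(n, 0, 12), y = runif(n, 0, 12),
                     z = runif(n, 0, 12))
    m <- point_model(df)
    ext <- extract_ligands(m, lists)
    pairs <- covalent_pairs(m, 2.1)
    expected <- brute_groups(model_residues(m)$res_key, pairs)
    got <- lapply(ext$ligands, function(l) l$components)
    # brute groups touching nothing rejected/excluded here (all comps clean)
    expect_equal(got, expected, info = paste("seed", seed))
  }
})

test_that("extraction is invariant under residue reordering", {
  df <- data.frame(comp = c("AAA", "BBB", "CCC"), chain = "L",
                   seq = c(101, 102, 103), het = TRUE,
                   x = c(0, 1.4, 9), y = 0, z = 0)
  m1 <- point_model(df)
  m2 <- point_model(df[c(3, 1, 2), ])
  ids <- function(ext) vapply(ext$ligands, function(l) l$group_id, "")
  expect_equal(ids(extract_ligands(m1)), ids(extract_ligands(m2)))
})

test_that("rejection is monotone in the bond cutoff", {
  lists <- default_exclusion_lists()
  m <- point_model(data.frame(comp = c("GLY", "INH"), chain = c("A", "L"),
                              seq = c(1, 101), het = c(FALSE, TRUE),
                              x = c(0, 2.5), y = 0, z = 0))
  rejected_at <- function(cut) {
    nrow(extract_ligands(m, lists, bond_cutoff = cut)$rejections) > 0
  }
  for (cuts in list(c(2.1, 2.6), c(2.6, 3.5), c(1.0, 2.1))) {
    if (rejected_at(cuts[1])) expect_true(rejected_at(cuts[2]))
  }
  expect_false(rejected_at(2.1))
  expect_true(rejected_at(2.6))
})
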