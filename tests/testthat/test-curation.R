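test_that("saturated substituents never change the conjugated core", {
  fx <- molecules(toyFixtures())
  naph <- extractConjugatedCore(fx$naphthalene)
  methyl <- extractConjugatedCore(fx$methylnaphthalene)
  expect_identical(naph$core_key, methyl$core_key)
  expect_identical(naph$core_hac, 10L)
  expect_identical(extractConjugatedCore(fx$ethane)$core_key, "")
  expect_identical(extractConjugatedCore(fx$ethane)$core_hac, 0L)
  bi <- extractConjugatedCore(fx$biphenyl)
  biEthyl <- extractConjugatedCore(fx$ethylbiphenyl)
  expect_identical(bi$core_key, biEthyl$core_key)
  expect_identical(biEthyl$core_hac, 12L)
})

test_that("the core key is invariant under atom renumbering", {
  fx <- molecules(toyFixtures())
  for (nm in c("methylnaphthalene", "ethylbiphenyl", "nitrosobenzene")) {
    m <- fx[[nm]]
    ref <- extractConjugatedCore(m)$core_key
    set.seed(70)
    for (k in 1:10) {
      perm <- sample(nAtoms(m))
      expect_identical(extractConjugatedCore(permuteMolecule(m, perm))$core_key,
                       ref)
    }
  }
})

test_that("clustering discards small cores and counts singletons", {
  fx <- molecules(toyFixtures())
  # butadiene: conjugated core of 4 heavy atoms -> discarded
  butadiene <- Molecule("butadiene", rep("C", 4),
                        cbind(c(0, 1.4, 2.1, 3.5), c(0, 0, 1.1, 1.2),
                              0),
                        bonds = cbind(i = 1:3, j = 2:4,
                                      order = c(2, 1, 2)))
  # toluene-like molecule shares the benzene core
  toluene <- Molecule("toluene", c(rep("C", 6), "C"),
                      cbind(seq(0, 9, length.out = 7), 0.3 * (0:6), 0.1),
                      bonds = rbind(cbind(i = 1:6, j = c(2:6, 1), order = 1),
                                    cbind(i = 1, j = 7, order = 1)),
                      aromaticAtom = c(rep(TRUE, 6), FALSE),
                      aromaticBond = c(rep(TRUE, 6), FALSE))
  mols <- list(fx$benzene, toluene, fx$pyridine, fx$naphthalene, butadiene)
  cl <- clusterUniqueCores(mols)
  expect_identical(cl$discarded, "butadiene")
  expect_identical(length(cl$clusters), 3L)
  sizes <- vapply(cl$clusters, function(x) length(x$member_ids), integer(1))
  expect_identical(sort(sizes), c(1L, 1L, 2L))
  expect_identical(length(cl$singletons), 2L)
  benzCl <- Filter(function(x) "benzene" %in% x$member_ids, cl$clusters)[[1]]
  expect_true("toluene" %in% benzCl$member_ids)
  expect_identical(benzCl$core_hac, 6L)   # strict "< 6" discard keeps benzene
})

test_that("candidate filter applies element, size and nitroso rules", {
  fx <- toyFixtures()
  res <- filterTrainingCandidates(fx)
  rm <- res$removed
  expect_identical(rm$reason[rm$molecule_id == "chlorobenzene"], "element")
  expect_identical(rm$reason[rm$molecule_id == "chain26"], "hac")
  expect_true("naphthalene" %in% res$kept)
  # nitroso vs nitro discrimination (size rule relaxed to isolate it)
  rel <- filterTrainingCandidates(fx, hacRange = c(1L, 25L))
  expect_identical(rel$removed$reason[rel$removed$molecule_id ==
                                        "nitrosobenzene"], "nitroso")
  expect_true("nitrobenzene" %in% rel$kept)
  # exhaustive and exclusive partition
  ids <- vapply(molecules(fx), function(m) m@id, character(1))
  expect_identical(sort(c(rel$kept, rel$removed$molecule_id)),
                   sort(unname(ids)))
  expect_length(intersect(rel$kept, rel$removed$molecule_id), 0L)
})

test_that("ring filter removes alicyclic and polycyclic molecules", {
  fx <- toyFixtures()
  res <- qcdgeFilter(fx)
  rm <- res$removed
  expect_identical(rm$reason[rm$molecule_id == "cyclohexane"], "alicyclic")
  expect_true("pyridine" %in% res$kept)
  expect_identical(rm$reason[rm$molecule_id == "anthracene"], "ring_count")
  expect_identical(rm$reason[rm$molecule_id == "ethane"], "ring_count")
  expect_true("naphthalene" %in% res$kept)   # 2 aromatic rings
  # exact heavy-atom count flag
  strict <- qcdgeFilter(fx, exactHac = 10L)
  expect_true("naphthalene" %in% strict$kept)
  expect_identical(strict$removed$reason[strict$removed$molecule_id ==
                                           "pyridine"], "hac")
})

test_that("core-analogue sampling is capped, disjoint and deterministic", {
  mkCluster <- function(key, n)
    list(core_key = key, core_hac = 8L,
         member_ids = sprintf("%s_%02d", key, seq_len(n)))
  clusters <- list(mkCluster("a", 11), mkCluster("b", 2), mkCluster("c", 1))
  train <- c("a_01", "b_01", "c_01")
  test <- sampleCoreAnalogues(clusters, train, seed = 9)
  expect_length(intersect(test, train), 0L)
  expect_identical(sum(startsWith(test, "a")), 3L)   # capped at 3 of 10
  expect_identical(sum(startsWith(test, "b")), 1L)   # exhausted at 1
  expect_identical(sum(startsWith(test, "c")), 0L)   # no analogues
  expect_identical(sampleCoreAnalogues(clusters, train, seed = 9), test)
  # each test id shares a core with exactly one training molecule
  for (id in test) {
    owners <- vapply(clusters, function(cl) id %in% cl$member_ids,
                     logical(1))
    cl <- clusters[[which(owners)]]
    expect_identical(sum(train %in% cl$member_ids), 1L)
  }
})

test_that("parity split sends odd sorted positions to training", {
  sp <- paritySplit(as.character(1:10))
  expect_identical(sp$train, as.character(c(1, 3, 5, 7, 9)))
  expect_identical(sp$test, as.character(c(2, 4, 6, 8, 10)))
  shuffled <- paritySplit(as.character(c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)))
  expect_identical(shuffled, sp)
  big <- paritySplit(as.character(1:48000))
  expect_identical(length(big$train), 24000L)
  expect_identical(length(big$test), 24000L)
  expect_error(paritySplit(c("a", "a", "b")), "duplicate")
})
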