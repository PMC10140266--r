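# MCS computation, mapped RMSD, pose selection, and core SMARTS matching.

test_that("MCS of a molecule with itself covers every heavy atom", {
  for (smi in c("c1ccccc1", "CCO", "CC(=O)Nc1ccc(O)cc1")) {
    m <- parse_smiles(smi, smi)
    mm <- compute_mcs(m, m)
    expect_identical(mm$size, length(heavy <- which(m$elements != "H")))
    # identity mapping must be among the symmetry-equivalent matches
    keys <- vapply(mm$equivalents, function(p) all(p[, 1] == p[, 2]),
                   logical(1))
    expect_true(any(keys))
  }
})

test_that("benzene vs toluene MCS is the 6-atom ring", {
  mm <- compute_mcs(toluene(), benzene())
  expect_identical(mm$size, 6L)
  # the methyl carbon (atom 1 in the SMILES) is never mapped
  expect_false(1 %in% mm$pairs[, 1])
})

test_that("MCS errors on molecules without a common substructure", {
  expect_error(compute_mcs(parse_smiles("CC", "e"), parse_smiles("O", "w")),
               "insufficient common substructure")
})

test_that("MCS is deterministic for fixed inputs", {
  a <- parse_smiles("COc1ccc(CNC(=O)c2ccc(F)cc2)cc1", "a")
  b <- parse_smiles("COc1ccc(CNC(=O)c2ccc(Cl)cc2)cc1", "b")
  m1 <- compute_mcs(a, b)
  m2 <- compute_mcs(a, b)
  expect_identical(m1$pairs, m2$pairs)
  expect_identical(m1$size, 18L)
})

test_that("mapped RMSD obeys identity, translation, and closed-form cases", {
  set.seed(3)
  xyz <- matrix(rnorm(18), ncol = 3)
  map <- cbind(1:6, 1:6)
  expect_identical(mapped_rmsd(xyz, xyz, map), 0)
  expect_equal(mapped_rmsd(sweep(xyz, 2, c(3, 0, 0), "+"), xyz, map), 3,
               tolerance = 1e-12)
  # arbitrary-direction translation of norm d gives exactly d
  d <- c(1, 2, 2) # norm 3
  expect_equal(mapped_rmsd(sweep(xyz, 2, d, "+"), xyz, map), 3,
               tolerance = 1e-12)
  # 2 atoms, deviations 0 and 1
  q <- rbind(c(0, 0, 0), c(1, 0, 0))
  r <- matrix(0, 2, 3)
  expect_equal(mapped_rmsd(q, r, cbind(1:2, 1:2)), sqrt(1 / 2),
               tolerance = 1e-12)
  expect_error(mapped_rmsd(q, r, matrix(integer(0), ncol = 2)), "empty")
})

test_that("mapped RMSD is symmetric under swapping roles with inverted mapping", {
  set.seed(4)
  q <- matrix(rnorm(30), ncol = 3)
  r <- matrix(rnorm(30), ncol = 3)
  map <- cbind(sample(10), sample(10))
  expect_equal(mapped_rmsd(q, r, map), mapped_rmsd(r, q, map[, 2:1]),
               tolerance = 1e-12)
})

test_that("select_best_pose matches a brute-force rescan on 64 synthetic poses", {
  b <- benzene()
  ref <- hexagon_coords()
  mm <- compute_mcs(b, b)
  set.seed(7)
  scales <- sample(seq(0.1, 6.4, by = 0.1))
  ps <- perturb_poses(b, ref, scales, seed = 21)
  expect_length(ps$coords, 64)
  sel <- select_best_pose(ps, ref, mm)
  # oracle: rescan every pose independently
  rmsds <- vapply(ps$coords, function(xyz) mapped_rmsd(xyz, ref, mm),
                  numeric(1))
  expect_identical(sel$index, which.min(rmsds))
  expect_identical(sel$index, which.min(scales))
  # single pose
  one <- pose_set("bz", b, ps$coords[1])
  expect_identical(select_best_pose(one, ref, mm)$index, 1L)
  # monotone in displacement
  two <- perturb_poses(b, ref, c(2, 0.5), seed = 3, rot_per_ang = 0)
  expect_identical(select_best_pose(two, ref, mm)$index, 2L)
})

test_that("core SMARTS matching agrees with the OpenBabel matcher", {
  cases <- list(
    list(smi = "c1ccccc1", smarts = "c1ccccc1"),
    list(smi = "CCO", smarts = "c1ccccc1"),
    list(smi = "Cc1ccccc1", smarts = "c1ccccc1"),
    list(smi = "CC(=O)[O-]", smarts = "C(=O)[O-]"),
    list(smi = "c1ccncc1", smarts = "n"),
    list(smi = "CC(=O)Nc1ccc(O)cc1", smarts = "C(=O)N"),
    list(smi = "C1CCCCC1", smarts = "c1ccccc1")
  )
  for (cs in cases) {
    mol <- parse_smiles(cs$smi, cs$smi)
    got <- match_core(mol, cs$smarts)
    ob <- ChemmineOB::forEachMol("SMILES", cs$smi, identity)
    ob_n <- ChemmineOB::smartsSearch_OB(ob, cs$smarts)
    expect_identical(got$matched, ob_n > 0,
                     label = sprintf("%s ~ %s", cs$smi, cs$smarts))
    if (got$matched) {
      expect_true(all(got$atoms >= 1 & got$atoms <= length(mol$elements)))
      expect_false(anyDuplicated(got$atoms) > 0)
    } else {
      expect_length(got$atoms, 0)
    }
  }
})

test_that("benzene core match returns 6 ring atoms; invalid SMARTS errors", {
  got <- match_core(benzene(), "c1ccccc1")
  expect_true(got$matched)
  expect_length(got$atoms, 6)
  expect_false(match_core(parse_smiles("CCO", "e"), "c1ccccc1")$matched)
  expect_error(match_core(benzene(), "((("), "invalid SMARTS")
  expect_error(match_core(benzene(), "[Q]"), "invalid SMARTS")
})
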