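test_that("chi torsion matches constructed cis/trans arrangements", {
  # four coplanar atoms, cis: O4' and C4 on the same side
  res_cis <- rbind("O4'" = c(1, 1, 0), "C1'" = c(0, 1, 0),
                   "N9" = c(0, 0, 0), "C4" = c(1, 0, 0))
  expect_equal(chi_torsion(res_cis), 0)
  res_trans <- rbind("O4'" = c(-1, 1, 0), "C1'" = c(0, 1, 0),
                     "N9" = c(0, 0, 0), "C4" = c(1, 0, 0))
  expect_equal(abs(chi_torsion(res_trans)), 180)
})

test_that("chi torsion agrees with an independent dihedral construction", {
  set.seed(21)
  for (i in 1:100) {
    pts <- matrix(rnorm(12), 4, 3)
    res <- rbind("O4'" = pts[1, ], "C1'" = pts[2, ],
                 "N9" = pts[3, ], "C4" = pts[4, ])
    expect_equal(chi_torsion(res),
                 dihedral_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-6)
  }
})

test_that("missing atoms are reported by name", {
  res <- rbind("C1'" = c(0, 1, 0), "N9" = c(0, 0, 0), "C4" = c(1, 0, 0))
  expect_error(chi_torsion(res), "O4'")
})

test_that("syn/anti classification uses the (-90, 90] syn interval", {
  expect_identical(classify_gba(0), "syn")
  expect_identical(classify_gba(180), "anti")
  expect_identical(classify_gba(-120), "anti")
  expect_identical(classify_gba(90), "syn")
  expect_identical(classify_gba(-90), "anti") # boundary convention
  expect_identical(classify_gba(c(60, -170)), c("syn", "anti"))
})

test_that("twist angle recovers constructed rotations exactly", {
  for (tw in c(0, 30, -30, 48, -23)) {
    fx <- generate_stack_fixture("anti", "anti", twist_deg = tw)
    expect_equal(twist_angle(fx$lower, fx$upper), tw, tolerance = 1e-6)
  }
  # a large rotation swings the ring centroid past the stacking sanity
  # threshold but the twist itself is still recovered
  fx120 <- generate_stack_fixture("anti", "anti", twist_deg = 120)
  expect_warning(tw120 <- twist_angle(fx120$lower, fx120$upper), "6 A")
  expect_equal(tw120, 120, tolerance = 1e-6)
  # pure translation along the plane normal: zero twist
  fx0 <- generate_stack_fixture("syn", "anti", twist_deg = 0)
  expect_equal(twist_angle(fx0$lower, fx0$upper), 0, tolerance = 1e-9)
  # swapping the stack direction re-orients the axis, whose sign flip
  # compensates the reversed vector order: the apparent twist is unchanged
  fx <- generate_stack_fixture("anti", "anti", twist_deg = 35)
  expect_equal(twist_angle(fx$upper, fx$lower),
               twist_angle(fx$lower, fx$upper), tolerance = 1e-9)
})

test_that("fixtures honor the requested glycosidic conformations", {
  fx <- generate_stack_fixture("syn", "anti", twist_deg = 20)
  expect_identical(classify_gba(chi_torsion(fx$lower)), "syn")
  expect_identical(classify_gba(chi_torsion(fx$upper)), "anti")
  expect_equal(chi_torsion(fx$lower), 60, tolerance = 1e-6)
  expect_equal(chi_torsion(fx$upper), -120, tolerance = 1e-6)
})

test_that("implausible stacking separations warn", {
  fx <- generate_stack_fixture("anti", "anti", twist_deg = 10, rise_A = 8)
  expect_warning(twist_angle(fx$lower, fx$upper), "6 A")
})

test_that("overlap classes follow the GBA pair and context", {
  expect_identical(classify_overlap("anti", "anti", "same", "core"),
                   "same 5/6-ring")
  expect_identical(classify_overlap("syn", "syn", "same", "core"),
                   "same 5/6-ring")
  expect_identical(classify_overlap("syn", "anti", "same", "core"), "5-ring")
  expect_identical(classify_overlap("anti", "syn", "same", "core"),
                   "partial 6-ring")
  expect_identical(
    classify_overlap("a", "a", "opposite", "interface", annotation = "5/6r"),
    "5/6-ring")
  expect_identical(
    classify_overlap("a", "a", "opposite", "interface", annotation = "6r"),
    "6-ring")
  expect_error(classify_overlap("anti", "anti", "opposite", "core"),
               "interface")
  expect_error(classify_overlap("anti", "anti", "opposite", "interface"),
               "annotation")
})

test_that("PDB round trip preserves coordinates at format precision", {
  fx <- generate_stack_fixture("syn", "anti", twist_deg = 48)
  fx <- lapply(fx, round, 3) # PDB stores 3 decimals
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(fx, path)
  struct <- read_structure(path)
  expect_equal(sort(unique(struct$resno)), c(1, 2))
  lo <- residue_geometry(struct, 1, "A", 1)
  expect_equal(lo[rownames(fx$lower), ], fx$lower)
  expect_equal(twist_angle(residue_geometry(struct, 1, "A", 1),
                           residue_geometry(struct, 1, "A", 2)),
               48, tolerance = 1e-2) # 3-decimal coordinate rounding
})

test_that("multi-model files give one geometry set per model", {
  m1 <- generate_stack_fixture("anti", "anti", twist_deg = 30)
  m2 <- generate_stack_fixture("anti", "anti", twist_deg = 40)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(list(m1, m2), path)
  struct <- read_structure(path)
  expect_equal(sort(unique(struct$model)), c(1, 2))
  tw <- vapply(1:2, function(m) {
    twist_angle(residue_geometry(struct, m, "A", 1),
                residue_geometry(struct, m, "A", 2))
  }, numeric(1))
  expect_equal(tw, c(30, 40), tolerance = 1e-2)
})

test_that("ensemble twist summaries aggregate per stack and per class", {
  # 2 models x 2 stacks with known twists
  mk_model <- function(tw1, tw2) {
    f1 <- generate_stack_fixture("syn", "anti", twist_deg = tw1)
    f2 <- generate_stack_fixture("anti", "anti", twist_deg = tw2)
    # four residues: stack 1 = res 1/2, stack 2 = res 3/4 (shifted apart)
    shift <- function(m, dx) sweep(m, 2, c(dx, 0, 0), "+")
    list(f1$lower, f1$upper, shift(f2$lower, 30), shift(f2$upper, 30))
  }
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(list(mk_model(46, 20), mk_model(50, 24)), path)
  struct <- read_structure(path)
  stacks <- data.frame(
    chain5 = "A", res5 = c(1, 3), chain3 = "A", res3 = c(2, 4),
    gba5 = c("syn", "anti"), gba3 = c("anti", "anti")
  )
  res <- ensemble_twist_summary(struct, stacks)
  sa <- res$stacks[res$stacks$class == "sa", ]
  expect_equal(sa$mean_twist, 48, tolerance = 1e-2)
  expect_equal(sa$sd_twist, stats::sd(c(46, 50)), tolerance = 1e-2)
  expect_equal(sa$n_models, 2)
  aa <- res$classes[res$classes$class == "aa", ]
  expect_equal(aa$mean_twist, 22, tolerance = 1e-2)
  expect_equal(aa$n_obs, 2)

  # duplicated model: sd exactly 0
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(list(mk_model(46, 20), mk_model(46, 20)), path2)
  res2 <- ensemble_twist_summary(read_structure(path2), stacks)
  expect_true(all(res2$stacks$sd_twist == 0))

  # single model: sd reported as absent
  path3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(mk_model(46, 20), path3)
  res3 <- ensemble_twist_summary(read_structure(path3), stacks)
  expect_true(all(is.na(res3$stacks$sd_twist)))

  expect_error(ensemble_twist_summary(struct, stacks[0, ]), "empty")
})
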