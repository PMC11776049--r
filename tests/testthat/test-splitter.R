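test_that("split_lipid partitions the fixture POPC with exact bookkeeping", {
  topo <- fixture_topology("POPC")
  spec <- derive_split_spec(topo)
  st <- split_lipid(topo, spec)
  # 20 head atoms + V1, 32 tail atoms + V2
  expect_equal(nrow(st$head$atoms), 21L)
  expect_equal(nrow(st$tail$atoms), 33L)
  expect_equal(st$head$atoms$atom[21], "V1")
  expect_equal(st$tail$atoms$atom[33], "V2")
  # every original atom in exactly one moiety, unchanged properties
  orig <- topo$atoms[order(topo$atoms$atom), c("atom", "charge", "mass", "type")]
  real <- rbind(st$head$atoms[st$head$atoms$type != "VS", ],
                st$tail$atoms[st$tail$atoms$type != "VS", ])
  real <- real[order(real$atom), c("atom", "charge", "mass", "type")]
  rownames(orig) <- rownames(real) <- NULL
  expect_equal(real, orig)
  # charge sum preserved to 1e-6
  expect_equal(total_charge(st$head) + total_charge(st$tail),
               total_charge(topo), tolerance = 1e-6)
  # virtual sites are massless, chargeless, non-interacting
  vs <- rbind(st$head$atoms[21, ], st$tail$atoms[33, ])
  expect_true(all(vs$mass == 0))
  expect_true(all(vs$charge == 0))
  expect_true(all(vs$type == "VS"))
  # bond counting identity: cut removed, two vsite bonds added
  expect_equal(nrow(st$head$bonds) + nrow(st$tail$bonds),
               nrow(topo$bonds) - 1L + 2L)
  # cross-cut angles/dihedrals/pairs are dropped, internal ones kept
  expect_equal(nrow(st$head$angles) + nrow(st$tail$angles),
               nrow(topo$angles) - 3L)   # fixture has 3 cut-spanning angles
  expect_equal(nrow(st$head$dihedrals) + nrow(st$tail$dihedrals), 0L)
  expect_equal(nrow(st$head$pairs) + nrow(st$tail$pairs), 0L)
})

test_that("toy linear molecule splits with zero net moiety charges", {
  st <- split_lipid(toy_linear_topology(), toy_split_spec())
  expect_equal(st$head$atoms$atom, c("A", "B", "V1"))
  expect_equal(st$tail$atoms$atom, c("C", "D", "V2"))
  expect_equal(total_charge(st$head), 0.0, tolerance = 1e-12)
  expect_equal(total_charge(st$tail), 0.0, tolerance = 1e-12)
  # terminal cut falls back to the 2-atom linear construction
  expect_null(st$head$virtual_sites3)
  expect_equal(st$head$virtual_sites2$funct, 1L)
})

test_that("split errors name the offending atoms", {
  topo <- toy_linear_topology()
  expect_error(split_lipid(topo, split_spec("TOY", c("B", "C"),
                                            c("A", "B"), c("C", "Z"))),
               "Z")
  expect_error(split_lipid(topo, split_spec("TOY", c("A", "D"),
                                            c("A", "B"), c("C", "D"))),
               "absent")
})

test_that("split_system splits 2x64 POPC into 128 heads + 128 tails", {
  bl <- popc_bilayer_64()
  sp <- split_system(bl$frame, bl$topologies)
  mols <- sp$frame$molecules
  expect_equal(sum(mols$species == "POPCH"), 128L)
  expect_equal(sum(mols$species == "POPCT"), 128L)
  expect_equal(sum(mols$species == "SOL"),
               sum(bl$frame$molecules$species == "SOL"))
  # ordering contract: heads, then tails, then untouched species
  expect_equal(rle(mols$species)$values[1:2], c("POPCH", "POPCT"))
  # real-atom coordinates bit-identical
  im <- sp$index_map[!is.na(sp$index_map$old_index), ]
  expect_identical(sp$frame$atoms$x[im$new_index],
                   bl$frame$atoms$x[im$old_index])
  expect_identical(sp$frame$atoms$z[im$new_index],
                   bl$frame$atoms$z[im$old_index])
  # mass and charge conservation (virtual sites massless/chargeless)
  mass_of <- function(topos, frame) {
    per <- vapply(topos, function(t) sum(t$atoms$mass), 0.0)
    sum(per[frame$molecules$species] * 1)
  }
  expect_equal(mass_of(sp$topologies, sp$frame),
               mass_of(bl$topologies, bl$frame), tolerance = 1e-6)
  q_split <- sum(vapply(sp$topologies, total_charge,
                        0.0)[sp$frame$molecules$species])
  q_orig <- sum(vapply(bl$topologies, total_charge,
                       0.0)[bl$frame$molecules$species])
  expect_equal(q_split, q_orig, tolerance = 1e-6)
})

test_that("skip species pass through untouched and re-splitting errors", {
  bl <- build_bilayer(c(POPC = 4, CHL = 4), waters_per_lipid = 2, seed = 3)
  sp <- split_system(bl$frame, bl$topologies)
  expect_equal(sum(sp$frame$molecules$species == "CHL"),
               sum(bl$frame$molecules$species == "CHL"))
  chl_old <- bl$frame$atoms[bl$frame$atoms$resname == "CHL", ]
  chl_new <- sp$frame$atoms[sp$frame$atoms$resname == "CHL", ]
  expect_equal(chl_new$x, chl_old$x)
  expect_error(split_system(sp$frame, sp$topologies, specs = sp$specs),
               "already split")
  # unknown lipid without spec or skip entry
  expect_error(split_system(bl$frame, bl$topologies,
                            specs = list(),
                            skip_species = c("SOL", "NA", "CL", "POPC")),
               "CHL")
})

test_that("virtual sites land on the removed neighbour and are equivariant", {
  bl <- small_bilayer()
  sp <- split_system(bl$frame, bl$topologies)
  # V1 coincides with the original C2 position for every head
  mols <- sp$frame$molecules
  heads <- mols[mols$species == "POPCH", ][1:5, ]
  orig_mols <- bl$frame$molecules
  popc_orig <- orig_mols[orig_mols$species == "POPC", ]
  for (i in seq_len(nrow(heads))) {
    rng <- heads$first[i]:(heads$first[i] + heads$n[i] - 1L)
    v1 <- as.numeric(sp$frame$atoms[rng[sp$frame$atoms$name[rng] == "V1"],
                                    c("x", "y", "z")])
    org <- orig_mols[orig_mols$species == "POPC", ][i, ]
    orng <- org$first:(org$first + org$n - 1L)
    c2 <- as.numeric(bl$frame$atoms[orng[bl$frame$atoms$name[orng] == "C2"],
                                    c("x", "y", "z")])
    expect_lt(sqrt(sum((v1 - c2)^2)), 1e-3)
  }
  # construction reproduces the target, and is rotation/translation
  # equivariant
  topo <- sp$topologies$POPCH
  vs <- topo$virtual_sites3[1L, ]
  keep <- topo$atoms$type != "VS"
  h1 <- mols[mols$species == "POPCH", ][1L, ]
  rng <- h1$first:(h1$first + h1$n - 1L)
  co <- as.matrix(sp$frame$atoms[rng, c("x", "y", "z")])[keep, , drop = FALSE]
  site <- place_virtual_site(co, vs)
  expect_equal(site,
               as.numeric(sp$frame$atoms[rng[!keep], c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  shift <- c(1, 1, 1)
  expect_equal(place_virtual_site(sweep(co, 2, shift, `+`), vs),
               site + shift, tolerance = 1e-9, ignore_attr = TRUE)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(place_virtual_site(co %*% t(R), vs),
               as.numeric(R %*% site), tolerance = 1e-9, ignore_attr = TRUE)
  # collinear constructing atoms are rejected for the 3-atom construction
  degenerate <- co
  degenerate[vs$aj, ] <- degenerate[vs$ai, ] + c(0.1, 0, 0)
  degenerate[vs$ak, ] <- degenerate[vs$ai, ] + c(0.2, 0, 0)
  expect_error(place_virtual_site(degenerate, vs), "collinear")
})
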