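test_that("freshly split fixture pairs every head with its own tail", {
  sp <- split_small()
  plan <- plan_merge(sp)
  expect_equal(nrow(plan$pairs), 32L)
  expect_lt(plan$max_junction_distance, 0.2)
  # heads and tails are emitted in the same lipid order, so pair i is
  # head-block molecule i with tail-block molecule i
  mols <- sp$frame$molecules
  specs <- sp$specs
  heads <- mols$molid[mols$species %in%
                        vapply(specs, function(s) s$head_resname, "")]
  tails <- mols$molid[mols$species %in%
                        vapply(specs, function(s) s$tail_resname, "")]
  expect_setequal(plan$pairs$head_mol, heads)
  expect_equal(plan$pairs$tail_mol[order(plan$pairs$head_mol)],
               tails[order(heads)])
})

test_that("junction distances use minimum image in xy, plain z", {
  hp <- matrix(c(0.1, 3, 2), 1)
  tp <- matrix(c(5.9, 3, 2.0), 1)
  D <- splitmem:::junction_distance_matrix(hp, tp, c(6, 6, 10))
  expect_equal(D[1, 1], 0.2, tolerance = 1e-12)
  # z is never wrapped
  tp2 <- matrix(c(0.1, 3, 11), 1)
  D2 <- splitmem:::junction_distance_matrix(hp, tp2, c(6, 6, 10))
  expect_equal(D2[1, 1], 9, tolerance = 1e-12)
})

test_that("greedy equals brute-force optimum with unique nearest neighbours", {
  # 3x3 instance with well separated pairs
  D <- matrix(c(0.1, 2.0, 3.0,
                2.5, 0.2, 2.2,
                3.5, 2.1, 0.3), 3, 3, byrow = TRUE)
  g <- splitmem:::greedy_assignment(D)
  b <- brute_force_assignment(D)
  h <- splitmem:::hungarian_assignment(D)
  expect_equal(g, b)
  expect_equal(h, b)
})

test_that("hungarian matches brute force and never exceeds greedy cost", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    D <- matrix(runif(n * n, 0, 5), n, n)
    h <- splitmem:::hungarian_assignment(D)
    b <- brute_force_assignment(D)
    g <- splitmem:::greedy_assignment(D)
    cost <- function(a) sum(D[cbind(seq_len(n), a)])
    expect_equal(cost(h), cost(b), tolerance = 1e-9)
    expect_gte(cost(g) + 1e-12, cost(h))
    expect_equal(sort(h), seq_len(n))   # bijection
  }
})

test_that("pairing respects lipid type and leaflet and detects mismatch", {
  sp <- split_small()
  plan <- plan_merge(sp)
  lf <- assign_leaflets(sp$frame)
  lab <- setNames(as.character(lf$leaflet), lf$molid)
  spdf <- sp$frame$molecules
  for (r in seq_len(nrow(plan$pairs))) {
    hm <- plan$pairs$head_mol[r]; tm <- plan$pairs$tail_mol[r]
    expect_equal(lab[as.character(hm)], lab[as.character(tm)],
                 ignore_attr = TRUE)
    expect_equal(sub("H$", "", spdf$species[spdf$molid == hm]),
                 sub("T$", "", spdf$species[spdf$molid == tm]))
  }
  # drop one tail molecule -> count mismatch error naming the class
  broken <- sp
  tailm <- spdf[spdf$species == "POPCT", ][1L, ]
  keep <- setdiff(seq_len(nrow(sp$frame$atoms)),
                  tailm$first:(tailm$first + tailm$n - 1L))
  broken$frame <- system_frame(sp$frame$atoms[keep, ], sp$frame$box)
  expect_error(plan_merge(broken), "mismatch.*POPC")
})

test_that("merge plan is invariant under global xy translation", {
  sp <- split_small()
  plan <- plan_merge(sp)
  moved <- sp
  a <- moved$frame$atoms
  a$x <- (a$x + 1.7) %% moved$frame$box[1]
  a$y <- (a$y + 2.9) %% moved$frame$box[2]
  moved$frame <- system_frame(a, moved$frame$box)
  plan2 <- plan_merge(moved)
  expect_equal(plan$pairs[c("head_mol", "tail_mol")],
               plan2$pairs[c("head_mol", "tail_mol")])
  expect_equal(plan$pairs$distance, plan2$pairs$distance, tolerance = 1e-9)
})

test_that("split -> merge is the identity on an unmoved system", {
  bl <- small_bilayer()
  sp <- split_system(bl$frame, bl$topologies)
  merged <- apply_merge(sp)
  expect_identical(merged$frame$atoms, bl$frame$atoms)
  # topology equality against a freshly built reference, section by section
  for (spn in names(sp$specs))
    expect_topology_equal(merged$topologies[[spn]], fixture_topology(spn))
  # per-lipid net charge preserved
  for (spn in names(sp$specs))
    expect_equal(total_charge(merged$topologies[[spn]]),
                 total_charge(bl$topologies[[spn]]), tolerance = 1e-6)
  # merged frame survives a GRO round trip with the original atom count
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(merged$frame, f)
  expect_equal(nrow(read_gro(f)$atoms), nrow(bl$frame$atoms))
})

test_that("strain report flags and sorts distant junctions", {
  plan <- structure(list(
    pairs = data.frame(head_mol = 1:3, tail_mol = 4:6,
                       distance = c(0.1, 0.8, 0.5),
                       leaflet = "upper", species = "POPC"),
    unmatched = list(), max_junction_distance = 0.8),
    class = "merge_plan")
  rep0 <- strain_report(plan, threshold = 1.0)
  expect_equal(nrow(rep0$flagged), 0L)
  rep1 <- strain_report(plan, threshold = 0.3)
  expect_equal(nrow(rep1$flagged), 2L)
  expect_equal(rep1$flagged$distance, c(0.8, 0.5))   # descending
  # headgroup-fixing posres files support the re-equilibration recipe
  sp <- split_small()
  dir <- withr::local_tempdir()
  rep2 <- strain_report(plan_merge(sp), threshold = 0.0, split = sp,
                        posres_dir = dir)
  expect_true(length(rep2$posres_files) >= 1)
  fixed <- read_itp(rep2$posres_files[1])
  expect_equal(nrow(fixed$position_restraints),
               sum(fixed$atoms$type != "VS"))
})
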