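# shared fixtures, built once per test run and cached
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_bilayer <- function() cached("small_bilayer", function()
  build_bilayer(c(POPC = 8, POPS = 8), seed = 7))

popc_bilayer_64 <- function() cached("popc64", function()
  build_bilayer(c(POPC = 64), apl = 0.658, waters_per_lipid = 2, seed = 1))

split_small <- function() cached("split_small", function()
  split_system(small_bilayer()$frame, small_bilayer()$topologies))

# toy 4-atom linear molecule A-B-C-D with charges summing to zero on both
# sides of the B-C cut
toy_linear_topology <- function() {
  atoms <- data.frame(nr = 1:4, type = c("A", "B", "C", "D"), resnr = 1L,
                      resname = "TOY", atom = c("A", "B", "C", "D"),
                      cgnr = 1:4, charge = c(0.3, -0.3, 0.1, -0.1),
                      mass = c(12, 12, 12, 12), stringsAsFactors = FALSE)
  bonds <- data.frame(ai = 1:3, aj = 2:4, funct = 1L,
                      params = "0.15300 1000.0", stringsAsFactors = FALSE)
  molecule_topology("TOY", atoms, bonds = bonds)
}

toy_split_spec <- function() {
  split_spec("TOY", cut_bond = c("B", "C"),
             head_atoms = c("A", "B"), tail_atoms = c("C", "D"))
}

# brute-force optimal assignment by enumerating permutations (n <= 7)
brute_force_assignment <- function(D) {
  n <- nrow(D)
  perms <- permutations_of(n)
  costs <- vapply(perms, function(p) sum(D[cbind(seq_len(n), p)]), 0.0)
  perms[[which.min(costs)]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (p in permutations_of(n - 1L))
      out[[length(out) + 1L]] <- c(k, rest[p])
  }
  out
}

expect_topology_equal <- function(a, b) {
  for (sec in c("atoms", "bonds", "pairs", "angles", "dihedrals")) {
    ta <- a[[sec]]; tb <- b[[sec]]
    rownames(ta) <- rownames(tb) <- NULL
    expect_equal(ta, tb, info = paste("section", sec, "of", a$name))
  }
}
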