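test_that("parse_structure assigns roles and builds regions from a minimal PDB", {
  txt <- pdb_lines(list(
    atom_rec(1, "P", "DA", "A", 1, 0, 0, 0, elem = "P"),
    atom_rec(2, "C1'", "DA", "A", 1, 1, 0, 0, elem = "C"),
    atom_rec(3, "N9", "DA", "A", 1, 2, 0, 0, elem = "N")))
  sys <- parse_structure(txt)
  expect_length(sys$regions, 2L)
  alphas <- vapply(sys$regions, `[[`, "", "alpha")
  bb <- sys$regions[[which(alphas == "BB")]]
  nb <- sys$regions[[which(alphas == "NB")]]
  expect_setequal(trimws(sys$atoms$elety[bb$atom_idx]), c("P", "C1'"))
  expect_setequal(trimws(sys$atoms$elety[nb$atom_idx]), "N9")
  expect_true(all(sys$atoms$role == "solute"))
})

test_that("water-only input yields zero regions and water roles", {
  txt <- pdb_lines(list(
    atom_rec(1, "O", "HOH", "W", 1, 0, 0, 0, type = "HETATM", elem = "O"),
    atom_rec(2, "O", "HOH", "W", 2, 5, 0, 0, type = "HETATM", elem = "O")))
  sys <- parse_structure(txt)
  expect_length(sys$regions, 0L)
  expect_true(all(sys$atoms$role == "water"))
})

test_that("model selection pulls coordinates from the requested model only", {
  sys <- generate_duplex("GC")
  traj <- simulate_shell_dynamics(
    sys, schedule = annealing_schedule(rate = 25, duration = 20,
                                       replicates = 1),
    stride_ps = 10, seed = 5)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, tf)
  s2 <- read_structure(tf, model = 2)
  expect_equal(s2$model_count, 3L)
  expect_equal(nrow(s2$atoms), nrow(traj$atoms))
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               trajectory_frame(traj, 2), ignore_attr = TRUE,
               tolerance = 1e-3)
  expect_error(read_structure(tf, model = 9),
               class = "parch_validation_error")
})

test_that("RNA O2' belongs to the backbone region", {
  sys <- generate_duplex("GU", type = "rna")
  g_bb <- Filter(function(r) r$resname == "G" && r$alpha == "BB",
                 sys$regions)[[1]]
  expect_true("O2'" %in% trimws(sys$atoms$elety[g_bb$atom_idx]))
})

test_that("the dT partition splits 20 atoms into 11 backbone + 9 base", {
  names_dt <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
                "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7",
                "C6")
  recs <- lapply(seq_along(names_dt), function(i)
    atom_rec(i, names_dt[i], "DT", "A", 1, i * 1.0, 0, 0,
             elem = substr(names_dt[i], 1, 1)))
  sys <- parse_structure(pdb_lines(recs))
  alphas <- vapply(sys$regions, `[[`, "", "alpha")
  expect_length(sys$regions[[which(alphas == "BB")]]$atom_idx, 11L)
  expect_length(sys$regions[[which(alphas == "NB")]]$atom_idx, 9L)
})

test_that("a 5'-terminal residue without phosphate still yields a sugar-only BB", {
  recs <- list(atom_rec(1, "C1'", "DG", "A", 1, 0, 0, 0),
               atom_rec(2, "O4'", "DG", "A", 1, 1, 0, 0),
               atom_rec(3, "N9", "DG", "A", 1, 2, 0, 0))
  sys <- parse_structure(pdb_lines(recs))
  alphas <- vapply(sys$regions, `[[`, "", "alpha")
  bb <- sys$regions[[which(alphas == "BB")]]
  expect_setequal(trimws(sys$atoms$elety[bb$atom_idx]), c("C1'", "O4'"))
})

test_that("a nucleotide with no sugar atoms is malformed", {
  recs <- list(atom_rec(1, "N9", "DG", "A", 1, 0, 0, 0),
               atom_rec(2, "C8", "DG", "A", 1, 1, 0, 0))
  expect_error(parse_structure(pdb_lines(recs)),
               class = "parch_validation_error")
})

test_that("unrecognized solute residues are excluded with a warning", {
  recs <- list(atom_rec(1, "C1", "XYZ", "A", 1, 0, 0, 0),
               atom_rec(2, "CA", "GLY", "A", 2, 5, 0, 0))
  expect_warning(sys <- parse_structure(pdb_lines(recs)),
                 class = "parch_warning")
  expect_length(sys$regions, 1L)
  expect_equal(sys$regions[[1]]$alpha, "AA")
})

test_that("BB and NB partition every nucleotide completely and disjointly", {
  for (seqs in list(c("ACGT", "dna"), c("ACGU", "rna"))) {
    sys <- expect_no_warning(generate_duplex(seqs[1], type = seqs[2]))
    atoms <- sys$atoms
    res_key <- paste(atoms$chain, atoms$resno)
    for (key in unique(res_key)) {
      res_idx <- which(res_key == key)
      regs <- Filter(function(r) paste(r$chain, r$resno) == key, sys$regions)
      expect_setequal(vapply(regs, `[[`, "", "alpha"), c("BB", "NB"))
      idx <- lapply(regs, `[[`, "atom_idx")
      expect_length(intersect(idx[[1]], idx[[2]]), 0L)
      expect_setequal(c(idx[[1]], idx[[2]]), res_idx)
    }
  }
})

test_that("region membership is invariant under atom record order", {
  sys <- generate_duplex("AT")
  atoms <- sys$atoms
  perm <- rev(seq_len(nrow(atoms)))
  shuffled <- atoms[perm, ]
  regs <- classify_regions(shuffled)
  orig <- classify_regions(atoms)
  sig <- function(regions, at) sort(vapply(regions, function(r)
    paste(region_id(r), paste(sort(trimws(at$elety[r$atom_idx])),
                              collapse = ","), sep = "|"), ""))
  expect_equal(sig(regs, shuffled), sig(orig, atoms))
})

test_that("annotate_bfactor writes clamped two-decimal PV and round-trips", {
  txt <- pdb_lines(list(
    atom_rec(1, "P", "DA", "A", 1, 0.123, 4.567, -8.910),
    atom_rec(2, "C1'", "DA", "A", 1, 1, 0, 0),
    atom_rec(3, "N9", "DA", "A", 1, 2, 0, 0),
    atom_rec(4, "O", "HOH", "W", 2, 9, 9, 9, type = "HETATM", elem = "O")))
  sys <- parse_structure(txt)
  tab <- data.frame(chain = "A", resseq = 1L, resname = "DA",
                    alpha = c("BB", "NB"), PV = c(4.28, 0))
  out <- annotate_bfactor(sys, tab)
  lines <- strsplit(out, "\n")[[1]]
  atom_lines <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  expect_equal(substr(atom_lines[1], 61, 66), "  4.28")
  expect_equal(substr(atom_lines[3], 61, 66), "  0.00")  # NB region
  expect_equal(substr(atom_lines[4], 61, 66), "  0.00")  # water
  # round trip: coordinates exact at field precision, PV within half a unit
  # of the last printed digit
  sys2 <- parse_structure(out)
  expect_equal(as.matrix(sys2$atoms[, c("x", "y", "z")]),
               as.matrix(sys$atoms[, c("x", "y", "z")]), ignore_attr = TRUE)
  expect_lt(abs(sys2$atoms$b[1] - 4.28), 0.005)

  tab_big <- transform(tab, PV = c(1234.5, 0))
  expect_warning(out_big <- annotate_bfactor(sys, tab_big),
                 class = "parch_warning")
  expect_equal(substr(grep("^ATOM", strsplit(out_big, "\n")[[1]],
                           value = TRUE)[1], 61, 66), "999.99")
})

test_that("annotation fails loudly when a region has no PV", {
  sys <- parse_structure(pdb_lines(list(
    atom_rec(1, "P", "DA", "A", 1, 0, 0, 0),
    atom_rec(2, "C1'", "DA", "A", 1, 1, 0, 0),
    atom_rec(3, "N9", "DA", "A", 1, 2, 0, 0))))
  tab <- data.frame(chain = "A", resseq = 1L, resname = "DA",
                    alpha = "BB", PV = 1)
  expect_error(annotate_bfactor(sys, tab), "A:1:DA:NB",
               class = "parch_validation_error")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  txt <- pdb_lines(list(
    atom_rec(1, "P", "DA", "A", 1, 0, 0, 0, alt = "A", occ = 0.4),
    atom_rec(2, "P", "DA", "A", 1, 5, 0, 0, alt = "B", occ = 0.6),
    atom_rec(3, "C1'", "DA", "A", 1, 1, 0, 0),
    atom_rec(4, "N9", "DA", "A", 1, 2, 0, 0)))
  sys <- parse_structure(txt)
  p_rows <- which(trimws(sys$atoms$elety) == "P")
  expect_length(p_rows, 1L)
  expect_equal(sys$atoms$x[p_rows], 5)
})
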