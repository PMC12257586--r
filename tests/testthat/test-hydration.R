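region_stub <- function(atom_idx, class = "nucleotide", chain = "A",
                        resno = 1L, resname = "DA", alpha = "BB") {
  list(chain = chain, resno = resno, insert = NA, resname = resname,
       class = class, alpha = alpha, atom_idx = atom_idx)
}

test_that("the counting boundary is closed at the cutoff", {
  frame <- rbind(c(0, 0, 0), c(4.49, 0, 0), c(4.51, 0, 0), c(4.5, 0, 0))
  reg <- region_stub(1L)
  expect_equal(count_waters_frame(frame, reg, 2:3, 4.5), 1L)
  # a water at exactly the cutoff distance counts
  expect_equal(count_waters_frame(frame, reg, 2:4, 4.5), 2L)
  expect_equal(count_waters_frame(frame, reg, integer(0), 4.5), 0L)
})

test_that("out-of-bounds region atom indices are an error", {
  frame <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(count_waters_frame(frame, region_stub(5L), 2L, 4.5),
               class = "parch_validation_error")
})

test_that("cell-list and brute-force counts match the pairwise oracle", {
  set.seed(77)
  for (i in 1:20) {
    with_box <- i %% 2 == 0
    box <- if (with_box) c(16, 18, 14) else NULL
    n_at <- sample(3:8, 1)
    n_w <- sample(30:120, 1)
    frame <- rbind(matrix(runif(3 * n_at, 2, 12), ncol = 3),
                   matrix(runif(3 * n_w, 0, if (with_box) 16 else 25),
                          ncol = 3))
    reg <- region_stub(seq_len(n_at))
    wat <- n_at + seq_len(n_w)
    oracle <- oracle_count(frame[reg$atom_idx, , drop = FALSE],
                           frame[wat, , drop = FALSE], 4.5, box)
    expect_identical(count_waters_frame(frame, reg, wat, 4.5, box, "cell"),
                     oracle)
    expect_identical(count_waters_frame(frame, reg, wat, 4.5, box, "brute"),
                     oracle)
  }
})

test_that("minimum-image counting sees waters across the boundary", {
  box <- c(10, 10, 10)
  frame <- rbind(c(0.5, 5, 5), c(9.8, 5, 5))  # 0.7 A apart through the wall
  reg <- region_stub(1L)
  expect_equal(count_waters_frame(frame, reg, 2L, 1.0, box), 1L)
  expect_equal(count_waters_frame(frame, reg, 2L, 1.0, box = NULL), 0L)
})

toy_two_frame_traj <- function() {
  # frame 1: 3 waters within 4.5 of atom 1; frame 2: 5
  atoms <- data.frame(
    type = "ATOM", eleno = 1:7, elety = c("CA", rep("O", 6)),
    alt = NA, resid = c("ALA", rep("HOH", 6)), chain = c("A", rep("W", 6)),
    resno = c(1L, 2:7), insert = NA, x = 0, y = 0, z = 0, o = 1, b = 0,
    segid = NA, elesy = c("C", rep("O", 6)), charge = NA,
    role = c("solute", rep("water", 6)), stringsAsFactors = FALSE)
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
              c(9, 0, 0), c(10, 0, 0), c(11, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
              c(3.1, 0, 0), c(2.9, 0, 0), c(11, 0, 0))
  parch_trajectory(atoms, rbind(as.vector(t(f1)), as.vector(t(f2))),
                   times_ps = c(0, 10))
}

test_that("count_series reproduces hand counts and stride arithmetic", {
  traj <- toy_two_frame_traj()
  cs <- count_series(traj, cutoff = 4.5)
  expect_s3_class(cs, "parch_counts")
  expect_equal(cs$count, c(3L, 5L))
  expect_equal(cs$alpha, c("AA", "AA"))
  # identical frames give a constant series
  traj2 <- parch_trajectory(traj$atoms,
                            traj$xyz[c(1, 1, 1, 1), , drop = FALSE],
                            times_ps = c(0, 10, 20, 30))
  expect_equal(unique(count_series(traj2, cutoff = 4.5)$count), 3L)
  expect_equal(nrow(count_series(traj2, cutoff = 4.5, stride = 2)), 2L)
  expect_error(count_series(traj2, cutoff = 4.5, stride = 4),
               class = "parch_validation_error")
})

test_that("counting is monotone under added waters and never under-counts", {
  set.seed(31)
  sys <- generate_duplex("AT")
  sched <- annealing_schedule(rate = 50, duration = 10, replicates = 1)
  traj <- simulate_shell_dynamics(sys, schedule = sched, stride_ps = 10,
                                  seed = 3)
  cs <- count_series(traj, regions = sys$regions, cutoff = 4.5)
  # regions may double-count shared waters, so the per-frame sum over
  # regions is at least the count around the whole solute
  whole <- region_stub(which(traj$atoms$role == "solute"))
  wat <- water_oxygens(traj$atoms)
  for (f in 1:2) {
    total <- count_waters_frame(trajectory_frame(traj, f), whole, wat, 4.5)
    expect_gte(sum(cs$count[cs$time_ps == traj$times_ps[f]]), total)
  }
  # adding a water inside a region's cutoff raises (only) that count
  fr <- trajectory_frame(traj, 1)
  r1 <- sys$regions[[1]]
  base_ct <- count_waters_frame(fr, r1, wat, 4.5)
  new_w <- fr[r1$atom_idx[1], ] + c(2, 0, 0)
  fr2 <- rbind(fr, new_w)
  expect_equal(count_waters_frame(fr2, r1, c(wat, nrow(fr2)), 4.5),
               base_ct + 1L)
  far_w <- fr[r1$atom_idx[1], ] + c(500, 0, 0)
  fr3 <- rbind(fr, far_w)
  expect_equal(count_waters_frame(fr3, r1, c(wat, nrow(fr3)), 4.5), base_ct)
})

test_that("counts CSV round-trips through the documented schema", {
  traj <- toy_two_frame_traj()
  cs <- count_series(traj, cutoff = 4.5)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_counts(cs, tf)
  back <- read_counts(tf)
  expect_equal(as.data.frame(back), as.data.frame(cs))
  expect_error(read_counts(withr::local_tempfile(fileext = ".csv")),
               class = "parch_io_error")
})

test_that("g(r) is flat for ideal-gas points and localized for a shell", {
  box <- c(20, 20, 20)
  n_b <- 300
  n_frames <- 40
  set.seed(5)
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(1 + n_b), elety = c("P", rep("O", n_b)),
    alt = NA, resid = c("DA", rep("HOH", n_b)), chain = c("A", rep("W", n_b)),
    resno = seq_len(1 + n_b), insert = NA, x = 0, y = 0, z = 0, o = 1, b = 0,
    segid = NA, elesy = c("P", rep("O", n_b)), charge = NA,
    role = c("solute", rep("water", n_b)), stringsAsFactors = FALSE)
  xyz <- t(vapply(seq_len(n_frames), function(f)
    c(10, 10, 10, as.vector(t(matrix(runif(3 * n_b, 0, 20), ncol = 3)))),
    numeric(3 * (1 + n_b))))
  traj <- parch_trajectory(atoms, xyz, times_ps = 10 * (seq_len(n_frames) - 1),
                           box = box)
  rdf <- radial_distribution(traj, sel_a = 1L, sel_b = 2:(n_b + 1),
                             r_max = 8, bin_width = 0.5)
  mid <- rdf$bin_centers > 2 & rdf$bin_centers < 8
  counts_per_bin <- n_frames * n_b / 8000 *
    (4 / 3 * pi * diff(seq(0, 8, 0.5)^3))[mid]
  se <- 1 / sqrt(counts_per_bin)
  expect_true(all(abs(rdf$g[mid] - 1) < 3 * pmax(se, 0.05)))

  # all B on a 3.1 A sphere (mid-bin) around a central A
  sph <- 40
  u <- matrix(rnorm(3 * sph), ncol = 3)
  u <- 3.1 * u / sqrt(rowSums(u^2))
  atoms2 <- atoms[seq_len(1 + sph), ]
  xyz2 <- matrix(c(10, 10, 10, as.vector(t(u + 10))), nrow = 1)
  traj2 <- parch_trajectory(atoms2, xyz2, times_ps = 0, box = box)
  rdf2 <- radial_distribution(traj2, 1L, 2:(sph + 1), r_max = 6,
                              bin_width = 0.5)
  expect_equal(which.max(rdf2$g), findInterval(3.1, seq(0, 6, 0.5)))
  expect_equal(sum(rdf2$g > 0), 1L)
})

test_that("RDF histogram equals brute-force distance binning on a fixture", {
  set.seed(13)
  box <- c(12, 12, 12)
  na <- 4; nb <- 25
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(na + nb),
    elety = c(rep("P", na), rep("O", nb)), alt = NA,
    resid = c(rep("DA", na), rep("HOH", nb)),
    chain = c(rep("A", na), rep("W", nb)), resno = seq_len(na + nb),
    insert = NA, x = 0, y = 0, z = 0, o = 1, b = 0, segid = NA,
    elesy = c(rep("P", na), rep("O", nb)), charge = NA,
    role = c(rep("solute", na), rep("water", nb)), stringsAsFactors = FALSE)
  xyz <- rbind(runif(3 * (na + nb), 0, 12), runif(3 * (na + nb), 0, 12))
  traj <- parch_trajectory(atoms, xyz, times_ps = c(0, 10), box = box)
  r_max <- 5; bw <- 0.25
  expect_warning(rdf <- radial_distribution(traj, seq_len(na),
                                            na + seq_len(nb), r_max = 7,
                                            bin_width = bw),
                 class = "parch_warning")  # r_max > L/2 truncation
  # oracle: bin every pair distance by hand
  breaks <- seq(0, 6, bw)
  h <- numeric(length(breaks) - 1)
  for (f in 1:2) {
    fr <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    for (i in seq_len(na)) for (j in na + seq_len(nb)) {
      d <- oracle_dist(fr[i, ], fr[j, ], box)
      if (d <= 6) {
        b <- max(1L, findInterval(d, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE))
        h[b] <- h[b] + 1
      }
    }
  }
  shell <- 4 / 3 * pi * diff(breaks^3)
  g_oracle <- h / (2 * na * (nb / prod(box)) * shell)
  expect_equal(rdf$g, g_oracle)
  expect_equal(rdf$r_max, 6)
})
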