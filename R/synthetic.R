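#' @title Synthetic fixtures: toy structures, dynamics and count series
#' @name synthetic
#' @description
#' Desk-scale stand-ins for the real protocol, all seed-deterministic: an
#' idealized helical duplex with correct PDB v3 atom names (backbone on the
#' outside of the cylinder, bases pointing inward), overdamped
#' reflected-random-walk water dynamics inside the hydration shell under the
#' annealing temperature ramp (the solute is frozen, mimicking position
#' restraints), AR(1) count series with a known analytic autocorrelation,
#' and a buried-versus-exposed two-region system exercising the
#' zero-exposure rule. These generators emulate count fluctuations, not
#' forces; they make the PARCH math testable without an MD engine.
NULL

# ---- idealized duplex ------------------------------------------------------

# Cylindrical atom templates: (radius A, angle deg, z offset A). The
# backbone sits at large radius, the base walks inward toward the helix
# axis; values are schematic, chosen for clean region separation rather
# than chemical accuracy.
.tpl_backbone <- list(
  P = c(9.4, -24, -1.9), OP1 = c(10.3, -28, -2.3), OP2 = c(9.5, -27, -0.9),
  `O5'` = c(8.8, -18, -1.6), `C5'` = c(8.9, -12, -1.0),
  `C4'` = c(8.3, -7, -0.5), `O4'` = c(7.4, -6, 0.3), `C3'` = c(8.6, -2, -0.9),
  `O3'` = c(8.8, 3, -1.5), `C2'` = c(7.8, 0, -0.2), `C1'` = c(6.9, 0, 0.0))
.tpl_o2p <- list(`O2'` = c(8.5, 4, 0.4))
.tpl_purine <- list(
  N9 = c(5.6, 2, 0.0), C8 = c(5.3, 12, 0.2), N7 = c(4.4, 14, 0.3),
  C5 = c(4.0, 5, 0.1), C6 = c(3.0, 2, 0.2), N1 = c(2.4, -8, 0.1),
  C2 = c(3.2, -13, 0.0), N3 = c(4.2, -11, -0.1), C4 = c(4.7, -3, 0.0))
.tpl_pyrimidine <- list(
  N1 = c(5.6, 2, 0.0), C2 = c(4.9, -7, 0.0), O2 = c(5.3, -14, -0.1),
  N3 = c(3.9, -6, 0.1), C4 = c(3.5, 3, 0.2), C5 = c(4.2, 11, 0.2),
  C6 = c(5.2, 10, 0.1))

.base_template <- function(base) {
  switch(base,
         A = c(.tpl_purine, list(N6 = c(2.2, 10, 0.4))),
         G = c(.tpl_purine, list(O6 = c(2.2, 10, 0.4), N2 = c(3.0, -22, -0.1))),
         C = c(.tpl_pyrimidine, list(N4 = c(2.5, 5, 0.3))),
         T = c(.tpl_pyrimidine, list(O4 = c(2.5, 5, 0.3), C7 = c(3.9, 20, 0.3))),
         U = c(.tpl_pyrimidine, list(O4 = c(2.5, 5, 0.3))),
         stop_validation("unknown base '", base, "'"))
}

.residue_template <- function(base, rna, terminal5) {
  bb <- .tpl_backbone
  if (terminal5) bb <- bb[setdiff(names(bb), c("P", "OP1", "OP2"))]
  if (rna) bb <- c(bb, .tpl_o2p)
  c(bb, .base_template(base))
}

.complement <- c(A = "T", T = "A", G = "C", C = "G")

#' Generate an idealized helical duplex
#'
#' Builds a synthetic helix with correct PDB v3 atom names: every residue is
#' a rigid template (backbone at 7-10 A radius, base inward toward the axis)
#' placed by the declared twist/rise. DNA sequences get a complementary
#' antiparallel second strand (B-form geometry: 36 deg, 3.38 A); RNA yields
#' a single A-form strand (32.7 deg, 2.81 A). 5'-terminal residues carry no
#' phosphate. The geometry is schematic — regions classify cleanly and
#' backbone/base exposure is realistic in sign, but it is not a refined
#' structure.
#'
#' @param sequence nucleotide string over `A C G T` (DNA) or `A C G U`
#'   (RNA), length >= 2.
#' @param type `"auto"` (U present: RNA; otherwise DNA), `"dna"` or `"rna"`.
#' @param twist,rise helical parameters (deg, Angstrom); defaults per form.
#' @return a `parch_system` with a `helix` element recording the generator
#'   parameters.
#' @export
generate_duplex <- function(sequence, type = c("auto", "dna", "rna"),
                            twist = NULL, rise = NULL) {
  type <- match.arg(type)
  letters <- strsplit(toupper(sequence), "")[[1L]]
  if (length(letters) < 2L) stop_validation("sequence must have length >= 2")
  if (!all(letters %in% c("A", "C", "G", "T", "U")))
    stop_validation("invalid letter(s) in sequence: ",
                    paste(setdiff(letters, c("A", "C", "G", "T", "U")),
                          collapse = ", "))
  if (type == "auto") type <- if ("U" %in% letters) "rna" else "dna"
  if (type == "dna" && "U" %in% letters)
    stop_validation("U is not a DNA letter")
  if (type == "rna" && "T" %in% letters)
    stop_validation("T is not an RNA letter")
  rna <- type == "rna"
  twist <- twist %||% if (rna) 32.7 else 36
  rise <- rise %||% if (rna) 2.81 else 3.38
  L <- length(letters)
  place <- function(base, level, phi0, chain, resno, terminal5, eleno0) {
    tpl <- .residue_template(base, rna, terminal5)
    ang <- (level - 1L) * twist + phi0 + vapply(tpl, `[[`, 0, 2L)
    r <- vapply(tpl, `[[`, 0, 1L)
    z <- (level - 1L) * rise + vapply(tpl, `[[`, 0, 3L)
    nm <- names(tpl)
    data.frame(
      type = "ATOM", eleno = eleno0 + seq_along(tpl) - 1L, elety = nm,
      alt = NA_character_,
      resid = if (rna) base else paste0("D", base), chain = chain,
      resno = resno, insert = NA_character_,
      x = r * cos(ang * pi / 180), y = r * sin(ang * pi / 180), z = z,
      o = 1, b = 0, segid = NA_character_,
      elesy = substr(nm, 1L, 1L), charge = NA_character_,
      role = "solute", stringsAsFactors = FALSE)
  }
  rows <- list()
  eleno <- 1L
  for (j in seq_len(L)) {
    df <- place(letters[j], level = j, phi0 = 0, chain = "A", resno = j,
                terminal5 = j == 1L, eleno0 = eleno)
    eleno <- eleno + nrow(df)
    rows[[length(rows) + 1L]] <- df
  }
  if (!rna) {
    comp <- unname(.complement[letters])
    for (j in seq_len(L)) {
      # strand B residue j pairs with strand A residue L + 1 - j
      df <- place(comp[L + 1L - j], level = L + 1L - j, phi0 = 168,
                  chain = "B", resno = j, terminal5 = j == 1L, eleno0 = eleno)
      eleno <- eleno + nrow(df)
      rows[[length(rows) + 1L]] <- df
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  sys <- .system_from_atoms(atoms, parch_aliases())
  sys$helix <- list(twist = twist, rise = rise, form = if (rna) "A" else "B")
  sys
}

# ---- toy shell dynamics ----------------------------------------------------

#' Simulate restrained-solute water dynamics under the annealing ramp
#'
#' Waters perform overdamped random walks confined to the hydration shell
#' (water oxygen between `steric_floor` and `shell_thickness` of the nearest
#' solute atom): each recorded step draws an isotropic Gaussian displacement
#' with per-axis variance `2 D(T) dt`, where D(T) scales linearly with the
#' instantaneous ramp temperature, and steps leaving the shell are rejected
#' (the water stays put that step — a hard-wall move that preserves the
#' uniform stationary distribution over the accessible volume). Solute and
#' ions are immobile, mimicking position restraints. A fixed seed gives a
#' bit-identical trajectory.
#'
#' @param system a `parch_system`; if it carries no waters, a shell is
#'   generated first with [build_hydration_shell()].
#' @param schedule an [annealing_schedule()]; its duration sets the number
#'   of recorded frames.
#' @param shell_thickness,steric_floor shell geometry, Angstrom.
#' @param diffusion_300K water diffusion coefficient at 300 K, A^2/ps
#'   (0.23 is the experimental bulk value).
#' @param stride_ps recording interval, ps (default 10, the ramp
#'   granularity of 1 K per 10 ps).
#' @param n_waters optionally subsample the shell to this many waters.
#' @param seed integer seed.
#' @return a `parch_trajectory` with a `temperature_K` attribute giving the
#'   ramp temperature at each frame.
#' @export
simulate_shell_dynamics <- function(system, schedule = annealing_schedule(),
                                    shell_thickness = 4.5, steric_floor = 1.5,
                                    diffusion_300K = 0.23, stride_ps = 10,
                                    n_waters = NULL, seed = 1L) {
  if (diffusion_300K <= 0) stop_validation("diffusion_300K must be > 0")
  if (stride_ps <= 0) stop_validation("stride_ps must be > 0")
  n_frames <- floor(schedule$duration / stride_ps) + 1L
  if (n_frames < 1L) stop_validation("schedule yields zero frames")
  if (!length(water_oxygens(system)))
    system <- build_hydration_shell(system, thickness = shell_thickness,
                                    source = "generate",
                                    steric_floor = steric_floor, seed = seed)
  atoms <- system$atoms
  sol <- as.matrix(atoms[atoms$role %in% c("solute", "ion"),
                         c("x", "y", "z")])
  o_idx <- water_oxygens(atoms)
  if (!is.null(n_waters) && n_waters < length(o_idx)) {
    keep_res <- with_seed(seed + 2L, sample(atoms$resno[o_idx], n_waters))
    drop <- atoms$role == "water" & !(atoms$resno %in% keep_res)
    atoms <- atoms[!drop, , drop = FALSE]
    rownames(atoms) <- NULL
    o_idx <- water_oxygens(atoms)
  }
  # water hydrogens ride rigidly with their oxygen (same residue)
  wat_rows <- which(atoms$role == "water")
  o_of <- o_idx[match(atoms$resno[wat_rows], atoms$resno[o_idx])]
  times <- stride_ps * (seq_len(n_frames) - 1L)
  temps <- schedule_temperature(schedule, times)
  nat <- nrow(atoms)
  xyz <- matrix(NA_real_, n_frames, 3L * nat)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  frame_vec <- function(p) as.vector(t(p))
  xyz[1L, ] <- frame_vec(pos)
  m <- length(o_idx)
  with_seed(seed, {
    opos <- pos[o_idx, , drop = FALSE]
    for (f in seq_len(n_frames - 1L)) {
      sdv <- sqrt(2 * diffusion_300K * (temps[f] / 300) * stride_ps)
      prop <- opos + matrix(stats::rnorm(3L * m, sd = sdv), ncol = 3L)
      d2 <- min_dist2(prop, sol)
      ok <- d2 >= steric_floor^2 & d2 <= shell_thickness^2
      shift <- prop - opos
      shift[!ok, ] <- 0
      opos <- opos + shift
      # every water atom shifts by its residue oxygen's displacement
      pos[wat_rows, ] <- pos[wat_rows, ] + shift[match(o_of, o_idx), ]
      xyz[f + 1L, ] <- frame_vec(pos)
    }
  })
  traj <- parch_trajectory(atoms, xyz, times, box = system$box)
  attr(traj, "temperature_K") <- temps
  traj
}

# ---- AR(1) series ----------------------------------------------------------

#' Generate a stationary AR(1) series
#'
#' x_t = mu + phi (x_(t-1) - mu) + eps_t with Gaussian innovations and
#' stationary initialization. Its raw (non-mean-subtracted) autocorrelation
#' is known in closed form — see [ar1_autocov()] — which makes it the
#' analytic oracle for the estimator chain.
#'
#' @param n series length (>= 2).
#' @param mu mean.
#' @param phi lag-1 coefficient, |phi| < 1.
#' @param sigma innovation standard deviation (>= 0).
#' @param dt sample spacing, ps.
#' @param seed integer seed.
#' @return list with `series`, `times`, `dt` and the generating parameters.
#' @export
generate_ar1 <- function(n, mu = 5, phi = 0.8, sigma = 1, dt = 1, seed = 1L) {
  if (n < 2L) stop_validation("n must be >= 2")
  if (abs(phi) >= 1) stop_validation("|phi| must be < 1")
  if (sigma < 0) stop_validation("sigma must be >= 0")
  x <- with_seed(seed, {
    x <- numeric(n)
    x[1L] <- mu + stats::rnorm(1L, sd = sigma / sqrt(1 - phi^2))
    eps <- stats::rnorm(n - 1L, sd = sigma)
    for (t in seq_len(n - 1L)) x[t + 1L] <- mu + phi * (x[t] - mu) + eps[t]
    x
  })
  list(series = x, times = dt * (seq_len(n) - 1L), dt = dt,
       mu = mu, phi = phi, sigma = sigma, seed = seed)
}

#' Analytic raw autocovariance of a stationary AR(1)
#'
#' E[x_t x_(t+k)] = mu^2 + phi^k sigma^2 / (1 - phi^2).
#'
#' @param mu,phi,sigma AR(1) parameters.
#' @param k lag index (vector, in samples).
#' @return numeric vector.
#' @export
ar1_autocov <- function(mu, phi, sigma, k) {
  mu^2 + phi^abs(k) * sigma^2 / (1 - phi^2)
}

# ---- zwitterionic lysine reference -----------------------------------------

#' Toy zwitterionic-lysine reference system
#'
#' A single free lysine residue (charged amino and carboxylate termini, i.e.
#' the zwitterion) with schematic extended-chain coordinates and standard
#' PDB atom names. It classifies as one AA region and serves as the
#' synthetic stand-in for the reference run of the scale: fully
#' water-exposed, counted at the amino-acid cutoff. The numeric Cbar_ref of
#' the original protocol is not published, so every `parch_table` records
#' which calibration produced it.
#'
#' @return a `parch_system` with one AA region.
#' @export
reference_lysine_system <- function() {
  nm <- c("N", "CA", "C", "O", "OXT", "CB", "CG", "CD", "CE", "NZ")
  xyz <- rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.3, 0.7, 0), c(1.4, 1.9, 0.2),
               c(2.3, -0.1, -0.2), c(0, -1.0, 1.2), c(1.0, -2.1, 1.2),
               c(0.9, -3.0, 2.4), c(1.9, -4.1, 2.4), c(1.8, -5.0, 3.6))
  atoms <- data.frame(
    type = "ATOM", eleno = seq_along(nm), elety = nm, alt = NA_character_,
    resid = "LYS", chain = "R", resno = 1L, insert = NA_character_,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0,
    segid = NA_character_, elesy = substr(nm, 1L, 1L),
    charge = NA_character_, role = "solute", stringsAsFactors = FALSE)
  .system_from_atoms(atoms, parch_aliases())
}

#' Calibrate against the toy lysine reference
#'
#' Runs [reference_lysine_system()] through [simulate_shell_dynamics()] (at
#' the protein shell thickness of 4.15 A), counts waters at the amino-acid
#' cutoff of 3.15 A, and calibrates with [calibrate_reference()] over
#' `replicates` independent seeds. This is the package's shipped,
#' regenerable calibration recipe; a production calibration would use the
#' same counting on a real annealing run of lysine.
#'
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @param n_frames recorded frames per replicate.
#' @param stride_ps recording interval, ps.
#' @param replicates number of reference replicates.
#' @param config a [parch_config()].
#' @return a `parch_calibration`.
#' @export
toy_lysine_calibration <- function(seed = 1L, n_frames = 150L, stride_ps = 10,
                                   replicates = 3L, config = parch_config()) {
  sys <- reference_lysine_system()
  duration <- (n_frames - 1L) * stride_ps
  sched <- annealing_schedule(rate = 500 / duration, duration = duration,
                              replicates = replicates)
  counts <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    traj <- simulate_shell_dynamics(sys, schedule = sched,
                                    shell_thickness = 4.15,
                                    stride_ps = stride_ps,
                                    seed = seed + r - 1L)
    count_series(traj, regions = sys$regions, cutoff = 3.15,
                 replicate_id = r)
  }))
  calibrate_reference(counts, config = config,
                      provenance = sprintf(
                        "toy zwitterionic lysine, shell 4.15 A, cutoff 3.15 A, %d x %d frames, stride %g ps, seed %d",
                        replicates, n_frames, stride_ps, seed))
}

# ---- buried vs exposed fixture ---------------------------------------------

#' Buried-versus-exposed two-region fixture
#'
#' A dense ball of frozen pseudo-atoms (grid spacing 1.6 A, radius 6 A)
#' occludes its central residue completely: no point accessible to water
#' (>= 1.5 A from every atom) comes within the amino-acid counting cutoff
#' of the central atoms, so its count series is identically zero and its
#' PARCH value is exactly 0 by the zero-exposure rule. A three-atom stalk
#' protruding from the ball forms the exposed residue, which shell waters
#' visit constantly. Residues are labeled as alanines so they classify as
#' single AA regions.
#'
#' @param seed integer seed for shell generation and dynamics.
#' @param n_frames recorded frames.
#' @param stride_ps recording interval, ps.
#' @return list with `system`, `trajectory`, and the region ids `buried_id`,
#'   `exposed_id`.
#' @export
buried_vs_exposed_fixture <- function(seed = 1L, n_frames = 120L,
                                      stride_ps = 10) {
  spacing <- 1.6
  g <- seq(-6, 6, by = spacing)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(grid^2))
  ball <- grid[r <= 6, , drop = FALSE]
  rr <- sqrt(rowSums(ball^2))
  buried <- ball[rr <= 2.0, , drop = FALSE]
  shell_atoms <- ball[rr > 2.0, , drop = FALSE]
  stalk <- rbind(c(0, 0, 7.6), c(0, 0, 9.2), c(0, 0, 10.8))
  mk <- function(xyz, resno, eleno0) data.frame(
    type = "ATOM", eleno = eleno0 + seq_len(nrow(xyz)) - 1L,
    elety = paste0("C", seq_len(nrow(xyz))), alt = NA_character_,
    resid = "ALA", chain = "S", resno = resno, insert = NA_character_,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0,
    segid = NA_character_, elesy = "C", charge = NA_character_,
    role = "solute", stringsAsFactors = FALSE)
  atoms <- rbind(mk(buried, 1L, 1L),
                 mk(stalk, 2L, nrow(buried) + 1L),
                 mk(shell_atoms, 3L, nrow(buried) + nrow(stalk) + 1L))
  sys <- .system_from_atoms(atoms, parch_aliases())
  duration <- (n_frames - 1L) * stride_ps
  sched <- annealing_schedule(T_start = 300, T_end = 800,
                              rate = 500 / duration, duration = duration,
                              replicates = 1L)
  traj <- simulate_shell_dynamics(sys, schedule = sched,
                                  shell_thickness = 4.5, stride_ps = stride_ps,
                                  seed = seed)
  list(system = sys, trajectory = traj,
       buried_id = "S:1:ALA:AA", exposed_id = "S:2:ALA:AA")
}
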