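#' @title System preparation for PARCH annealing runs
#' @name sysprep
#' @description
#' The PARCH protocol strips a structure of bulk solvent, rebuilds a thin
#' water shell around the solute (4.5 A for nucleic acids, 4.15 A for
#' proteins, set from the backbone-phosphorus/water-oxygen RDF), neutralizes
#' with counterions placed at least 3 A from the molecular surface and from
#' each other, and boxes the system 3 A beyond the shell. The annealing
#' itself (300 to 800 K at 1 K / 10 ps, restrained, in triplicate) is run by
#' an external MD engine — or by [simulate_shell_dynamics()] for desk-scale
#' work — from the plain-text descriptor emitted here.
NULL

# Number density of liquid water, molecules per cubic Angstrom.
.WATER_DENSITY <- 0.0334

.solute_xyz <- function(system) {
  i <- which(system$atoms$role == "solute")
  if (length(i) == 0L) stop_validation("system has no solute atoms")
  as.matrix(system$atoms[i, c("x", "y", "z")])
}

.next_eleno <- function(atoms) if (nrow(atoms)) max(atoms$eleno) + 1L else 1L

.water_rows <- function(o_xyz, h1_xyz, h2_xyz, start_eleno, start_resno) {
  n <- nrow(o_xyz)
  mk <- function(elety, elesy, xyz, off) data.frame(
    type = "HETATM", eleno = start_eleno + off + 3L * (seq_len(n) - 1L),
    elety = elety, alt = NA_character_, resid = "HOH", chain = "W",
    resno = start_resno + seq_len(n) - 1L, insert = NA_character_,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0,
    segid = NA_character_, elesy = elesy, charge = NA_character_,
    role = "water", stringsAsFactors = FALSE)
  out <- rbind(mk("O", "O", o_xyz, 0L), mk("H1", "H", h1_xyz, 1L),
               mk("H2", "H", h2_xyz, 2L))
  out[order(out$resno, out$eleno), , drop = FALSE]
}

# Rigid 3-site water geometry (0.9572 A O-H, 104.52 deg), random orientation.
.orient_hydrogens <- function(o_xyz) {
  n <- nrow(o_xyz)
  u <- matrix(stats::rnorm(3L * n), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v <- v - u * rowSums(u * v)
  v <- v / sqrt(rowSums(v^2))
  half <- 104.52 / 2 * pi / 180
  d <- 0.9572
  h1 <- o_xyz + d * (cos(half) * u + sin(half) * v)
  h2 <- o_xyz + d * (cos(half) * u - sin(half) * v)
  list(h1 = h1, h2 = h2)
}

#' Build the rehydration shell
#'
#' Removes all existing waters and surrounds the solute with a water shell:
#' the retained water oxygens are exactly those within `thickness` of at
#' least one solute atom and at least `steric_floor` away from every solute
#' atom. Candidates come either from the stripped original solvent
#' (`source = "retain"`) or from a seeded, jittered cubic lattice at liquid
#' water density (`source = "generate"`); `"auto"` retains when the input had
#' waters and generates otherwise. Generated waters are rigid 3-site; all
#' distance tests use the oxygen only.
#'
#' @param system a `parch_system`.
#' @param thickness shell thickness in Angstrom (4.5 for nucleic acids;
#'   use 4.15 for proteins).
#' @param source `"auto"`, `"retain"` or `"generate"`.
#' @param steric_floor minimum water-oxygen to solute distance, Angstrom.
#' @param seed integer seed for lattice jitter and hydrogen orientation.
#' @return a `parch_system` whose waters are exactly the shell waters.
#' @export
build_hydration_shell <- function(system, thickness = 4.5,
                                  source = c("auto", "retain", "generate"),
                                  steric_floor = 1.5, seed = 1L) {
  source <- match.arg(source)
  if (!is.numeric(thickness) || thickness <= 0)
    stop_validation("shell thickness must be > 0")
  sol <- .solute_xyz(system)
  atoms <- system$atoms
  wat_o <- which(atoms$role == "water" & .water_oxygen_mask(atoms))
  if (source == "auto") source <- if (length(wat_o)) "retain" else "generate"

  if (source == "retain") {
    if (length(wat_o) == 0L)
      stop_validation("shell construction: no waters to retain in input system")
    d2 <- min_dist2(as.matrix(atoms[wat_o, c("x", "y", "z")]), sol)
    # waters are kept/dropped as whole residues (chain+resno key)
    is_wat <- atoms$role == "water"
    wkey <- paste(atoms$chain, atoms$resno)
    keep_keys <- unique(wkey[wat_o][d2 <= thickness^2 & d2 >= steric_floor^2])
    keep <- !is_wat | wkey %in% keep_keys
    new_atoms <- atoms[keep, , drop = FALSE]
  } else {
    spacing <- .WATER_DENSITY^(-1 / 3)
    lo <- apply(sol, 2L, min) - thickness - spacing / 2
    hi <- apply(sol, 2L, max) + thickness + spacing / 2
    grid <- expand.grid(x = seq(lo[1], hi[1], by = spacing),
                        y = seq(lo[2], hi[2], by = spacing),
                        z = seq(lo[3], hi[3], by = spacing))
    cand <- with_seed(seed, {
      jit <- matrix(stats::runif(3L * nrow(grid), -spacing / 4, spacing / 4),
                    ncol = 3L)
      as.matrix(grid) + jit
    })
    d2 <- min_dist2(cand, sol)
    o_xyz <- cand[d2 <= thickness^2 & d2 >= steric_floor^2, , drop = FALSE]
    if (nrow(o_xyz) == 0L)
      stop_validation("shell construction: no candidate waters fit the shell")
    h <- with_seed(seed + 1L, .orient_hydrogens(o_xyz))
    new_atoms <- atoms[atoms$role != "water", , drop = FALSE]
    wr <- .water_rows(o_xyz, h$h1, h$h2, .next_eleno(new_atoms),
                      start_resno = 1L)
    new_atoms <- rbind(new_atoms, wr[, names(new_atoms), drop = FALSE])
  }
  rownames(new_atoms) <- NULL
  if (!any(new_atoms$role == "water"))
    warn_parch("hydration shell is empty (thickness ", thickness, " A)")
  out <- .system_from_atoms(new_atoms, system$aliases %||% parch_aliases(),
                            box = system$box, model_count = system$model_count)
  out
}

#' Neutralizing counterion placement
#'
#' Adds `abs(net_charge)` monovalent counterions (Na+ for a negative solute,
#' Cl- for a positive one; `species` overrides) by seeded rejection sampling
#' inside the box, requiring every ion to lie at least `min_dist` from every
#' solute atom and from every other ion, and clear of water oxygens by the
#' steric floor. The "molecular surface" is taken as distance to the nearest
#' solute atom. Placement is reproducible for a fixed seed.
#'
#' @param system a `parch_system`.
#' @param net_charge integer net charge of the solute to neutralize;
#'   0 returns the system unchanged.
#' @param min_dist minimum ion-solute and ion-ion distance, Angstrom.
#' @param seed integer seed.
#' @param species ion residue name; default chosen from the charge sign.
#' @param box orthorhombic box edges; defaults to `system$box` or
#'   [compute_box()] with a 3 A margin.
#' @param max_attempts rejection-sampling budget.
#' @return a `parch_system` with the ions appended.
#' @export
place_counterions <- function(system, net_charge, min_dist = 3.0, seed = 1L,
                              species = NULL, box = NULL,
                              max_attempts = 20000L) {
  if (!is.numeric(min_dist) || min_dist <= 0)
    stop_validation("min_dist must be > 0")
  net_charge <- as.integer(net_charge)
  if (net_charge == 0L) return(system)
  n_ions <- abs(net_charge)
  species <- species %||% if (net_charge < 0L) "NA" else "CL"
  box <- check_box(box %||% system$box %||% compute_box(system, margin = 3))
  xyz_all <- as.matrix(system$atoms[, c("x", "y", "z")])
  # box centered on the system: sampling origin is its lower corner
  origin <- (apply(xyz_all, 2L, min) + apply(xyz_all, 2L, max)) / 2 - box / 2
  sol <- .solute_xyz(system)
  wato <- which(system$atoms$role == "water" & .water_oxygen_mask(system$atoms))
  wxyz <- as.matrix(system$atoms[wato, c("x", "y", "z"), drop = FALSE])
  placed <- matrix(numeric(0), 0L, 3L)
  attempts <- 0L
  with_seed(seed, {
    while (nrow(placed) < n_ions) {
      if (attempts >= max_attempts)
        stop_validation("counterion placement infeasible after ", attempts,
                        " attempts (", nrow(placed), "/", n_ions, " placed)")
      attempts <- attempts + 1L
      p <- origin + stats::runif(3L) * box
      ok <- min_dist2(rbind(p), sol) >= min_dist^2
      if (ok && nrow(placed))
        ok <- min_dist2(rbind(p), placed) >= min_dist^2
      if (ok && nrow(wxyz))
        ok <- min_dist2(rbind(p), wxyz) >= 1.5^2
      if (ok) placed <- rbind(placed, p)
    }
  })
  atoms <- system$atoms
  elesy <- if (species %in% c("NA", "SOD")) "NA" else
    if (species %in% c("CL", "CLA")) "CL" else species
  ions <- data.frame(
    type = "HETATM", eleno = .next_eleno(atoms) + seq_len(n_ions) - 1L,
    elety = species, alt = NA_character_, resid = species, chain = "I",
    resno = seq_len(n_ions), insert = NA_character_,
    x = placed[, 1L], y = placed[, 2L], z = placed[, 3L], o = 1, b = 0,
    segid = NA_character_, elesy = elesy, charge = NA_character_,
    role = "ion", stringsAsFactors = FALSE)
  new_atoms <- rbind(atoms, ions[, names(atoms), drop = FALSE])
  rownames(new_atoms) <- NULL
  .system_from_atoms(new_atoms, system$aliases %||% parch_aliases(),
                     box = system$box, model_count = system$model_count)
}

#' Simulation box from system extent
#'
#' Orthorhombic box with each edge equal to the coordinate span of all atoms
#' (shell waters included) plus `margin` on both sides — the protocol sets
#' the boundary 3 A beyond the outer edge of the water shell.
#'
#' @param system a `parch_system`.
#' @param margin margin per side, Angstrom.
#' @return numeric length-3 box edge lengths.
#' @export
compute_box <- function(system, margin = 3.0) {
  if (margin < 0) stop_validation("margin must be >= 0")
  xyz <- as.matrix(system$atoms[, c("x", "y", "z")])
  if (nrow(xyz) == 0L) stop_validation("empty system")
  unname(apply(xyz, 2L, max) - apply(xyz, 2L, min) + 2 * margin)
}

# ---- annealing schedule ----------------------------------------------------

#' Annealing schedule descriptor
#'
#' The restrained heating protocol during which water counts are recorded:
#' 300 to 800 K at 0.1 K/ps (1 K per 10 ps), 5000 ps, position restraints of
#' 10000 kJ mol-1 nm-2, in triplicate. Any of rate/duration may be derived
#' from the others; an inconsistent triple is rejected.
#'
#' @param T_start,T_end temperatures, K.
#' @param rate heating rate, K/ps.
#' @param duration ps; default `(T_end - T_start) / rate`.
#' @param restraint_fc position-restraint force constant, kJ mol-1 nm-2.
#' @param replicates number of independent annealing replicates.
#' @return an `annealing_schedule` object.
#' @export
annealing_schedule <- function(T_start = 300, T_end = 800, rate = 0.1,
                               duration = NULL, restraint_fc = 10000,
                               replicates = 3L) {
  if (T_end < T_start) stop_validation("T_end must be >= T_start")
  if (rate < 0) stop_validation("rate must be >= 0")
  if (replicates < 1L) stop_validation("replicates must be >= 1")
  if (is.null(duration)) {
    if (rate <= 0) stop_validation("need a positive rate or an explicit duration")
    duration <- (T_end - T_start) / rate
  } else if (rate > 0 &&
             abs(duration * rate - (T_end - T_start)) > 1e-6 * max(1, T_end)) {
    stop_validation("inconsistent schedule: duration * rate != T_end - T_start")
  }
  structure(list(T_start = T_start, T_end = T_end, rate = rate,
                 duration = duration, restraint_fc = restraint_fc,
                 replicates = as.integer(replicates)),
            class = "annealing_schedule")
}

#' Temperature along the ramp
#' @param schedule an `annealing_schedule`.
#' @param t_ps time points, ps.
#' @return temperatures, K.
#' @export
schedule_temperature <- function(schedule, t_ps) {
  pmin(schedule$T_end, schedule$T_start + schedule$rate * t_ps)
}

#' Serialize / parse the schedule descriptor
#'
#' Plain `key = value` text (one field per line, `#` comments allowed) that a
#' user can translate into their MD engine's input and that
#' [simulate_shell_dynamics()] consumes directly. `parse_schedule(emit_schedule(x))`
#' reproduces `x`.
#'
#' @param schedule an `annealing_schedule`.
#' @param file optional path to write to.
#' @return `emit_schedule`: character scalar; `parse_schedule`: an
#'   `annealing_schedule`.
#' @export
emit_schedule <- function(schedule, file = NULL) {
  txt <- paste(sprintf("%s = %.10g",
                       c("T_start_K", "T_end_K", "rate_K_per_ps",
                         "duration_ps", "restraint_kJ_mol_nm2", "replicates"),
                       c(schedule$T_start, schedule$T_end, schedule$rate,
                         schedule$duration, schedule$restraint_fc,
                         schedule$replicates)),
               collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  txt
}

#' @rdname emit_schedule
#' @param text descriptor text (string or lines).
#' @export
parse_schedule <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop_validation("malformed schedule descriptor")
  vals <- stats::setNames(as.numeric(trimws(vapply(kv, `[[`, "", 2L))),
                          trimws(vapply(kv, `[[`, "", 1L)))
  need <- c("T_start_K", "T_end_K", "rate_K_per_ps", "duration_ps",
            "restraint_kJ_mol_nm2", "replicates")
  if (!all(need %in% names(vals)))
    stop_validation("schedule descriptor missing field(s): ",
                    paste(setdiff(need, names(vals)), collapse = ", "))
  annealing_schedule(T_start = vals[["T_start_K"]], T_end = vals[["T_end_K"]],
                     rate = vals[["rate_K_per_ps"]],
                     duration = vals[["duration_ps"]],
                     restraint_fc = vals[["restraint_kJ_mol_nm2"]],
                     replicates = vals[["replicates"]])
}

#' @export
print.annealing_schedule <- function(x, ...) {
  cat(sprintf("annealing: %g -> %g K at %g K/ps (%g ps), restraint %g, x%d\n",
              x$T_start, x$T_end, x$rate, x$duration, x$restraint_fc,
              x$replicates))
  invisible(x)
}
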