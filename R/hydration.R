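#' @title Hydration-shell water counting and radial distribution functions
#' @name hydration
#' @description
#' The PARCH descriptor eta(t) is the number of water molecules (tested on
#' their oxygen) within a cutoff of any atom of a region at each recorded
#' frame: 4.5 A for nucleotide regions, 3.15 A for amino acids. The boundary
#' is closed (<= cutoff); one water may count for BB and NB of the same
#' residue simultaneously, since the two regions are scored independently.
#' Counting is cell-list accelerated; the cell list only prunes candidate
#' pairs and applies the identical final distance test as the brute-force
#' path, so the two agree exactly.
NULL

.water_oxygen_mask <- function(atoms) {
  atoms$role == "water" &
    (toupper(trimws(atoms$elesy)) %in% "O" |
       grepl("^O", toupper(trimws(atoms$elety))))
}

#' Water-oxygen atom indices of a system or atom table
#' @param x a `parch_system` or atom `data.frame`.
#' @return integer row indices.
#' @export
water_oxygens <- function(x) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  which(.water_oxygen_mask(atoms))
}

# Shared final pair test: squared distance (min-image if box) accumulated in
# a fixed coordinate order so brute-force and cell-list agree bit-for-bit.
.dist2_to_point <- function(w, a, box) {
  d <- w[, 1L] - a[1L]
  if (!is.null(box)) d <- d - box[1L] * round(d / box[1L])
  d2 <- d * d
  d <- w[, 2L] - a[2L]
  if (!is.null(box)) d <- d - box[2L] * round(d / box[2L])
  d2 <- d2 + d * d
  d <- w[, 3L] - a[3L]
  if (!is.null(box)) d <- d - box[3L] * round(d / box[3L])
  d2 + d * d
}

.hits_brute <- function(region_xyz, water_xyz, cutoff, box) {
  hit <- logical(nrow(water_xyz))
  for (i in seq_len(nrow(region_xyz))) {
    todo <- which(!hit)
    if (!length(todo)) break
    d2 <- .dist2_to_point(water_xyz[todo, , drop = FALSE],
                          region_xyz[i, ], box)
    hit[todo[d2 <= cutoff^2]] <- TRUE
  }
  hit
}

.hits_cell <- function(region_xyz, water_xyz, cutoff, box) {
  m <- nrow(water_xyz)
  if (m == 0L) return(logical(0L))
  if (is.null(box)) {
    origin <- apply(rbind(water_xyz, region_xyz), 2L, min)
    width <- rep(cutoff, 3L)
    ncell <- ceiling((apply(rbind(water_xyz, region_xyz), 2L, max) -
                        origin) / width) + 1L
    wrap <- FALSE
  } else {
    origin <- c(0, 0, 0)
    ncell <- pmax(1L, floor(box / cutoff))
    if (any(ncell < 3L)) return(.hits_brute(region_xyz, water_xyz, cutoff, box))
    width <- box / ncell
    wrap <- TRUE
  }
  cell_of <- function(xyz) {
    idx <- sweep(xyz, 2L, origin)
    if (wrap) for (k in 1:3) idx[, k] <- idx[, k] %% box[k]
    idx <- floor(sweep(idx, 2L, width, "/"))
    if (wrap) for (k in 1:3) idx[, k] <- pmin(idx[, k], ncell[k] - 1L)
    idx
  }
  wcell <- cell_of(water_xyz)
  wkey <- wcell[, 1L] + ncell[1L] * (wcell[, 2L] + ncell[2L] * wcell[, 3L])
  buckets <- split(seq_len(m), wkey)
  acell <- cell_of(region_xyz)
  hit <- logical(m)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(region_xyz))) {
    nb <- sweep(off, 2L, acell[i, ], "+")
    if (wrap) {
      for (k in 1:3) nb[, k] <- nb[, k] %% ncell[k]
    } else {
      ok <- nb[, 1L] >= 0 & nb[, 1L] < ncell[1L] &
        nb[, 2L] >= 0 & nb[, 2L] < ncell[2L] &
        nb[, 3L] >= 0 & nb[, 3L] < ncell[3L]
      nb <- nb[ok, , drop = FALSE]
    }
    keys <- unique(nb[, 1L] + ncell[1L] * (nb[, 2L] + ncell[2L] * nb[, 3L]))
    cand <- unlist(buckets[as.character(keys)], use.names = FALSE)
    cand <- cand[!hit[cand]]
    if (!length(cand)) next
    d2 <- .dist2_to_point(water_xyz[cand, , drop = FALSE],
                          region_xyz[i, ], box)
    hit[cand[d2 <= cutoff^2]] <- TRUE
  }
  hit
}

#' Count shell waters around one region in one frame
#'
#' Number of water oxygens within `cutoff` of at least one region atom,
#' minimum-image distances when a box is given.
#'
#' @param frame all-atom coordinates of the frame (n x 3 matrix or flat xyz
#'   vector).
#' @param region a region (element of `system$regions`).
#' @param waters water-oxygen coordinates: an m x 3 matrix, or integer row
#'   indices into `frame`.
#' @param cutoff distance cutoff, Angstrom (closed boundary).
#' @param box optional orthorhombic box edges.
#' @param method `"cell"` (cell-list pruning) or `"brute"`.
#' @return integer count.
#' @export
count_waters_frame <- function(frame, region, waters, cutoff, box = NULL,
                               method = c("cell", "brute")) {
  method <- match.arg(method)
  if (!is.numeric(cutoff) || cutoff <= 0) stop_validation("cutoff must be > 0")
  box <- check_box(box)
  frame <- as_xyz_matrix(frame)
  idx <- region$atom_idx
  if (any(idx < 1L | idx > nrow(frame)))
    stop_validation("region atom index out of frame bounds")
  rxyz <- frame[idx, , drop = FALSE]
  wxyz <- if (is.matrix(waters)) as_xyz_matrix(waters)
  else frame[as.integer(waters), , drop = FALSE]
  if (nrow(wxyz) == 0L) return(0L)
  f <- if (method == "cell") .hits_cell else .hits_brute
  sum(f(rxyz, wxyz, cutoff, box))
}

# ---- trajectories ----------------------------------------------------------

#' Trajectory container
#'
#' A `parch_trajectory` couples a static atom table with per-frame
#' coordinates (bio3d xyz layout: one row per frame, 3N columns), frame times
#' in ps, and an optional box.
#'
#' @param atoms atom `data.frame` (as in a `parch_system`).
#' @param xyz n_frames x 3N coordinate matrix.
#' @param times_ps frame times, ps, strictly increasing and uniformly spaced.
#' @param box optional orthorhombic box edges.
#' @return a `parch_trajectory`.
#' @export
parch_trajectory <- function(atoms, xyz, times_ps, box = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop_validation("xyz has ", ncol(xyz), " columns; expected ",
                    3L * nrow(atoms))
  if (length(times_ps) != nrow(xyz))
    stop_validation("times_ps length must equal the number of frames")
  if (length(times_ps) > 1L) {
    dt <- diff(times_ps)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * max(dt))
      stop_validation("frame times must be strictly increasing and uniform")
  }
  structure(list(atoms = atoms, xyz = xyz, times_ps = as.numeric(times_ps),
                 box = check_box(box)),
            class = "parch_trajectory")
}

#' @rdname parch_trajectory
#' @param traj a `parch_trajectory`.
#' @param i frame index.
#' @export
trajectory_frame <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' @export
print.parch_trajectory <- function(x, ...) {
  cat("parch_trajectory:", nrow(x$xyz), "frames x", nrow(x$atoms), "atoms,",
      "t =", x$times_ps[1L], "..", x$times_ps[length(x$times_ps)], "ps\n")
  invisible(x)
}

#' Read / write multi-model PDB trajectories
#'
#' @param file path to a multi-model PDB.
#' @param dt_ps frame spacing in ps (frame times are `0, dt, 2 dt, ...`).
#' @param aliases alias table for role assignment.
#' @return a `parch_trajectory`.
#' @export
read_trajectory <- function(file, dt_ps = 10, aliases = parch_aliases()) {
  if (!file.exists(file)) stop_io("no such file: ", file)
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE),
                  error = function(e) stop_io("trajectory parse failure: ",
                                              conditionMessage(e)))
  sys <- .system_from_atoms(pdb$atom, aliases)
  parch_trajectory(sys$atoms, pdb$xyz, dt_ps * (seq_len(nrow(pdb$xyz)) - 1L))
}

#' @rdname read_trajectory
#' @param traj a `parch_trajectory`.
#' @export
write_trajectory <- function(traj, file) {
  at <- traj$atoms
  bio3d::write.pdb(file = file, xyz = traj$xyz, resno = at$resno,
                   resid = at$resid, eleno = at$eleno, elety = at$elety,
                   chain = at$chain, insert = at$insert, o = at$o, b = at$b,
                   elesy = at$elesy)
  invisible(file)
}

# ---- count series ----------------------------------------------------------

.default_cutoff <- function(region, cutoff_na = 4.5, cutoff_aa = 3.15) {
  if (identical(region$class, "amino")) cutoff_aa else cutoff_na
}

#' Per-region water-count time series
#'
#' Applies [count_waters_frame()] over the (possibly strided) frames of a
#' trajectory, one series per region. Cutoffs default per region class:
#' 4.5 A for nucleotide BB/NB regions, 3.15 A for amino acids.
#'
#' @param traj a `parch_trajectory`.
#' @param regions list of regions; defaults to classifying `traj$atoms`.
#' @param cutoff single cutoff overriding the per-class defaults.
#' @param cutoff_na,cutoff_aa class defaults, Angstrom.
#' @param stride keep every `stride`-th frame.
#' @param replicate_id integer tag stored in the `replicate` column.
#' @param method `"cell"` or `"brute"`.
#' @return a `parch_counts` data frame with columns `chain`, `resseq`,
#'   `resname`, `alpha`, `replicate`, `time_ps`, `count`.
#' @export
count_series <- function(traj, regions = NULL, cutoff = NULL,
                         cutoff_na = 4.5, cutoff_aa = 3.15, stride = 1L,
                         replicate_id = 1L, method = c("cell", "brute")) {
  method <- match.arg(method)
  regions <- regions %||% classify_regions(traj$atoms)
  if (!length(regions)) stop_validation("no regions to count around")
  frames <- seq(1L, nrow(traj$xyz), by = as.integer(stride))
  if (length(frames) < 2L)
    stop_validation("need at least 2 sampled frames (got ", length(frames), ")")
  wat <- water_oxygens(traj$atoms)
  out <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    r <- regions[[ri]]
    co <- cutoff %||% .default_cutoff(r, cutoff_na, cutoff_aa)
    counts <- integer(length(frames))
    for (fi in seq_along(frames)) {
      fr <- trajectory_frame(traj, frames[fi])
      counts[fi] <- count_waters_frame(fr, r, wat, co, box = traj$box,
                                       method = method)
    }
    out[[ri]] <- data.frame(chain = r$chain, resseq = r$resno,
                            resname = r$resname, alpha = r$alpha,
                            replicate = as.integer(replicate_id),
                            time_ps = traj$times_ps[frames], count = counts,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("parch_counts", "data.frame")
  res
}

#' @rdname count_series
#' @param counts a `parch_counts` data frame.
#' @param file CSV path.
#' @export
write_counts <- function(counts, file) {
  utils::write.csv(as.data.frame(counts), file, row.names = FALSE)
  invisible(file)
}

#' @rdname count_series
#' @export
read_counts <- function(file) {
  if (!file.exists(file)) stop_io("no such file: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("chain", "resseq", "resname", "alpha", "replicate", "time_ps",
            "count")
  if (!all(need %in% names(df)))
    stop_validation("counts CSV missing column(s): ",
                    paste(setdiff(need, names(df)), collapse = ", "))
  df$chain <- as.character(df$chain)
  class(df) <- c("parch_counts", "data.frame")
  df
}

# ---- radial distribution function ------------------------------------------

#' Radial distribution function between two selections
#'
#' g(r) from minimum-image A-B distances over trajectory frames, normalized
#' by the ideal-gas expectation at the B number density (the
#' backbone-phosphorus / water-oxygen form of this function is what fixes
#' the 4.5 A shell thickness).
#'
#' @param traj a `parch_trajectory`.
#' @param sel_a,sel_b atom row indices of the two selections.
#' @param r_max histogram range, Angstrom.
#' @param bin_width bin width, Angstrom.
#' @param box orthorhombic box edges; defaults to `traj$box` (required for
#'   the density normalization).
#' @return a `parch_rdf`: list with `bin_centers`, `g`, `r_max`, `bin_width`,
#'   `n_frames`.
#' @export
radial_distribution <- function(traj, sel_a, sel_b, r_max, bin_width,
                                box = NULL) {
  box <- check_box(box %||% traj$box)
  if (is.null(box))
    stop_validation("radial_distribution needs a box for the density normalization")
  if (!length(sel_a) || !length(sel_b))
    stop_validation("both selections must be nonempty")
  if (!(r_max > bin_width && bin_width > 0))
    stop_validation("need r_max > bin_width > 0")
  if (r_max > min(box) / 2) {
    warn_parch("r_max ", r_max, " exceeds half the shortest box edge; truncated")
    r_max <- min(box) / 2
  }
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  n_frames <- nrow(traj$xyz)
  for (f in seq_len(n_frames)) {
    fr <- trajectory_frame(traj, f)
    d2 <- dist2_matrix(fr[sel_a, , drop = FALSE], fr[sel_b, , drop = FALSE],
                       box)
    self <- outer(sel_a, sel_b, "==")
    d <- sqrt(d2[!self])
    h <- findInterval(d[d <= r_max], breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
    h[h == 0L] <- 1L  # r = 0 edge
    counts <- counts + tabulate(h, nbins = nb)
  }
  vol <- prod(box)
  rho_b <- length(sel_b) / vol
  shell <- 4 / 3 * pi * (breaks[-1L]^3 - breaks[-length(breaks)]^3)
  g <- counts / (n_frames * length(sel_a) * rho_b * shell)
  structure(list(bin_centers = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 g = g, r_max = r_max, bin_width = bin_width,
                 n_frames = n_frames),
            class = "parch_rdf")
}
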