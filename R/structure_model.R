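#' @title Structure parsing and region classification
#' @name structure_model
#' @description
#' A `parch_system` holds an atom table (bio3d-style columns), the derived
#' residue regions, an optional orthorhombic box and the model count of the
#' source file. Nucleotide residues are split into a backbone (BB) region —
#' phosphate plus sugar atoms — and a base (NB) region; amino-acid residues
#' form a single AA region. PARCH values are written back into the PDB
#' B-factor column for visualization.
NULL

# ---- residue vocabulary ----------------------------------------------------

.dna_canon <- c("DA", "DC", "DG", "DT", "DU")
.rna_canon <- c("A", "C", "G", "U")
.aa_canon <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
               "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
               "TYR", "VAL")

.default_aliases <- function() {
  nt <- c(
    ADE = "A", GUA = "G", CYT = "C", URA = "U", URI = "U", THY = "DT",
    RA = "A", RC = "C", RG = "G", RU = "U",
    A3 = "A", A5 = "A", C3 = "C", C5 = "C", G3 = "G", G5 = "G",
    U3 = "U", U5 = "U",
    DA3 = "DA", DA5 = "DA", DC3 = "DC", DC5 = "DC",
    DG3 = "DG", DG5 = "DG", DT3 = "DT", DT5 = "DT"
  )
  aa <- c(HID = "HIS", HIE = "HIS", HIP = "HIS", HSD = "HIS", HSE = "HIS",
          HSP = "HIS", CYX = "CYS", CYM = "CYS", ASH = "ASP", GLH = "GLU",
          LYN = "LYS", MSE = "MET")
  water <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "TP3", "SPC", "T3P")
  ions <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "BR", "F",
            "I", "LI", "RB", "CS", "SOD", "CLA", "POT", "MGH", "CAL", "CES")
  list(nucleotide = nt, amino = aa, water = water, ion = ions)
}

#' Residue-name alias table
#'
#' PDB dialects drift: CHARMM writes `SOD` for sodium and `TIP3` for water,
#' Amber appends 5/3 to terminal nucleotides, older files use `ADE`/`GUA`.
#' The alias table maps such names onto canonical residue names and lists the
#' water and monatomic-ion names used for role assignment. Users can extend
#' any component.
#'
#' @param nucleotide,amino named character vectors of extra aliases
#'   (`c(XYZ = "DA")`).
#' @param water,ion extra residue names to treat as water / ions.
#' @return a list with components `nucleotide`, `amino`, `water`, `ion`.
#' @export
parch_aliases <- function(nucleotide = NULL, amino = NULL,
                          water = NULL, ion = NULL) {
  al <- .default_aliases()
  if (!is.null(nucleotide)) al$nucleotide <- c(al$nucleotide, nucleotide)
  if (!is.null(amino)) al$amino <- c(al$amino, amino)
  if (!is.null(water)) al$water <- c(al$water, water)
  if (!is.null(ion)) al$ion <- c(al$ion, ion)
  al
}

.canonical_resname <- function(resid, aliases) {
  resid <- toupper(trimws(resid))
  hit <- aliases$nucleotide[resid]
  resid[!is.na(hit)] <- hit[!is.na(hit)]
  hit <- aliases$amino[resid]
  resid[!is.na(hit)] <- hit[!is.na(hit)]
  resid
}

.residue_class <- function(canon, aliases) {
  out <- rep("other", length(canon))
  out[canon %in% c(.dna_canon, .rna_canon)] <- "nucleotide"
  out[canon %in% .aa_canon] <- "amino"
  out[canon %in% aliases$water] <- "water"
  out[canon %in% aliases$ion] <- "ion"
  out
}

# ---- BB / NB partition -----------------------------------------------------

# Backbone heavy atoms: the phosphate group (incl. 5'-terminal OP3 and the
# old O1P/O2P/O3P spellings) and the full sugar ring, O2' included for RNA.
.bb_heavy <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
               "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")

# A hydrogen belongs to the backbone iff its name pairs with a sugar or
# phosphate heavy atom: primed names (H5', H2'', HO2', ...) and the terminal
# hydroxyl/phosphate hydrogens. Everything else (H8, H61, H3, ...) is base.
.is_bb_hydrogen <- function(name) {
  grepl("'", name, fixed = TRUE) |
    grepl("^HO[235P]", name) | name %in% c("H5T", "H3T", "HOP2", "HOP3")
}

.is_hydrogen <- function(elety, elesy) {
  sy <- toupper(trimws(elesy))
  ifelse(!is.na(sy) & nzchar(sy), sy == "H",
         grepl("^[0-9]*H", toupper(trimws(elety))))
}

.region_key <- function(chain, resno, insert, resname) {
  ins <- ifelse(is.na(insert) | insert == "", "", as.character(insert))
  sprintf("%s:%s%s:%s", chain, resno, ins, resname)
}

#' Region identifier
#'
#' Builds the `"chain:resseq[icode]:resname:alpha"` string used as the unique
#' key of a residue region throughout the package.
#'
#' @param region a single region (element of `system$regions`).
#' @return character scalar.
#' @export
region_id <- function(region) {
  paste0(.region_key(region$chain, region$resno, region$insert, region$resname),
         ":", region$alpha)
}

#' Classify residues into PARCH regions
#'
#' Splits every solute residue into its scoring unit(s): a nucleotide yields
#' two disjoint regions whose union is the residue — BB (phosphate + sugar,
#' with their hydrogens) and NB (the base) — while an amino acid yields one
#' AA region. Region membership is a pure function of atom names; record
#' order is irrelevant. Unrecognized solute residues are excluded with a
#' warning. A 5'-terminal nucleotide without a phosphate still gets a BB
#' region from its sugar atoms; a nucleotide with no sugar atoms at all is a
#' malformed residue and raises an error.
#'
#' @param system a `parch_system`, or a bare atom `data.frame` with bio3d
#'   columns plus `role`.
#' @param aliases alias table from [parch_aliases()].
#' @return list of regions; each has `chain`, `resno`, `insert`, `resname`,
#'   `class` (`"nucleotide"`/`"amino"`), `alpha` (`"BB"`, `"NB"` or `"AA"`)
#'   and `atom_idx` (row indices into the atom table).
#' @export
classify_regions <- function(system, aliases = parch_aliases()) {
  atoms <- if (is.data.frame(system)) system else system$atoms
  sol <- which(atoms$role == "solute")
  regions <- list()
  if (length(sol) == 0L) return(regions)
  a <- atoms[sol, , drop = FALSE]
  canon <- .canonical_resname(a$resid, aliases)
  cls <- .residue_class(canon, aliases)
  fac <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert), sep = "\r")
  for (grp in split(seq_along(sol), factor(fac, levels = unique(fac)))) {
    i <- sol[grp]
    rclass <- cls[grp[1L]]
    rname <- canon[grp[1L]]
    base <- list(chain = a$chain[grp[1L]], resno = a$resno[grp[1L]],
                 insert = a$insert[grp[1L]], resname = rname)
    if (rclass == "amino") {
      regions[[length(regions) + 1L]] <-
        c(base, list(class = "amino", alpha = "AA", atom_idx = list(i)[[1]]))
      next
    }
    if (rclass != "nucleotide") {
      if (rclass == "other")
        warn_parch("residue ", .region_key(base$chain, base$resno, base$insert,
                                           rname),
                   " is not a recognized nucleotide or amino acid; excluded")
      next
    }
    nm <- toupper(trimws(a$elety[grp]))
    hyd <- .is_hydrogen(a$elety[grp], a$elesy[grp])
    bb <- (!hyd & nm %in% .bb_heavy) | (hyd & .is_bb_hydrogen(nm))
    sugar <- c("C1'", "C2'", "C3'", "C4'", "O4'")
    if (!any(nm %in% sugar))
      stop_validation("malformed nucleotide ",
                      .region_key(base$chain, base$resno, base$insert, rname),
                      ": no sugar atoms found")
    regions[[length(regions) + 1L]] <-
      c(base, list(class = "nucleotide", alpha = "BB", atom_idx = i[bb]))
    if (any(!bb)) {
      regions[[length(regions) + 1L]] <-
        c(base, list(class = "nucleotide", alpha = "NB", atom_idx = i[!bb]))
    } else {
      warn_parch("nucleotide ", .region_key(base$chain, base$resno,
                                            base$insert, rname),
                 " has no base atoms; NB region omitted")
    }
  }
  regions
}

# ---- parsing ---------------------------------------------------------------

.system_from_atoms <- function(atoms, aliases, box = NULL, model_count = 1L) {
  canon <- .canonical_resname(atoms$resid, aliases)
  cls <- .residue_class(canon, aliases)
  role <- rep("solute", nrow(atoms))
  role[cls == "water"] <- "water"
  role[cls == "ion"] <- "ion"
  atoms$role <- role
  sys <- structure(list(atoms = atoms, regions = list(), box = check_box(box),
                        model_count = as.integer(model_count),
                        aliases = aliases),
                   class = "parch_system")
  sys$regions <- classify_regions(sys, aliases)
  sys
}

# Keep only the highest-occupancy alternate conformer of each atom.
.resolve_altloc <- function(atom) {
  alt <- atom$alt
  if (all(is.na(alt) | alt %in% c("", "A"))) {
    return(atom[is.na(alt) | alt == "" | alt == "A", , drop = FALSE])
  }
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  keep <- unlist(lapply(split(seq_len(nrow(atom)), key),
                        function(i) i[which.max(occ[i])]), use.names = FALSE)
  atom[sort(keep), , drop = FALSE]
}

#' Parse a PDB structure into a `parch_system`
#'
#' Reads one model from PDB text (via bio3d), assigns every atom a role —
#' water (HOH/SOL/WAT/TIP3...), monatomic ion, or solute — resolves alternate
#' locations by keeping the highest-occupancy conformer, and classifies the
#' solute into PARCH regions. Coordinates are Angstrom, serials 1-based.
#'
#' @param pdb_text character: PDB file content (single string or vector of
#'   lines).
#' @param model 1-based model index to extract from a multi-model file.
#' @param aliases alias table from [parch_aliases()].
#' @return a `parch_system`.
#' @export
parse_structure <- function(pdb_text, model = 1L, aliases = parch_aliases()) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(paste(pdb_text, collapse = "\n"), tf)
  read_structure(tf, model = model, aliases = aliases)
}

#' @rdname parse_structure
#' @param file path to a PDB file.
#' @export
read_structure <- function(file, model = 1L, aliases = parch_aliases()) {
  if (!file.exists(file)) stop_io("no such file: ", file)
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop_io("PDB parse failure: ",
                                              conditionMessage(e)))
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L) stop_io("no parsable ATOM/HETATM records")
  n_models <- nrow(pdb$xyz)
  model <- as.integer(model)
  if (model < 1L || model > n_models)
    stop_validation("requested model ", model, " but file has ",
                    n_models, " model(s)")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  atom$x <- xyz[, 1L]; atom$y <- xyz[, 2L]; atom$z <- xyz[, 3L]
  atom <- .resolve_altloc(atom)
  if (any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)))
    stop_validation("non-finite coordinates in model ", model)
  atom$b[is.na(atom$b)] <- 0
  atom$o[is.na(atom$o)] <- 1
  rownames(atom) <- NULL
  .system_from_atoms(atom, aliases, model_count = n_models)
}

#' @export
print.parch_system <- function(x, ...) {
  roles <- table(factor(x$atoms$role, levels = c("solute", "water", "ion")))
  alphas <- table(vapply(x$regions, `[[`, "", "alpha"))
  cat("parch_system:", nrow(x$atoms), "atoms (",
      paste(names(roles), roles, collapse = ", "), ")\n")
  cat("  regions:", length(x$regions),
      if (length(alphas)) paste0("(", paste(names(alphas), alphas,
                                            collapse = ", "), ")") else "", "\n")
  if (!is.null(x$box))
    cat("  box:", paste(sprintf("%.2f", x$box), collapse = " x "), "A\n")
  invisible(x)
}

# ---- annotation ------------------------------------------------------------

#' Write PARCH values into the B-factor column
#'
#' Every solute atom's B-factor is replaced by the PARCH value of the region
#' it belongs to (two decimals, clamped to the PDB field range 0-999.99);
#' waters and ions get 0.00. The result renders hydropathy directly in any
#' molecular viewer that colors by B-factor. A round-trip through
#' [parse_structure()] recovers the values to +/-0.005.
#'
#' @param system a `parch_system`.
#' @param table a `parch_table` (see [compute_parch()]) covering every region
#'   of the system.
#' @return character scalar: the annotated PDB text.
#' @export
annotate_bfactor <- function(system, table) {
  pv <- stats::setNames(table$PV, paste0(.region_key(table$chain, table$resseq,
                                                     table$insert %||%
                                                       rep(NA, nrow(table)),
                                                     table$resname),
                                         ":", table$alpha))
  b <- numeric(nrow(system$atoms))
  missing <- character()
  for (r in system$regions) {
    id <- region_id(r)
    if (is.na(pv[id])) { missing <- c(missing, id); next }
    val <- pv[[id]]
    if (val > 999.99) {
      warn_parch("PARCH value ", val, " for ", id, " clamped to 999.99")
      val <- 999.99
    }
    b[r$atom_idx] <- max(0, val)
  }
  if (length(missing))
    stop_validation("no PARCH value for region(s): ",
                    paste(missing, collapse = ", "))
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  at <- system$atoms
  bio3d::write.pdb(file = tf, xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, eleno = at$eleno,
                   elety = at$elety, chain = at$chain, insert = at$insert,
                   o = at$o, b = round(b, 2), elesy = at$elesy)
  paste(readLines(tf), collapse = "\n")
}

#' @rdname annotate_bfactor
#' @param file output path for the annotated PDB.
#' @export
write_annotated_pdb <- function(system, table, file) {
  txt <- annotate_bfactor(system, table)
  writeLines(txt, file)
  invisible(file)
}
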