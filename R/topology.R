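##
## Topology: the static description of a molecular system -- one row per atom
## with names, residue bookkeeping, masses and (optionally) force-field
## parameters.  Internal units: Angstrom, ns, amu, kJ/mol, elementary charge.
##

## Standard atomic masses (amu) for elements seen in biomolecular systems.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, "NA" = 22.990,
  K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845,
  MN = 54.938, SE = 78.971
)

.water_resnames <- c("HOH", "SOL", "WAT", "TIP3", "TIP3P", "TIP", "SPC")
.ion_resnames <- c("NA", "CL", "K", "MG", "CA", "ZN", "SOD", "CLA", "POT",
                   "MG2", "CAL", "NA+", "CL-", "K+")
.amino_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN", "MSE"
)

#' Construct a Topology
#'
#' A Topology holds one row per atom: 0-based \code{atom_index}, atom and
#' residue names, author residue numbers, chain ids, element, mass (amu) and
#' optional per-atom force-field parameters (charge in elementary charges,
#' Lennard-Jones \code{lj_sigma} in nm and \code{lj_epsilon} in kJ/mol,
#' \code{vdw_radius} in Angstrom).  A per-atom \code{molecule_tag} classifies
#' atoms as protein, ligand, water, ion or other.
#'
#' @param atoms data.frame with at least \code{atom_name}, \code{residue_name},
#'   \code{residue_number}, \code{chain_id}; \code{element} and \code{mass}
#'   are derived when absent.
#' @param water_resnames residue names recognised as water.
#' @return an object of class \code{"topology"}.
#' @export
topology <- function(atoms, water_resnames = .water_resnames) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("atom_name", "residue_name", "residue_number", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_pd("topology(): missing atom fields: %s",
                            paste(miss, collapse = ", "))
  n <- nrow(atoms)
  atoms$atom_name <- trimws(as.character(atoms$atom_name))
  atoms$residue_name <- trimws(toupper(as.character(atoms$residue_name)))
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$atom_index <- 0:(n - 1L)

  if (is.null(atoms$element) || any(!nzchar(trimws(atoms$element)))) {
    guess <- guess_element(atoms$atom_name, atoms$residue_name)
    if (is.null(atoms$element)) {
      atoms$element <- guess
    } else {
      blank <- !nzchar(trimws(atoms$element))
      atoms$element[blank] <- guess[blank]
    }
  }
  atoms$element <- toupper(trimws(atoms$element))

  if (is.null(atoms$mass)) {
    m <- .element_masses[atoms$element]
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop_pd("topology(): unknown element '%s' for atom %d ('%s' in %s%d)",
              atoms$element[bad], bad - 1L, atoms$atom_name[bad],
              atoms$residue_name[bad], atoms$residue_number[bad])
    }
    atoms$mass <- unname(m)
  }
  if (any(atoms$mass <= 0)) stop_pd("topology(): non-positive atomic mass")

  ## contiguous 0-based residue_index per chain, in file order
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$residue_name,
               sep = "\r")
  atoms$residue_index <- match(key, unique(key)) - 1L

  if (is.null(atoms$molecule_tag)) {
    tag <- rep("other", n)
    tag[atoms$residue_name %in% .amino_resnames] <- "protein"
    tag[atoms$residue_name %in% toupper(water_resnames)] <- "water"
    tag[atoms$residue_name %in% .ion_resnames] <- "ion"
    atoms$molecule_tag <- tag
  }

  structure(list(atoms = atoms, n_atoms = n), class = "topology")
}

## Element from atom name: strip digits, take leading letters; names starting
## with a digit (e.g. "1HB") or leading H after digit stripping are hydrogen.
guess_element <- function(atom_name, residue_name = NULL) {
  nm <- toupper(trimws(atom_name))
  stripped <- gsub("[0-9']", "", nm)
  el <- substr(stripped, 1, 1)
  two <- substr(stripped, 1, 2)
  el[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")] <-
    two[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")]
  ## "CA" is the alpha carbon in amino acids but calcium as a lone ion
  if (!is.null(residue_name)) {
    is_ca_ion <- two == "CA" & toupper(residue_name) %in% c("CA", "CAL")
    el[is_ca_ion] <- "CA"
  }
  el[substr(nm, 1, 1) %in% as.character(0:9)] <- "H"
  unknown <- !el %in% names(.element_masses)
  if (any(unknown)) {
    stop_pd("cannot assign an element to atom name '%s'", nm[unknown][1])
  }
  el
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("topology: %d atoms, %d residues, %d chain(s)\n",
              x$n_atoms, length(unique(a$residue_index)),
              length(unique(a$chain_id))))
  tab <- table(a$molecule_tag)
  cat("  tags:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a topology.
#' @return integer atom count.
#' @export
n_atoms <- function(top) top$n_atoms

## residue_index -> rows lookup, as a list of integer vectors (1-based rows)
residue_atom_rows <- function(top, residue_indices = NULL) {
  ri <- top$atoms$residue_index
  if (is.null(residue_indices)) residue_indices <- sort(unique(ri))
  lapply(residue_indices, function(r) which(ri == r))
}

is_hydrogen <- function(top) top$atoms$element == "H"

#' Select atoms by expression
#'
#' Selection expressions are conjunctions joined by \code{" and "}.  Terms:
#' keywords \code{protein}, \code{ligand}, \code{water}, \code{ion},
#' \code{main_chain} (backbone N, CA, C, O of protein residues), \code{heavy}
#' (element != H), \code{calpha}, \code{water_oxygen}, \code{sidechain};
#' \code{chain X}; \code{resnum A-B} or \code{resnum A,B,C}; \code{resname X};
#' \code{name N1,N2}.  Example: \code{"chain A and resnum 228-255 and
#' main_chain"}.
#'
#' @param top a topology.
#' @param expression selection string.
#' @param label optional label stored on the selection.
#' @return object of class \code{"atom_selection"}: ordered unique 0-based
#'   \code{indices} plus the \code{label}.
#' @export
select_atoms <- function(top, expression, label = expression) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  terms <- strsplit(expression, "\\s+and\\s+")[[1]]
  terms <- trimws(terms[nzchar(trimws(terms))])
  if (!length(terms)) stop_pd("select_atoms(): empty selection expression")
  for (tm in terms) {
    low <- tolower(tm)
    keep <- keep & switch(
      strsplit(low, "\\s+")[[1]][1],
      protein = a$molecule_tag == "protein",
      ligand = a$molecule_tag %in% c("ligand", "other") &
        !a$residue_name %in% .water_resnames,
      water = a$molecule_tag == "water",
      ion = a$molecule_tag == "ion",
      heavy = a$element != "H",
      main_chain = a$molecule_tag == "protein" &
        a$atom_name %in% c("N", "CA", "C", "O"),
      sidechain = a$molecule_tag == "protein" &
        !a$atom_name %in% c("N", "CA", "C", "O") & a$element != "H",
      calpha = a$molecule_tag == "protein" & a$atom_name == "CA",
      water_oxygen = a$molecule_tag == "water" & a$element == "O",
      chain = a$chain_id %in% parse_list_term(tm),
      resnum = a$residue_number %in% parse_range_term(tm),
      resname = a$residue_name %in% toupper(parse_list_term(tm)),
      name = a$atom_name %in% toupper(parse_list_term(tm)),
      stop_pd("select_atoms(): unknown selection term '%s'", tm)
    )
  }
  idx <- which(keep)
  if (!length(idx)) stop_pd("select_atoms(): empty selection for '%s'",
                            expression)
  structure(list(indices = idx - 1L, label = label),
            class = "atom_selection")
}

parse_list_term <- function(term) {
  arg <- sub("^\\S+\\s+", "", trimws(term))
  trimws(strsplit(arg, ",")[[1]])
}

parse_range_term <- function(term) {
  parts <- parse_list_term(term)
  out <- integer(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE) && !grepl("^-", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      out <- c(out, as.integer(p))
    }
  }
  out
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

## 1-based rows for an atom_selection (or raw 0-based integer vector)
sel_rows <- function(sel) {
  if (inherits(sel, "atom_selection")) sel$indices + 1L else as.integer(sel) + 1L
}
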