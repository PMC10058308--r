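# Parsing of multi-model PDB depositions into the ensemble data model used by
# the whole pipeline, plus residue typing and chemical-group annotation.

# Modified nucleotides mapped to their parent base; unknown residues fall
# through to kind "other" with a warning.
.NUC_PARENT <- c(
  A = "A", C = "C", G = "G", U = "U",
  DA = "A", DC = "C", DG = "G", DT = "U", DU = "U",
  `1MA` = "A", `2MG` = "G", `7MG` = "G", M2G = "G", OMG = "G", YG = "G",
  PSU = "U", H2U = "U", `5MU` = "U", `4SU` = "U", OMU = "U",
  `5MC` = "C", OMC = "C", I = "G"
)

.AA_CATEGORY <- c(
  ASP = "charged", GLU = "charged", LYS = "charged", ARG = "charged",
  HIS = "charged",
  CYS = "polar", ASN = "polar", GLN = "polar", SER = "polar", THR = "polar",
  TYR = "polar",
  ALA = "hydrophobic", PHE = "hydrophobic", GLY = "hydrophobic",
  ILE = "hydrophobic", LEU = "hydrophobic", TRP = "hydrophobic",
  MET = "hydrophobic", PRO = "hydrophobic", VAL = "hydrophobic"
)

.WATER <- c("HOH", "WAT", "H2O", "DOD", "SOL")

.PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")
# O5'/O3' kept with the ribose so that the phosphate group is the PO4 core and
# 5'/3' termini partition unambiguously.
.RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'",
                   "O2'", "O3'", "O4'", "O5'")

.norm_atom_name <- function(x) gsub("\\*", "'", toupper(trimws(x)))

.element_from_name <- function(elety) {
  nm <- toupper(trimws(elety))
  nm <- gsub("['*]", "", nm)
  two <- c("CL", "BR", "FE", "MG", "ZN", "NA", "MN", "SE")
  first2 <- substr(nm, 1, 2)
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    s <- nm[i]
    if (first2[i] %in% two && nchar(s) == 2) {
      out[i] <- first2[i]
      next
    }
    s <- sub("^[0-9]+", "", s)
    out[i] <- substr(s, 1, 1)
  }
  out
}

#' Classify an atom into its chemical group
#'
#' Nucleotide heavy atoms partition into exactly one of `phosphate`
#' (P, OP1, OP2, OP3), `ribose` (C1'-C5', O2', O3', O4', O5') or `base`
#' (all remaining heavy atoms). Amino-acid atoms are labelled by the residue's
#' physicochemical category: `charged` (Asp, Glu, Lys, Arg, His), `polar`
#' (Cys, Asn, Gln, Ser, Thr, Tyr) or `hydrophobic` (Ala, Phe, Gly, Ile, Leu,
#' Trp, Met, Pro, Val).
#'
#' @param res_name Residue name (3-letter amino acid or 1-3 character
#'   nucleotide code; modified nucleotides are mapped to their parent base).
#' @param atom_name PDB atom name (`*` primes accepted).
#' @return A single string: `"phosphate"`, `"ribose"`, `"base"`, `"charged"`,
#'   `"polar"` or `"hydrophobic"`.
#' @export
classify_chemical_group <- function(res_name, atom_name) {
  res <- toupper(trimws(res_name))
  atm <- .norm_atom_name(atom_name)
  if (!nzchar(atm))
    stop("classification error: empty atom name in residue '", res, "'")
  if (res %in% names(.AA_CATEGORY))
    return(unname(.AA_CATEGORY[res]))
  if (res %in% names(.NUC_PARENT)) {
    if (atm %in% .PHOSPHATE_ATOMS) return("phosphate")
    if (atm %in% .RIBOSE_ATOMS) return("ribose")
    if (grepl("^H|^[0-9]+H|^D", atm)) {
      # hydrogens follow the heavy atom they decorate
      if (grepl("'", atm)) return("ribose")
      if (grepl("P", atm)) return("phosphate")
      return("base")
    }
    return("base")
  }
  stop("classification error: unknown residue name '", res,
       "' (atom '", atm, "')")
}

.residue_kind <- function(res_name, rectype) {
  res <- toupper(trimws(res_name))
  ifelse(res %in% names(.NUC_PARENT), "nucleotide",
    ifelse(res %in% names(.AA_CATEGORY), "amino_acid",
      ifelse(rectype == "HETATM", "ligand", "other")))
}

#' Read a multi-model PDB file into an ensemble
#'
#' Parses all `MODEL`/`ENDMDL` blocks of an NMR-style deposition (one implicit
#' model is accepted), drops waters, keeps the highest-occupancy alternate
#' location, annotates every atom with its residue kind and chemical group,
#' and checks that all models share one residue topology.
#'
#' @param path Path to a PDB file.
#' @param rna_chain Chain identifier of the RNA chain; when `NULL` the chain
#'   with the most nucleotide residues is used.
#' @param entry_id Optional identifier stored in the result (defaults to the
#'   file base name).
#' @return An object of class `rpflex_ensemble`: a list with `entry_id`,
#'   `atoms` (shared topology table), `xyz` (`n_atoms x 3 x n_models` array),
#'   `n_models`, `rna_chain`, `partner_kind` and `one_model` flag.
#' @export
read_multimodel_pdb <- function(path, rna_chain = NULL, entry_id = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  # per-model atom counts must agree (same topology across models)
  counts <- .model_atom_counts(path)
  if (length(counts) > 1 && length(unique(counts)) != 1)
    stop("topology error: models have differing atom counts (",
         paste(unique(counts), collapse = ", "), ")")
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)

  keep <- !(toupper(at$resid) %in% .WATER)
  # highest-occupancy alternate location per atom site
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any(nzchar(alt)) ||
      anyDuplicated(paste(at$chain, at$resno, at$insert, at$elety))) {
    site <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(site, -occ)
    keep_alt <- !duplicated(site[ord])
    keep_alt <- keep_alt[order(ord)]
    keep <- keep & keep_alt
  }
  at <- at[keep, , drop = FALSE]
  idx <- which(keep)
  xyz_arr <- array(NA_real_, dim = c(nrow(at), 3, n_models))
  for (m in seq_len(n_models)) {
    xm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    xyz_arr[, , m] <- xm[idx, , drop = FALSE]
  }

  at$elety <- .norm_atom_name(at$elety)
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | !nzchar(elem)
  if (any(miss)) elem[miss] <- .element_from_name(at$elety[miss])
  at$element <- elem
  at$is_heavy <- !(elem %in% c("H", "D"))
  at$kind <- .residue_kind(at$resid, at$type)
  unknown <- unique(at$resid[at$kind == "other"])
  if (length(unknown))
    warning("residues of unknown kind excluded from group statistics: ",
            paste(unknown, collapse = ", "))
  at$insert[is.na(at$insert)] <- ""
  at$reskey <- paste0(at$chain, "/", at$resno, at$insert)

  # RNA chain selection
  nuc <- at$kind == "nucleotide"
  if (is.null(rna_chain)) {
    if (!any(nuc)) stop("input error: no RNA chain found in ", path)
    tab <- table(at$chain[nuc])
    rna_chain <- names(tab)[which.max(tab)]
  } else if (!any(nuc & at$chain == rna_chain)) {
    stop("input error: no nucleotides on chain '", rna_chain, "'")
  }

  at$group <- NA_character_
  cls <- at$kind %in% c("nucleotide", "amino_acid")
  at$group[cls] <- mapply(classify_chemical_group,
                          at$resid[cls], at$elety[cls], USE.NAMES = FALSE)

  # residue ordinal in file order
  at$res_index <- cumsum(!duplicated(at$reskey))[match(at$reskey, at$reskey)]
  at$res_index <- match(at$reskey, unique(at$reskey))

  partner_kind <- "none"
  if (any(at$kind == "amino_acid")) partner_kind <- "protein"
  else if (any(at$kind == "ligand")) partner_kind <- "ligand"

  ens <- structure(list(
    entry_id = if (is.null(entry_id))
      toupper(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))
    else entry_id,
    atoms = at,
    xyz = xyz_arr,
    n_models = n_models,
    rna_chain = rna_chain,
    partner_kind = partner_kind,
    one_model = n_models == 1L
  ), class = "rpflex_ensemble")
  if (ens$one_model)
    warning("entry ", ens$entry_id,
            " has a single structural model; flexibility analysis needs >= 2")
  ens
}

.model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (!length(model_starts)) {
    return(sum(rec %in% c("ATOM  ", "HETATM")))
  }
  ends <- which(trimws(rec) == "ENDMDL")
  mapply(function(s, e) sum(rec[s:e] %in% c("ATOM  ", "HETATM")),
         model_starts, ends)
}

# model-m coordinates as a matrix even when the ensemble has a single atom
.xyz_slice <- function(ensemble, m) {
  x <- ensemble$xyz[, , m]
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x
}

#' Extract one structural model from an ensemble
#'
#' @param ensemble An `rpflex_ensemble`.
#' @param i 1-based model index (MODEL record order).
#' @return An `rpflex_model`: list with the shared `atoms` table and an
#'   `n_atoms x 3` coordinate matrix `xyz`.
#' @export
get_model <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "rpflex_ensemble"),
            i >= 1, i <= ensemble$n_models)
  structure(list(atoms = ensemble$atoms,
                 xyz = .xyz_slice(ensemble, i),
                 model_index = as.integer(i)),
            class = "rpflex_model")
}

#' Heavy atoms of a structural model
#'
#' @param model An `rpflex_model`.
#' @param residue_subset Optional vector of residue keys (`chain/resno`) to
#'   restrict to.
#' @return An `rpflex_model` restricted to atoms with element != H, preserving
#'   residue association and order.
#' @export
heavy_atoms <- function(model, residue_subset = NULL) {
  keep <- model$atoms$is_heavy
  if (!is.null(residue_subset))
    keep <- keep & model$atoms$reskey %in% residue_subset
  structure(list(atoms = model$atoms[keep, , drop = FALSE],
                 xyz = model$xyz[keep, , drop = FALSE],
                 model_index = model$model_index),
            class = "rpflex_model")
}

.fmt_pdb_atom <- function(serial, name, resid, chain, resno, x, y, z,
                          rectype = "ATOM", element = "") {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial %% 100000, substr(nm, 1, 4), substr(resid, 1, 3),
          chain, resno %% 10000, x, y, z, 1, 0, element)
}

#' Write an ensemble to a multi-model PDB file
#'
#' Fixed-format ATOM/HETATM records inside MODEL/ENDMDL blocks; coordinates
#' at the standard 3-decimal precision.
#'
#' @param ensemble An `rpflex_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  at <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(ensemble$n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xm <- .xyz_slice(ensemble, m)
    rect <- ifelse(at$kind %in% c("ligand", "other"), "HETATM", "ATOM")
    lines <- vapply(seq_len(nrow(at)), function(r) {
      .fmt_pdb_atom(r, at$elety[r], at$resid[r], at$chain[r], at$resno[r],
                    xm[r, 1], xm[r, 2], xm[r, 3], rect[r], at$element[r])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
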