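# Hydrogen-bond and van der Waals contact detection by distance criteria
# (HBPLUS-style distances: H-acceptor < 2.7 A and donor-acceptor < 3.35 A for
# hydrogen bonds; < 3.9 A for vdW contacts between atoms not hydrogen
# bonded), and their summary by chemical-group pair categories.

.HB_DA_MAX <- 3.35
.HB_HA_MAX <- 2.7
.VDW_MAX <- 3.9
.COVALENT_GUARD <- 1.8

# Donor/acceptor dictionary: shipped as an editable csv. "NUC" rows apply to
# every nucleotide, "AA" rows to every amino acid main chain.
.hbond_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      path <- system.file("extdata", "hbond_donors_acceptors.csv",
                          package = "rpflex")
      tab <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    tab
  }
})

.donor_acceptor_roles <- function(res_parent, atom, kind) {
  tab <- .hbond_table()
  n <- length(atom)
  donor <- logical(n)
  acceptor <- logical(n)
  for (i in seq_len(n)) {
    keys <- switch(kind[i],
                   nucleotide = c(res_parent[i], "NUC"),
                   amino_acid = c(res_parent[i], "AA"),
                   character(0))
    if (!length(keys)) {
      # generic rule for ligands: N/O/S atoms may both donate and accept
      el <- substr(sub("^[0-9]+", "", atom[i]), 1, 1)
      donor[i] <- acceptor[i] <- el %in% c("N", "O", "S")
      next
    }
    hit <- tab$role[tab$res %in% keys & tab$atom == atom[i]]
    donor[i] <- any(hit %in% c("donor", "both"))
    acceptor[i] <- any(hit %in% c("acceptor", "both"))
  }
  list(donor = donor, acceptor = acceptor)
}

.parent_res <- function(resid, kind) {
  out <- toupper(resid)
  nuc <- kind == "nucleotide"
  out[nuc] <- .NUC_PARENT[out[nuc]]
  out
}

# Covalent inter-residue linkages: RNA backbone O3'(i)-P(i+1), peptide
# C(i)-N(i+1), plus a general short-distance guard.
.is_covalent_pair <- function(atom_i, atom_j, chain_i, chain_j,
                              resno_i, resno_j, dist) {
  adj <- chain_i == chain_j & abs(resno_i - resno_j) == 1L
  backbone <- adj & ((atom_i == "O3'" & atom_j == "P") |
                     (atom_j == "O3'" & atom_i == "P"))
  peptide <- adj & ((atom_i == "C" & atom_j == "N") |
                    (atom_j == "C" & atom_i == "N"))
  backbone | peptide | dist < .COVALENT_GUARD
}

.scope_atoms <- function(model, residue_scope) {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(residue_scope)) keep <- at$reskey %in% residue_scope
  list(atoms = at[keep, , drop = FALSE],
       xyz = model$xyz[keep, , drop = FALSE])
}

#' Detect hydrogen bonds by distance criteria
#'
#' A donor-acceptor atom pair in different residues is a hydrogen bond when
#' the donor-acceptor distance is strictly below 3.35 Angstrom and - when an
#' explicit hydrogen bonded to the donor is present - the hydrogen-acceptor
#' distance is strictly below 2.7 Angstrom. Without explicit hydrogens the
#' donor-acceptor criterion alone applies. Covalently linked pairs are
#' excluded. Only distance criteria are enforced (no angular terms).
#'
#' @param model An `rpflex_model`.
#' @param residue_scope Optional residue keys to restrict to.
#' @return Data frame of contact records: `res_i`, `res_j`, `atom_i`
#'   (donor), `atom_j` (acceptor), `distance`, `type = "hbond"`, `category`.
#' @export
find_hbonds <- function(model, residue_scope = NULL) {
  sc <- .scope_atoms(model, residue_scope)
  at <- sc$atoms
  heavy <- at$is_heavy
  parent <- .parent_res(at$resid, at$kind)
  roles <- .donor_acceptor_roles(parent, at$elety, at$kind)
  if (!any(heavy & roles$donor) || !any(heavy & roles$acceptor))
    return(.empty_records())

  # explicit hydrogens attached to each heavy atom (same residue, < 1.25 A)
  h_of <- vector("list", nrow(at))
  if (any(!at$is_heavy)) {
    cp_h <- cpp_close_pairs(sc$xyz, 1.25)
    for (t in seq_along(cp_h$i)) {
      a <- cp_h$i[t]; b <- cp_h$j[t]
      if (at$reskey[a] != at$reskey[b]) next
      if (!at$is_heavy[a] && at$is_heavy[b]) h_of[[b]] <- c(h_of[[b]], a)
      else if (at$is_heavy[a] && !at$is_heavy[b]) h_of[[a]] <- c(h_of[[a]], b)
    }
  }

  cp <- cpp_close_pairs(sc$xyz, .HB_DA_MAX)
  rec <- list()
  test_pair <- function(d, a, da) {
    # d donor atom index, a acceptor atom index
    if (!(at$is_heavy[d] && at$is_heavy[a])) return(NULL)
    if (!(roles$donor[d] && roles$acceptor[a])) return(NULL)
    if (at$reskey[d] == at$reskey[a]) return(NULL)
    if (.is_covalent_pair(at$elety[d], at$elety[a], at$chain[d], at$chain[a],
                          at$resno[d], at$resno[a], da)) return(NULL)
    dh <- h_of[[d]]
    if (length(dh)) {
      ha <- min(cpp_min_dist(sc$xyz[dh, , drop = FALSE],
                             sc$xyz[a, , drop = FALSE]))
      if (ha >= .HB_HA_MAX) return(NULL)
    }
    data.frame(res_i = at$reskey[d], res_j = at$reskey[a],
               atom_i = at$elety[d], atom_j = at$elety[a],
               distance = da, type = "hbond", stringsAsFactors = FALSE)
  }
  for (t in seq_along(cp$i)) {
    hit <- test_pair(cp$i[t], cp$j[t], cp$d[t])
    if (is.null(hit)) hit <- test_pair(cp$j[t], cp$i[t], cp$d[t])
    if (!is.null(hit)) rec[[length(rec) + 1]] <- hit
  }
  if (!length(rec)) return(.empty_records())
  out <- do.call(rbind, rec)
  out$category <- categorize(out, model)
  out
}

.empty_records <- function() {
  data.frame(res_i = character(0), res_j = character(0),
             atom_i = character(0), atom_j = character(0),
             distance = numeric(0), type = character(0),
             category = character(0), stringsAsFactors = FALSE)
}

#' Detect van der Waals contacts
#'
#' Heavy-atom pairs in different residues strictly below 3.9 Angstrom that
#' are not hydrogen-bond pairs and not covalent inter-residue linkages
#' (e.g. the backbone O3'-P bond).
#'
#' @param model An `rpflex_model`.
#' @param residue_scope Optional residue keys to restrict to.
#' @param hbonds Hydrogen-bond records from [find_hbonds()] (computed first).
#' @return Data frame of contact records with `type = "vdw"`.
#' @export
find_vdw <- function(model, residue_scope = NULL, hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- find_hbonds(model, residue_scope)
  sc <- .scope_atoms(model, residue_scope)
  keep <- sc$atoms$is_heavy
  at <- sc$atoms[keep, , drop = FALSE]
  xyz <- sc$xyz[keep, , drop = FALSE]
  n <- nrow(at)
  if (n < 2) return(.empty_records())
  hb_key <- if (nrow(hbonds)) paste(
    pmin(paste(hbonds$res_i, hbonds$atom_i), paste(hbonds$res_j, hbonds$atom_j)),
    pmax(paste(hbonds$res_i, hbonds$atom_i), paste(hbonds$res_j, hbonds$atom_j)),
    sep = "|") else character(0)
  cp <- cpp_close_pairs(xyz, .VDW_MAX)
  if (!length(cp$i)) return(.empty_records())
  i <- cp$i; j <- cp$j; d <- cp$d
  diffres <- at$reskey[i] != at$reskey[j]
  i <- i[diffres]; j <- j[diffres]; d <- d[diffres]
  if (!length(i)) return(.empty_records())
  cov <- .is_covalent_pair(at$elety[i], at$elety[j], at$chain[i], at$chain[j],
                           at$resno[i], at$resno[j], d)
  key <- paste(pmin(paste(at$reskey[i], at$elety[i]),
                    paste(at$reskey[j], at$elety[j])),
               pmax(paste(at$reskey[i], at$elety[i]),
                    paste(at$reskey[j], at$elety[j])), sep = "|")
  ok <- !cov & !(key %in% hb_key)
  if (!any(ok)) return(.empty_records())
  out <- data.frame(res_i = at$reskey[i][ok], res_j = at$reskey[j][ok],
                    atom_i = at$elety[i][ok], atom_j = at$elety[j][ok],
                    distance = d[ok], type = "vdw", stringsAsFactors = FALSE)
  out$category <- categorize(out, model)
  out
}

#' Categorize contact records by chemical-group pair
#'
#' RNA-RNA contacts map the unordered pair of chemical groups onto the five
#' labels BB (base-base), RB (ribose-base), PB (phosphate-base), PR
#' (phosphate-ribose) and RR (ribose-ribose); phosphate-phosphate pairs are
#' labelled `PP` and excluded from five-category percentages. RNA-protein
#' contacts carry the amino-acid category (`charged`, `polar`,
#' `hydrophobic`); RNA-ligand contacts are `ligand-base` or
#' `ligand-backbone` depending on the RNA-side group. Anything else is
#' `other`.
#'
#' @param records Data frame with `res_i`, `res_j`, `atom_i`, `atom_j`.
#' @param model The `rpflex_model` the records came from.
#' @return Character vector of categories.
#' @export
categorize <- function(records, model) {
  at <- model$atoms
  n <- nrow(records)
  if (!n) return(character(0))
  key <- paste(at$reskey, at$elety)
  ia <- match(paste(records$res_i, records$atom_i), key)
  ib <- match(paste(records$res_j, records$atom_j), key)
  ka <- at$kind[ia]; kb <- at$kind[ib]
  ga <- at$group[ia]; gb <- at$group[ib]
  pair_rna <- c(`base|base` = "BB", `base|ribose` = "RB",
                `base|phosphate` = "PB", `phosphate|ribose` = "PR",
                `ribose|ribose` = "RR", `phosphate|phosphate` = "PP")
  out <- rep("other", n)
  ok <- !is.na(ka) & !is.na(kb)
  nn <- ok & ka == "nucleotide" & kb == "nucleotide"
  if (any(nn)) {
    lab <- pair_rna[paste(pmin(ga[nn], gb[nn]), pmax(ga[nn], gb[nn]),
                          sep = "|")]
    lab[is.na(lab)] <- "other"
    out[nn] <- lab
  }
  np <- ok & xor(ka == "nucleotide", kb == "nucleotide")
  if (any(np)) {
    other_kind <- ifelse(ka[np] == "nucleotide", kb[np], ka[np])
    other_group <- ifelse(ka[np] == "nucleotide", gb[np], ga[np])
    rna_group <- ifelse(ka[np] == "nucleotide", ga[np], gb[np])
    lab <- rep("other", sum(np))
    lab[other_kind == "amino_acid"] <- other_group[other_kind == "amino_acid"]
    lig <- other_kind == "ligand"
    lab[lig] <- ifelse(rna_group[lig] == "base", "ligand-base",
                       "ligand-backbone")
    out[np] <- lab
  }
  out
}

#' Summarize contact records by category
#'
#' Counts and percentages per category, separately for hydrogen bonds and
#' vdW contacts. RNA-RNA percentages are over the five categories BB, RB,
#' PB, PR, RR; RNA-partner percentages are over the partner categories.
#'
#' @param records Data frame of contact records (hbond and/or vdw rows).
#' @return List of class `rpflex_contact_summary` with one data frame per
#'   contact type, each with `category`, `count`, `percent`.
#' @export
summarize_contacts <- function(records) {
  if (!nrow(records)) {
    warning("no contact records; all-zero summary")
    return(structure(list(hbond = .empty_summary(), vdw = .empty_summary()),
                     class = "rpflex_contact_summary"))
  }
  five <- c("BB", "RB", "PB", "PR", "RR")
  per_type <- function(df) {
    if (!nrow(df)) return(.empty_summary())
    cats <- table(df$category)
    rna <- cats[names(cats) %in% five]
    partner <- cats[!(names(cats) %in% c(five, "PP", "other"))]
    mk <- function(tab) {
      if (!length(tab)) return(NULL)
      data.frame(category = names(tab), count = as.integer(tab),
                 percent = 100 * as.integer(tab) / sum(tab),
                 stringsAsFactors = FALSE)
    }
    rbind(mk(rna), mk(partner))
  }
  structure(list(hbond = per_type(records[records$type == "hbond", ]),
                 vdw = per_type(records[records$type == "vdw", ])),
            class = "rpflex_contact_summary")
}

.empty_summary <- function() {
  data.frame(category = character(0), count = integer(0),
             percent = numeric(0), stringsAsFactors = FALSE)
}

#' Contact profile of a pocket group
#'
#' Hydrogen bonds and vdW contacts restricted to the pocket-lining
#' nucleotides of the group's pockets (plus any partner residues within the
#' entry), evaluated per member model and pooled.
#'
#' @param group An `rpflex_pocket_group` with `m >= 3`.
#' @param ensemble The `rpflex_ensemble`.
#' @param pockets The entry's pocket list.
#' @param contact_cutoff Passed to [pocket_lining_nucleotides()].
#' @return List with `records` (pooled, one row per contact per model),
#'   `summary` (pooled [summarize_contacts()]), and `per_model` summaries.
#' @export
group_interactions <- function(group, ensemble, pockets,
                               contact_cutoff = 4.0) {
  stopifnot(group$valid)
  by_label <- setNames(pockets,
                       vapply(pockets, function(p) p$label, character(1)))
  at <- ensemble$atoms
  lining <- unique(unlist(lapply(group$members, function(l) {
    p <- by_label[[l]]
    pocket_lining_nucleotides(p, get_model(ensemble, p$model_index),
                              contact_cutoff)
  })))
  partner <- unique(at$reskey[at$kind %in% c("amino_acid", "ligand")])
  scope <- c(lining, partner)
  models <- unique(vapply(group$members, function(l)
    by_label[[l]]$model_index, integer(1)))
  recs <- list()
  per_model <- list()
  for (m in models) {
    mod <- get_model(ensemble, m)
    hb <- find_hbonds(mod, scope)
    vd <- find_vdw(mod, scope, hb)
    both <- rbind(hb, vd)
    if (nrow(both)) both$model <- m
    recs[[length(recs) + 1]] <- both
    per_model[[as.character(m)]] <- suppressWarnings(summarize_contacts(both))
  }
  records <- do.call(rbind, recs)
  list(records = records,
       summary = suppressWarnings(
         summarize_contacts(if (is.null(records)) .empty_records()
                            else records)),
       per_model = per_model)
}
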